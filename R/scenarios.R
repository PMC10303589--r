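#' Bundle a monitored site into a named design scenario
#'
#' @param name Scenario label; unique within a run.
#' @param segment A [body_segment()].
#' @param collector A [collector_spec()].
#' @param monitoring A [monitoring_spec()].
#' @param s_min Required readouts for the healthcare decision, >= 1.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, segment, collector, monitoring, s_min) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(segment, "body_segment"),
            inherits(collector, "collector_spec"),
            inherits(monitoring, "monitoring_spec"),
            is.numeric(s_min), length(s_min) == 1L, s_min >= 1)
  structure(list(name = name, segment = segment, collector = collector,
                 monitoring = monitoring, s_min = s_min),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "\n")
  cat("  t_c =", x$segment$t_c, "s;")
  if (x$segment$mode == "velocity") {
    cat(" v in [", x$segment$v_min, ",", x$segment$v_max, "] cm/s;")
  } else {
    cat(" Q in [", x$segment$q_min, ",", x$segment$q_max, "] mL/s;",
        "r in [", x$segment$r_min, ",", x$segment$r_max, "] cm;")
  }
  cat(" w =", x$collector$w, "cm; T_M =", x$monitoring$duration_minutes,
      "min; s_min =", x$s_min, "\n")
  invisible(x)
}

#' Built-in case-study scenarios
#'
#' The bundled injury-monitoring case studies: tennis elbow (upper-limb
#' loop, 50 s circulation, velocities 1.5--19 cm/s, 20 cm collector),
#' runner's knee, shin splints, and heel inflammation (lower-limb loop,
#' 60 s circulation, velocities 3--15 cm/s, collectors of 15, 50, and 10 cm
#' respectively), each with a 100-readout requirement over a 10-minute
#' session; plus the shin-splints monitoring-time variants at 10, 12, and
#' 14 minutes under a 250-readout requirement.
#'
#' @return Named list of [scenario()] objects.
#' @export
builtin_scenarios <- function() {
  elbow_seg <- body_segment(50, v_min = 1.5, v_max = 19)
  leg_seg <- body_segment(60, v_min = 3, v_max = 15)
  scens <- list(
    scenario("tennis_elbow", elbow_seg, collector_spec(20, "elbow"),
             monitoring_spec(10), s_min = 100),
    scenario("runners_knee", leg_seg, collector_spec(15, "knee"),
             monitoring_spec(10), s_min = 100),
    scenario("shin_splints", leg_seg, collector_spec(50, "shin"),
             monitoring_spec(10), s_min = 100),
    scenario("heel_inflammation", leg_seg, collector_spec(10, "heel"),
             monitoring_spec(10), s_min = 100),
    scenario("shin_splints_tm10", leg_seg, collector_spec(50, "shin"),
             monitoring_spec(10), s_min = 250),
    scenario("shin_splints_tm12", leg_seg, collector_spec(50, "shin"),
             monitoring_spec(12), s_min = 250),
    scenario("shin_splints_tm14", leg_seg, collector_spec(50, "shin"),
             monitoring_spec(14), s_min = 250)
  )
  stats::setNames(scens, vapply(scens, `[[`, character(1), "name"))
}

# scenario <-> plain-list config mapping; units are documented in the
# schema: t_c seconds, velocities cm/s, flow mL/s, radii and w cm,
# monitoring minutes.
scenario_to_list <- function(sc) {
  seg <- sc$segment
  seg_list <- if (seg$mode == "velocity") {
    list(t_c = seg$t_c, v_min = seg$v_min, v_max = seg$v_max)
  } else {
    list(t_c = seg$t_c, q_min = seg$q_min, q_max = seg$q_max,
         r_min = seg$r_min, r_max = seg$r_max)
  }
  list(name = sc$name,
       segment = seg_list,
       collector = list(w = sc$collector$w, site = sc$collector$site),
       monitoring = list(
         duration_minutes = sc$monitoring$duration_minutes,
         opportunity_rate = sc$monitoring$opportunity_rate),
       s_min = sc$s_min)
}

#' Write a scenario config file
#'
#' @param sc A [scenario()].
#' @param path Destination; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return The path, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  x <- scenario_to_list(sc)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Load a scenario from a config file
#'
#' Reads a YAML or JSON scenario config (see [write_scenario()] for the
#' schema) and validates it; missing or invalid fields raise an error that
#' names them. Units: `t_c` in seconds, velocities in cm/s, flow in mL/s,
#' radii and `w` in cm, monitoring duration in minutes.
#'
#' @param path Config file path (`.yaml`, `.yml`, or `.json`).
#' @return A validated [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop("scenario config not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  missing_fields <- setdiff(c("name", "segment", "collector",
                              "monitoring", "s_min"), names(x))
  if (length(missing_fields)) {
    stop("scenario config missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  seg <- x$segment
  if (is.null(seg$t_c)) {
    stop("scenario config missing field(s): segment.t_c", call. = FALSE)
  }
  has_v <- !is.null(seg$v_min) || !is.null(seg$v_max)
  segment <- tryCatch({
    if (has_v) {
      body_segment(seg$t_c, v_min = seg$v_min, v_max = seg$v_max)
    } else {
      body_segment(seg$t_c, q_min = seg$q_min, q_max = seg$q_max,
                   r_min = seg$r_min, r_max = seg$r_max)
    }
  }, error = function(e) {
    stop("invalid segment in scenario config: ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(x$collector$w)) {
    stop("scenario config missing field(s): collector.w", call. = FALSE)
  }
  if (is.null(x$monitoring$duration_minutes)) {
    stop("scenario config missing field(s): monitoring.duration_minutes",
         call. = FALSE)
  }
  collector <- collector_spec(x$collector$w,
                              site = x$collector$site %||% "")
  monitoring <- monitoring_spec(
    x$monitoring$duration_minutes,
    opportunity_rate = x$monitoring$opportunity_rate %||% 1)
  scenario(x$name, segment, collector, monitoring, x$s_min)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full design analysis for one scenario
#'
#' Computes the circulation path length (mean velocity in expectation mode,
#' one seeded draw in stochastic mode), the pass probability, the readout
#' curve out to three times the optimal count (so the peak and post-peak
#' decline are visible), the optimal sensor count and maximum floored
#' readouts, the feasible range for the scenario's requirement, and the
#' smart-sensor-selection result.
#'
#' @param sc A [scenario()].
#' @param mode `"expectation"` or `"stochastic"`.
#' @param seed RNG seed (stochastic mode).
#' @param n_max Curve sweep bound; defaults to `3 * optimal_sensor_count`.
#' @return A `case_study_report`: list with `scenario`, `l`, `p_c`,
#'   `curve`, `optimal_n`, `max_s_floor`, `feasible`, `sss`, `physiology`,
#'   `mode`, `seed`.
#' @export
run_case_study <- function(sc, mode = c("expectation", "stochastic"),
                           seed = NULL, n_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(sc, "scenario"))
  l <- if (mode == "expectation") {
    expected_path_length(sc$segment)
  } else {
    path_length(sample_velocity_series(sc$segment, seed = seed))
  }
  p_c <- pass_probability(sc$collector, l)
  opt_n <- optimal_sensor_count(p_c)
  if (is.null(n_max)) n_max <- 3L * opt_n
  curve <- readout_curve(p_c, n_max, sc$monitoring)
  feas <- feasible_sensor_range(p_c, sc$s_min, sc$monitoring)
  sss <- smart_sensor_selection(sc$monitoring, sc$s_min, sc$segment,
                                sc$collector, mode = mode, seed = seed)
  structure(list(
    scenario = sc,
    l = l, p_c = p_c,
    curve = curve,
    optimal_n = opt_n,
    max_s_floor = as.integer(floor(max(curve$s))),
    feasible = feas,
    sss = sss,
    physiology = validate_physiology(sc$segment, sc$monitoring),
    mode = mode,
    seed = seed
  ), class = "case_study_report")
}

#' @export
print.case_study_report <- function(x, ...) {
  cat("<case_study_report>", x$scenario$name, "(", x$mode, "mode )\n")
  cat("  L =", format(x$l), "cm; P_C =", format(x$p_c), "\n")
  cat("  peak:", x$max_s_floor, "readouts at n =", x$optimal_n, "\n")
  if (x$feasible$empty) {
    cat("  requirement s_min =", x$scenario$s_min, "infeasible\n")
  } else {
    cat("  feasible n in [", x$feasible$n_min, ",", x$feasible$n_max,
        "] for s_min =", x$scenario$s_min, "; selected n =", x$sss$n, "\n")
  }
  invisible(x)
}

#' Minimum shared sensor count covering several sites
#'
#' When one sensor pool monitors several body sites in a single procedure,
#' the pool must satisfy the readout requirement of every site, so the
#' shared minimum is the maximum over sites of each site's minimal feasible
#' count.
#'
#' @param scenarios List of [scenario()] objects sharing one body.
#' @param s_min Optional required readouts applied to every site; defaults
#'   to each scenario's own `s_min`.
#' @param mode,seed Passed to [smart_sensor_selection()].
#' @return A list with `n` (shared sensor count) and `per_site` (named
#'   integer vector of per-site minima).
#' @export
multi_site_minimum <- function(scenarios, s_min = NULL,
                               mode = "expectation", seed = NULL) {
  stopifnot(length(scenarios) >= 1)
  minima <- vapply(scenarios, function(sc) {
    stopifnot(inherits(sc, "scenario"))
    req <- if (is.null(s_min)) sc$s_min else s_min
    res <- smart_sensor_selection(sc$monitoring, req, sc$segment,
                                  sc$collector, mode = mode, seed = seed)
    if (!res$feasible) {
      stop("site '", sc$name, "' cannot meet its readout requirement at ",
           "any sensor count", call. = FALSE)
    }
    res$n
  }, integer(1))
  names(minima) <- vapply(scenarios, `[[`, character(1), "name")
  list(n = max(minima), per_site = minima)
}

#' Write a case-study report to disk
#'
#' Writes the readout curve as CSV (columns `n`, `p_s`, `s`, `s_floor`)
#' and/or a summary JSON. Output is bit-stable for fixed inputs and seed;
#' the JSON carries a `timestamp` field that is the only run-dependent
#' element.
#'
#' @param report A [run_case_study()] result.
#' @param dir Output directory (created if missing).
#' @param format `"csv"`, `"json"`, or both.
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  stopifnot(inherits(report, "case_study_report"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, report$scenario$name)
  paths <- character()
  if ("csv" %in% format) {
    csv_path <- paste0(base, "_curve.csv")
    write_curve_csv(report$curve, csv_path)
    paths <- c(paths, csv_path)
  }
  if ("json" %in% format) {
    json_path <- paste0(base, "_summary.json")
    summary <- list(
      scenario = scenario_to_list(report$scenario),
      mode = report$mode,
      seed = report$seed,
      path_length_cm = report$l,
      pass_probability = report$p_c,
      optimal_n = report$optimal_n,
      max_readouts_floor = report$max_s_floor,
      feasible_range = if (report$feasible$empty) NULL else
        list(n_min = report$feasible$n_min, n_max = report$feasible$n_max),
      feasible = !report$feasible$empty,
      selected_n = report$sss$n,
      selected_readouts = report$sss$s,
      physiology_violations = report$physiology$violations,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, json_path)
  }
  invisible(paths)
}
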