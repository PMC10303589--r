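#' Physiological parameters of the monitored circulation
#'
#' Describes one effective loop of the circulatory system as seen by a
#' drifting in-body sensor. Two parameterizations are supported:
#'
#' * **velocity mode** — the blood velocity `v(t)` is drawn uniformly from
#'   `[v_min, v_max]` (cm/s) at each 1-second step;
#' * **flow mode** — the volumetric flow `Q(t)` (mL/s) and vessel radius
#'   `r(t)` (cm) are drawn uniformly from their bounds and the velocity is
#'   derived as `Q / (pi * r^2)`.
#'
#' Exactly one parameterization is active per object.
#'
#' @param t_c Circulation time in seconds (positive integer; the number of
#'   1-second transport steps in one loop).
#' @param v_min,v_max Blood velocity bounds in cm/s (velocity mode).
#' @param q_min,q_max Volumetric flow bounds in mL/s (flow mode).
#' @param r_min,r_max Vessel radius bounds in cm (flow mode).
#' @return An object of class `body_segment` with fields `t_c`, `mode`, and
#'   the bounds of the active parameterization.
#' @examples
#' body_segment(t_c = 50, v_min = 1.5, v_max = 19)
#' body_segment(t_c = 60, q_min = 60, q_max = 100, r_min = 0.8, r_max = 1.2)
#' @export
body_segment <- function(t_c, v_min = NULL, v_max = NULL,
                         q_min = NULL, q_max = NULL,
                         r_min = NULL, r_max = NULL) {
  stopifnot(is.numeric(t_c), length(t_c) == 1L, is.finite(t_c))
  if (t_c <= 0 || t_c != round(t_c)) {
    stop("`t_c` must be a positive whole number of seconds", call. = FALSE)
  }
  velocity_given <- !is.null(v_min) || !is.null(v_max)
  flow_given <- !is.null(q_min) || !is.null(q_max) ||
    !is.null(r_min) || !is.null(r_max)
  if (velocity_given && flow_given) {
    stop("supply either velocity bounds or flow/radius bounds, not both",
         call. = FALSE)
  }
  if (velocity_given) {
    check_bounds(v_min, v_max, "v")
    out <- list(t_c = as.integer(t_c), mode = "velocity",
                v_min = v_min, v_max = v_max)
  } else if (flow_given) {
    check_bounds(q_min, q_max, "q")
    check_bounds(r_min, r_max, "r")
    out <- list(t_c = as.integer(t_c), mode = "flow",
                q_min = q_min, q_max = q_max,
                r_min = r_min, r_max = r_max)
  } else {
    stop("one of the velocity or flow/radius parameterizations is required",
         call. = FALSE)
  }
  structure(out, class = "body_segment")
}

check_bounds <- function(lo, hi, what) {
  if (is.null(lo) || is.null(hi)) {
    stop(sprintf("both `%s_min` and `%s_max` are required", what, what),
         call. = FALSE)
  }
  stopifnot(is.numeric(lo), is.numeric(hi),
            length(lo) == 1L, length(hi) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || lo > hi) {
    stop(sprintf("need 0 < %s_min <= %s_max", what, what), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.body_segment <- function(x, ...) {
  cat("<body_segment> t_c =", x$t_c, "s, mode =", x$mode, "\n")
  if (x$mode == "velocity") {
    cat("  v in [", x$v_min, ",", x$v_max, "] cm/s\n")
  } else {
    cat("  Q in [", x$q_min, ",", x$q_max, "] mL/s;",
        "r in [", x$r_min, ",", x$r_max, "] cm\n")
  }
  invisible(x)
}

#' Blood velocity from volumetric flow
#'
#' Converts volumetric flow through a vessel of radius `r` into linear
#' velocity, `v = Q / (pi * r^2)`. A sensor suspended in the blood moves at
#' this velocity.
#'
#' @param q Volumetric flow in mL/s; positive.
#' @param r Vessel radius in cm; positive. Vectorized with `q`.
#' @return Velocity in cm/s.
#' @examples
#' velocity_from_flow(pi, 1)   # 1 cm/s
#' velocity_from_flow(10, 1)   # 10/pi
#' @export
velocity_from_flow <- function(q, r) {
  if (!is.numeric(q) || !is.numeric(r) || any(!is.finite(q)) ||
      any(!is.finite(r)) || any(q <= 0) || any(r <= 0)) {
    stop("`q` and `r` must be positive and finite", call. = FALSE)
  }
  q / (pi * r^2)
}

#' Draw a per-second velocity trajectory over one circulation
#'
#' Samples the sensor velocity at each 1-second step of one circulation
#' loop. In velocity mode each `v(i)` is uniform on `[v_min, v_max]`; in
#' flow mode `r(i)` and `Q(i)` are drawn uniformly from their bounds and
#' `v(i) = Q(i) / (pi * r(i)^2)`.
#'
#' @param params A [body_segment()].
#' @param seed Integer RNG seed; the same seed reproduces the same series.
#' @return An object of class `velocity_series`: numeric vector of length
#'   `t_c` (cm/s) with attributes `seed` and `mode`.
#' @export
sample_velocity_series <- function(params, seed = NULL) {
  stopifnot(inherits(params, "body_segment"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  v <- if (params$mode == "velocity") {
    stats::runif(params$t_c, params$v_min, params$v_max)
  } else {
    r <- stats::runif(params$t_c, params$r_min, params$r_max)
    q <- stats::runif(params$t_c, params$q_min, params$q_max)
    velocity_from_flow(q, r)
  }
  structure(v, class = "velocity_series", seed = seed, mode = params$mode)
}

#' Circulation path length from a velocity trajectory
#'
#' Accumulates the per-second velocities into the length of the effective
#' circulation loop: `L = sum(v(i)) * dt` with `dt = 1` s (a left Riemann
#' sum of the velocity over one circulation time).
#'
#' @param series A [sample_velocity_series()] result, or any numeric vector
#'   of per-second velocities in cm/s.
#' @return Path length in cm.
#' @export
path_length <- function(series) {
  v <- unclass(series)
  if (!is.numeric(v) || length(v) == 0L) {
    stop("`series` must be a non-empty numeric velocity series",
         call. = FALSE)
  }
  sum(v)
}

#' Expected circulation path length
#'
#' Deterministic counterpart of [path_length()]: with velocities uniform on
#' `[v_min, v_max]`, the expected loop length is the mean velocity times the
#' circulation time, `L = (v_min + v_max) / 2 * t_c`. This expectation mode
#' is the default for design computations; the stochastic mode is retained
#' for Monte Carlo studies.
#'
#' @param params A [body_segment()] in velocity mode. Flow mode has no
#'   closed-form mean velocity here (the mean of `Q/(pi r^2)` under
#'   independent uniforms is not the ratio of means); use sampling instead.
#' @return Expected path length in cm.
#' @examples
#' expected_path_length(body_segment(50, v_min = 1.5, v_max = 19))  # 512.5
#' @export
expected_path_length <- function(params) {
  stopifnot(inherits(params, "body_segment"))
  if (params$mode != "velocity") {
    stop("expected path length requires velocity-mode parameters; ",
         "use sample_velocity_series() for flow mode", call. = FALSE)
  }
  (params$v_min + params$v_max) / 2 * params$t_c
}

# Physiological plausibility bounds: circulation time 45-60 s, vessel
# radius 4 um (capillary) to 12.5 mm (aorta), and monitoring much longer
# than one circulation (>= 10 loops).
T_C_BOUNDS <- c(45, 60)          # s
RADIUS_BOUNDS <- c(4e-4, 1.25)   # cm
MONITORING_MIN_LOOPS <- 10

#' Check a scenario against physiological constraints
#'
#' Flags parameter values outside the physiologically typical envelope:
#' circulation time outside 45--60 s (warning severity), vessel radii
#' outside 4 um -- 12.5 mm (error severity), and monitoring shorter than 10
#' circulation loops, violating the requirement that monitoring time far
#' exceed the circulation time (warning severity). A report is always
#' returned; out-of-range circulation time is only a warning so that
#' pathological cases remain explorable.
#'
#' @param params A [body_segment()].
#' @param monitoring A [monitoring_spec()], or `NULL` to skip the
#'   monitoring-duration check.
#' @return An object of class `physiology_report`: a data frame with one
#'   row per violation and columns `parameter`, `value`, `bound`,
#'   `severity`. Zero rows means all constraints hold.
#' @export
validate_physiology <- function(params, monitoring = NULL) {
  stopifnot(inherits(params, "body_segment"))
  rows <- list()
  add <- function(parameter, value, bound, severity) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, value = value, bound = bound,
      severity = severity, stringsAsFactors = FALSE)
  }
  if (params$t_c < T_C_BOUNDS[1] || params$t_c > T_C_BOUNDS[2]) {
    add("t_c", params$t_c,
        sprintf("[%g, %g] s", T_C_BOUNDS[1], T_C_BOUNDS[2]), "warning")
  }
  if (params$mode == "flow") {
    for (nm in c("r_min", "r_max")) {
      r <- params[[nm]]
      if (r < RADIUS_BOUNDS[1] || r > RADIUS_BOUNDS[2]) {
        add(nm, r, sprintf("[%g, %g] cm", RADIUS_BOUNDS[1], RADIUS_BOUNDS[2]),
            "error")
      }
    }
  }
  if (!is.null(monitoring)) {
    stopifnot(inherits(monitoring, "monitoring_spec"))
    dur_s <- monitoring$duration_minutes * 60
    if (dur_s < MONITORING_MIN_LOOPS * params$t_c) {
      add("monitoring_duration", dur_s,
          sprintf(">= %d * t_c = %g s",
                  MONITORING_MIN_LOOPS, MONITORING_MIN_LOOPS * params$t_c),
          "warning")
    }
  }
  violations <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(parameter = character(), value = numeric(),
               bound = character(), severity = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(violations = violations), class = "physiology_report")
}

#' @export
print.physiology_report <- function(x, ...) {
  if (nrow(x$violations) == 0L) {
    cat("<physiology_report> all constraints satisfied\n")
  } else {
    cat("<physiology_report>", nrow(x$violations), "violation(s):\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
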