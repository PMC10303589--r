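#' Wearable data-collector geometry
#'
#' @param w Collector length in cm; positive. The collector covers a window
#'   of length `w` of the circulation loop at the monitored site.
#' @param site Free-text site label (e.g. "elbow", "knee", "shin", "heel").
#' @return An object of class `collector_spec`.
#' @export
collector_spec <- function(w, site = "") {
  stopifnot(is.numeric(w), length(w) == 1L)
  if (!is.finite(w) || w <= 0) {
    stop("collector length `w` must be positive", call. = FALSE)
  }
  structure(list(w = w, site = as.character(site)), class = "collector_spec")
}

#' Monitoring-session specification
#'
#' @param duration_minutes Monitoring time in minutes; positive.
#' @param opportunity_rate Transmission opportunities per second. The default
#'   of one opportunity per second makes the total opportunity count equal
#'   to the monitoring time in seconds.
#' @return An object of class `monitoring_spec`.
#' @export
monitoring_spec <- function(duration_minutes, opportunity_rate = 1) {
  stopifnot(is.numeric(duration_minutes), length(duration_minutes) == 1L,
            is.numeric(opportunity_rate), length(opportunity_rate) == 1L)
  if (!is.finite(duration_minutes) || duration_minutes <= 0) {
    stop("`duration_minutes` must be positive", call. = FALSE)
  }
  if (!is.finite(opportunity_rate) || opportunity_rate <= 0) {
    stop("`opportunity_rate` must be positive", call. = FALSE)
  }
  structure(list(duration_minutes = duration_minutes,
                 opportunity_rate = opportunity_rate),
            class = "monitoring_spec")
}

#' Total transmission opportunities in a monitoring session
#' @param monitoring A [monitoring_spec()].
#' @return Number of transmission opportunities (duration in seconds times
#'   the opportunity rate).
#' @export
n_opportunities <- function(monitoring) {
  stopifnot(inherits(monitoring, "monitoring_spec"))
  monitoring$duration_minutes * 60 * monitoring$opportunity_rate
}

#' Pass probability: chance a sensor is in the collector window
#'
#' In each circulation loop a sensor spends `w / L` of its path inside the
#' collector window, so at any transmission opportunity it is in range with
#' probability `P_C = w / L`.
#'
#' @param collector A [collector_spec()], or a single positive number taken
#'   as the collector length in cm.
#' @param l Circulation path length in cm; must exceed the collector length
#'   (otherwise the probability would reach 1 and the geometry is
#'   infeasible).
#' @return Pass probability, strictly in (0, 1).
#' @export
pass_probability <- function(collector, l) {
  w <- if (inherits(collector, "collector_spec")) collector$w else collector
  stopifnot(is.numeric(w), length(w) == 1L, is.numeric(l), length(l) == 1L)
  if (!is.finite(w) || w <= 0) {
    stop("collector length must be positive", call. = FALSE)
  }
  if (!is.finite(l) || l <= w) {
    stop(sprintf(paste0("infeasible geometry: collector length (%g cm) must ",
                        "be smaller than the circulation path length (%g cm)"),
                 w, l), call. = FALSE)
  }
  w / l
}

#' Per-sensor success probability under collisions
#'
#' A readout succeeds when one given sensor is in the collector window and
#' none of the other `n - 1` sensors is (two simultaneous transmitters
#' collide and neither is received): `P_S = P_C * (1 - P_C)^(n-1)`.
#'
#' @param p_c Pass probability, strictly in (0, 1).
#' @param n Sensor count, integer >= 1. Vectorized.
#' @return Success probability in (0, 1).
#' @export
success_probability <- function(p_c, n) {
  check_pc(p_c)
  if (!is.numeric(n) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be a whole number >= 1", call. = FALSE)
  }
  p_c * (1 - p_c)^(n - 1)
}

check_pc <- function(p_c) {
  if (!is.numeric(p_c) || length(p_c) != 1L || !is.finite(p_c) ||
      p_c <= 0 || p_c >= 1) {
    stop("`p_c` must be a probability strictly in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected readouts from n sensors over a monitoring session
#'
#' Each of the `n` sensors succeeds at each transmission opportunity with
#' probability `P_S = P_C (1-P_C)^(n-1)`, so the expected total is
#' `S = n * P_S * K` where `K` is the number of opportunities in the
#' session. Reported counts are `floor(S)`; feasibility comparisons use the
#' unfloored value.
#'
#' @inheritParams success_probability
#' @param monitoring A [monitoring_spec()].
#' @return A list with `s` (real expected readouts) and `s_floor` (integer
#'   reported count). Vectorized over `n`.
#' @export
expected_readouts <- function(p_c, n, monitoring) {
  p_s <- success_probability(p_c, n)
  s <- n * p_s * n_opportunities(monitoring)
  list(s = s, s_floor = as.integer(floor(s)))
}

#' Expected-readout curve over sensor counts
#'
#' Evaluates the design surface `S(n)` for `n = 1..n_max`. The curve rises
#' to a single peak (adding sensors adds transmitters) and then falls
#' (collisions dominate), so it is unimodal in `n`.
#'
#' @inheritParams expected_readouts
#' @param n_max Largest sensor count to evaluate, >= 1.
#' @return A `readout_curve`: data frame with columns `n`, `p_c`, `p_s`,
#'   `s`, `s_floor`.
#' @export
readout_curve <- function(p_c, n_max, monitoring) {
  check_pc(p_c)
  stopifnot(is.numeric(n_max), length(n_max) == 1L, n_max >= 1)
  n <- seq_len(n_max)
  er <- expected_readouts(p_c, n, monitoring)
  structure(
    data.frame(n = n, p_c = p_c, p_s = success_probability(p_c, n),
               s = er$s, s_floor = er$s_floor),
    class = c("readout_curve", "data.frame"))
}

#' Sensor count maximizing expected readouts
#'
#' The ratio `S(n+1)/S(n) = ((n+1)/n) (1-P_C)` crosses 1 exactly once, so
#' `S(n)` is unimodal with integer argmax `floor(1/P_C)`. When
#' `(1-P_C)/P_C` is an integer the two adjacent counts tie exactly and the
#' larger one is returned. The closed form is evaluated with a
#' neighbour check so a `1/P_C` that is integral up to floating-point
#' rounding (e.g. `P_C = 15/540`) cannot be floored to the wrong side.
#'
#' @inheritParams success_probability
#' @return Integer sensor count >= 1.
#' @export
optimal_sensor_count <- function(p_c) {
  check_pc(p_c)
  f <- function(n) n * p_c * (1 - p_c)^(n - 1)
  n0 <- max(1, floor(1 / p_c))
  cand <- unique(pmax(1, c(n0 - 1, n0, n0 + 1)))
  vals <- f(cand)
  # ties break to the larger n: last candidate within rounding of the max
  best <- cand[max(which(vals >= max(vals) * (1 - 1e-12)))]
  as.integer(best)
}

#' Feasible sensor-count range for a readout requirement
#'
#' By unimodality of `S(n)`, the set of sensor counts with
#' `S(n) >= s_min` is a contiguous interval. The lower edge is found by
#' scanning up from `n = 1` to the peak; the upper edge by scanning past
#' the peak until `S` drops below the requirement. Feasibility is tested on
#' the unfloored `S`.
#'
#' @inheritParams expected_readouts
#' @param s_min Required readouts, >= 1.
#' @param n_cap Search bound on the sensor count (default 100000); an
#'   unresolved upper edge past `n_cap` is an error.
#' @return A `feasible_range`: list with `n_min`, `n_max`, `empty`,
#'   `s_min`.
#' @export
feasible_sensor_range <- function(p_c, s_min, monitoring, n_cap = 1e5) {
  check_pc(p_c)
  stopifnot(is.numeric(s_min), length(s_min) == 1L, s_min >= 1)
  opp <- n_opportunities(monitoring)
  s_of <- function(n) n * p_c * (1 - p_c)^(n - 1) * opp
  peak <- optimal_sensor_count(p_c)
  if (s_of(peak) < s_min) {
    return(structure(list(n_min = NA_integer_, n_max = NA_integer_,
                          empty = TRUE, s_min = s_min),
                     class = "feasible_range"))
  }
  n_min <- 1L
  while (s_of(n_min) < s_min) n_min <- n_min + 1L  # bounded by the peak
  n_max <- as.integer(peak)
  repeat {
    if (n_max + 1L > n_cap) {
      stop("feasible-range search exceeded `n_cap` without closing the ",
           "upper edge", call. = FALSE)
    }
    if (s_of(n_max + 1L) < s_min) break
    n_max <- n_max + 1L
  }
  structure(list(n_min = as.integer(n_min), n_max = n_max, empty = FALSE,
                 s_min = s_min),
            class = "feasible_range")
}

#' @export
print.feasible_range <- function(x, ...) {
  if (x$empty) {
    cat("<feasible_range> empty: no sensor count reaches s_min =",
        x$s_min, "\n")
  } else {
    cat("<feasible_range> [", x$n_min, ",", x$n_max, "] for s_min =",
        x$s_min, "\n")
  }
  invisible(x)
}

#' Write a readout curve as CSV
#'
#' @param curve A [readout_curve()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "readout_curve"))
  utils::write.csv(curve[, c("n", "p_s", "s", "s_floor")], path,
                   row.names = FALSE)
  invisible(path)
}
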