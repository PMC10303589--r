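#' Smart sensor selection: minimum deployment meeting a readout budget
#'
#' Incremental search for the smallest sensor count whose expected readouts
#' over the monitoring session reach `s_min`. The circulation path length is
#' taken either at the mean velocity (expectation mode, the default for
#' design, which is deterministic) or from one seeded per-second velocity
#' draw (stochastic mode). From the path length the pass probability
#' `P_C = w/L` follows; the search then increments the candidate count `m`
#' from 1, updating the success probability and the collected readouts,
#' and stops at the first `m` whose expected readouts meet the requirement.
#'
#' Because `S(n)` is unimodal with its peak at `floor(1/P_C)`, a requirement
#' still unmet at the peak can never be met: the search then terminates with
#' `feasible = FALSE` instead of looping forever.
#'
#' @param monitoring A [monitoring_spec()].
#' @param s_min Required readouts, >= 1.
#' @param params A [body_segment()].
#' @param collector A [collector_spec()].
#' @param mode `"expectation"` (mean-velocity path length) or
#'   `"stochastic"` (one seeded velocity-series draw).
#' @param seed RNG seed for stochastic mode.
#' @return An `sss_result`: list with `n` (selected count, `NA` if
#'   infeasible), `s` (floored readouts at `n`), `s_real`, `l` (path length
#'   used, cm), `p_c`, `feasible`, `evaluations` (candidate counts tested),
#'   and `mode`.
#' @examples
#' elbow <- body_segment(50, v_min = 1.5, v_max = 19)
#' smart_sensor_selection(monitoring_spec(10), s_min = 100,
#'                        params = elbow, collector = collector_spec(20))
#' @export
smart_sensor_selection <- function(monitoring, s_min, params, collector,
                                   mode = c("expectation", "stochastic"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(monitoring, "monitoring_spec"),
            inherits(params, "body_segment"),
            inherits(collector, "collector_spec"),
            is.numeric(s_min), length(s_min) == 1L, s_min >= 1)
  l <- if (mode == "expectation") {
    expected_path_length(params)
  } else {
    path_length(sample_velocity_series(params, seed = seed))
  }
  p_c <- pass_probability(collector, l)
  opp <- n_opportunities(monitoring)
  peak <- optimal_sensor_count(p_c)

  p_s <- 0
  x <- 0
  m <- 1L
  evaluations <- 0L
  feasible <- FALSE
  repeat {
    p_s <- success_probability(p_c, m)
    x <- m * p_s * opp
    evaluations <- evaluations + 1L
    if (x >= s_min) {
      feasible <- TRUE
      break
    }
    if (m >= peak) break  # past the peak S only decreases
    m <- m + 1L
  }

  structure(list(
    n = if (feasible) m else NA_integer_,
    s = if (feasible) as.integer(floor(x)) else NA_integer_,
    s_real = if (feasible) x else NA_real_,
    l = l, p_c = p_c, feasible = feasible,
    evaluations = evaluations, mode = mode, s_min = s_min,
    seed = if (mode == "stochastic") seed else NULL
  ), class = "sss_result")
}

#' @export
print.sss_result <- function(x, ...) {
  cat("<sss_result>", x$mode, "mode; L =", format(x$l), "cm; P_C =",
      format(x$p_c), "\n")
  if (x$feasible) {
    cat("  n =", x$n, "sensors ->", x$s, "readouts (>=", x$s_min, ")\n")
  } else {
    cat("  infeasible: requirement of", x$s_min,
        "readouts unreachable at any sensor count\n")
  }
  invisible(x)
}
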