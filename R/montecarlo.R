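#' Simulate one monitoring session at the mechanism level
#'
#' Discrete-event oracle for the collision model behind the analytic
#' expectation: at each transmission opportunity every sensor is
#' independently inside the collector window with probability `p_c` and
#' transmits if so; a readout is collected iff exactly one sensor transmits
#' (two or more collide, zero means silence). Deterministic for a fixed
#' seed.
#'
#' @param n Sensor count, >= 1.
#' @param p_c Pass probability, strictly in (0, 1).
#' @param opportunities Number of transmission opportunities, >= 1.
#' @param seed Integer RNG seed.
#' @return Integer total readouts in `[0, opportunities]`.
#' @export
simulate_monitoring <- function(n, p_c, opportunities, seed = NULL) {
  check_pc(p_c)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            is.numeric(opportunities), length(opportunities) == 1L,
            opportunities >= 1, opportunities == round(opportunities))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  # per-sensor in-window indicators, chunked over opportunities to bound
  # memory for large sessions
  chunk <- max(1L, as.integer(1e6 %/% n))
  total <- 0L
  left <- as.integer(opportunities)
  while (left > 0L) {
    k <- min(chunk, left)
    transmitters <- colSums(matrix(stats::runif(n * k) < p_c, nrow = n))
    total <- total + sum(transmitters == 1L)
    left <- left - k
  }
  as.integer(total)
}

#' Replicated Monte Carlo monitoring sessions
#'
#' Runs [simulate_monitoring()] over independent replicates. Replicate `r`
#' uses seed `seed + r`, so each replicate is reproducible in isolation and
#' the set is reproducible as a whole.
#'
#' @inheritParams simulate_monitoring
#' @param replicates Number of independent sessions, >= 2.
#' @param seed Base RNG seed.
#' @return A `simulation_result`: list with `replicate_counts`, `mean`,
#'   `sd`, and the configuration echo (`n`, `p_c`, `opportunities`,
#'   `replicates`, `seed`).
#' @export
simulate_replicates <- function(n, p_c, opportunities, replicates,
                                seed = 1L) {
  stopifnot(is.numeric(replicates), length(replicates) == 1L,
            replicates >= 2)
  counts <- vapply(seq_len(replicates), function(r) {
    simulate_monitoring(n, p_c, opportunities, seed = seed + r)
  }, integer(1))
  structure(list(
    replicate_counts = counts,
    mean = mean(counts),
    sd = stats::sd(counts),
    n = n, p_c = p_c, opportunities = opportunities,
    replicates = as.integer(replicates), seed = seed
  ), class = "simulation_result")
}

#' Compare a simulation to the analytic expectation
#'
#' Tests the simulated mean readout count against the analytic expectation
#' `n * p_c * (1 - p_c)^(n-1) * opportunities` with a z-score on the
#' standard error of the replicate mean; agreement is declared at
#' `|z| <= 3`. Zero replicate variance with a nonzero discrepancy is
#' reported as a failure (infinite z).
#'
#' @param result A [simulate_replicates()] result.
#' @return A list with `analytic` (expected mean), `empirical` (simulated
#'   mean), `z`, and `pass` (logical, `|z| <= 3`).
#' @export
compare_to_analytic <- function(result) {
  stopifnot(inherits(result, "simulation_result"),
            result$replicates >= 2)
  analytic <- result$n * result$p_c * (1 - result$p_c)^(result$n - 1) *
    result$opportunities
  se <- result$sd / sqrt(result$replicates)
  z <- if (se == 0) {
    if (result$mean == analytic) 0 else Inf
  } else {
    (result$mean - analytic) / se
  }
  list(analytic = analytic, empirical = result$mean, z = z,
       pass = is.finite(z) && abs(z) <= 3)
}
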