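# Shared fixtures: the monitored segments and collectors used across tests.

elbow_segment <- function() body_segment(50, v_min = 1.5, v_max = 19)
leg_segment <- function() body_segment(60, v_min = 3, v_max = 15)

tm10 <- function() monitoring_spec(10)

# pass probabilities in expectation mode (mean velocity path lengths)
elbow_pc <- function() 20 / expected_path_length(elbow_segment())   # 20/512.5
knee_pc <- function() 15 / expected_path_length(leg_segment())      # 15/540
shin_pc <- function() 50 / expected_path_length(leg_segment())      # 50/540
heel_pc <- function() 10 / expected_path_length(leg_segment())      # 10/540

# a valid scenario config as a plain list, for malformation tests
scenario_fixture_list <- function() {
  list(name = "fixture",
       segment = list(t_c = 50, v_min = 1.5, v_max = 19),
       collector = list(w = 20, site = "elbow"),
       monitoring = list(duration_minutes = 10, opportunity_rate = 1),
       s_min = 100)
}

# brute-force expected-readout evaluation, independent of the package's
# vectorised path: plain loop product for (1-p)^(n-1)
brute_expected_s <- function(p_c, n, opportunities) {
  q <- 1
  if (n > 1) for (i in seq_len(n - 1)) q <- q * (1 - p_c)
  n * p_c * q * opportunities
}

# exhaustive enumeration of the argmax over n (independent of the
# closed-form floor(1/p) route the package uses)
brute_argmax <- function(p_c, n_max = 2000) {
  n <- seq_len(n_max)
  vals <- n * p_c * (1 - p_c)^(n - 1)
  best <- max(vals)
  max(which(vals >= best * (1 - 1e-12)))  # ties to the larger n
}
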