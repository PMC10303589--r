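test_that("velocity_from_flow implements v = Q / (pi r^2)", {
  expect_equal(velocity_from_flow(pi, 1), 1)
  expect_equal(velocity_from_flow(10, 1), 10 / pi)
  expect_equal(velocity_from_flow(1, 0.5), 1 / (pi * 0.25))
  expect_error(velocity_from_flow(-1, 1), "positive")
  expect_error(velocity_from_flow(1, 0), "positive")
})

test_that("velocity_from_flow is monotone in flow and radius", {
  q <- seq(0.5, 10, length.out = 20)
  expect_true(all(diff(velocity_from_flow(q, 0.7)) > 0))
  r <- seq(0.1, 1.2, length.out = 20)
  expect_true(all(diff(velocity_from_flow(5, r)) < 0))
})

test_that("body_segment enforces its invariants", {
  expect_error(body_segment(0, v_min = 1, v_max = 2), "positive")
  expect_error(body_segment(50.5, v_min = 1, v_max = 2), "whole")
  expect_error(body_segment(50, v_min = 3, v_max = 2), "v_min")
  expect_error(body_segment(50, v_min = 0, v_max = 2), "v_min")
  expect_error(body_segment(50), "parameterization")
  expect_error(body_segment(50, v_min = 1, v_max = 2, q_min = 1, q_max = 2,
                            r_min = 0.1, r_max = 0.2), "not both")
  expect_error(body_segment(50, q_min = 1, q_max = 2), "r_min")
})

test_that("sampled velocity series respect bounds, length, and seed", {
  elbow <- elbow_segment()
  s1 <- sample_velocity_series(elbow, seed = 42)
  expect_length(unclass(s1), 50)
  expect_true(all(s1 >= 1.5 & s1 <= 19))
  s2 <- sample_velocity_series(elbow, seed = 42)
  expect_identical(unclass(s1), unclass(s2))
  expect_false(identical(unclass(s1),
                         unclass(sample_velocity_series(elbow, seed = 43))))

  degen <- body_segment(5, v_min = 10, v_max = 10)
  expect_equal(as.numeric(sample_velocity_series(degen, seed = 1)),
               rep(10, 5))
})

test_that("flow-mode series are consistent with the flow/radius bounds", {
  seg <- body_segment(50, q_min = 50, q_max = 90, r_min = 0.8, r_max = 1.2)
  s <- sample_velocity_series(seg, seed = 11)
  expect_length(unclass(s), 50)
  v_lo <- velocity_from_flow(50, 1.2)  # slowest: min flow, widest vessel
  v_hi <- velocity_from_flow(90, 0.8)  # fastest: max flow, narrowest vessel
  expect_true(all(s >= v_lo & s <= v_hi))
})

test_that("path_length is the 1-second Riemann sum of the series", {
  expect_equal(path_length(rep(10, 5)), 50)
  expect_equal(path_length(c(1, 2, 3)), 6)
  expect_error(path_length(numeric(0)), "non-empty")
})

test_that("expected_path_length matches mean velocity times t_c", {
  expect_equal(expected_path_length(elbow_segment()), 10.25 * 50)
  expect_equal(expected_path_length(leg_segment()), 9 * 60)
  degen <- body_segment(7, v_min = 4, v_max = 4)
  expect_equal(expected_path_length(degen), 28)
  flow <- body_segment(50, q_min = 1, q_max = 2, r_min = 0.1, r_max = 0.2)
  expect_error(expected_path_length(flow), "velocity-mode")
})

test_that("constant-velocity path length equals the expectation exactly", {
  for (v in c(2, 9, 15)) {
    seg <- body_segment(60, v_min = v, v_max = v)
    s <- sample_velocity_series(seg, seed = 3)
    expect_equal(path_length(s), expected_path_length(seg))
  }
})

test_that("mean sampled path length converges to the expectation", {
  elbow <- elbow_segment()
  ls <- vapply(seq_len(1000), function(r) {
    path_length(sample_velocity_series(elbow, seed = 1000 + r))
  }, numeric(1))
  se <- sd(ls) / sqrt(length(ls))
  expect_lt(abs(mean(ls) - expected_path_length(elbow)), 3 * se)
})

test_that("physiology checks flag the stated bounds at the right severity", {
  ok <- validate_physiology(elbow_segment(), monitoring_spec(10))
  expect_s3_class(ok, "physiology_report")
  expect_equal(nrow(ok$violations), 0)

  fast <- validate_physiology(body_segment(30, v_min = 1, v_max = 2))
  expect_equal(fast$violations$parameter, "t_c")
  expect_equal(fast$violations$severity, "warning")

  wide <- validate_physiology(
    body_segment(50, q_min = 1, q_max = 2, r_min = 0.1, r_max = 2))
  expect_true("r_max" %in% wide$violations$parameter)
  expect_equal(wide$violations$severity[wide$violations$parameter == "r_max"],
               "error")

  short <- validate_physiology(elbow_segment(), monitoring_spec(5))
  expect_true("monitoring_duration" %in% short$violations$parameter)
  expect_equal(short$violations$severity, "warning")
})
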