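test_that("built-in scenarios carry the case-study settings", {
  scens <- builtin_scenarios()
  expect_length(scens, 7)
  base <- c("tennis_elbow", "runners_knee", "shin_splints",
            "heel_inflammation")
  expect_true(all(base %in% names(scens)))
  expect_true(all(paste0("shin_splints_tm", c(10, 12, 14)) %in%
                    names(scens)))

  elbow <- scens$tennis_elbow
  expect_equal(elbow$segment$t_c, 50L)
  expect_equal(c(elbow$segment$v_min, elbow$segment$v_max), c(1.5, 19))
  expect_equal(elbow$collector$w, 20)
  expect_equal(elbow$monitoring$duration_minutes, 10)
  expect_equal(elbow$s_min, 100)
  expect_equal(nrow(validate_physiology(elbow$segment,
                                        elbow$monitoring)$violations), 0)

  expect_equal(scens$heel_inflammation$collector$w, 10)
  expect_equal(scens$shin_splints$collector$w, 50)
  expect_equal(scens$runners_knee$collector$w, 15)
  expect_equal(scens$shin_splints_tm12$monitoring$duration_minutes, 12)
  expect_equal(scens$shin_splints_tm12$s_min, 250)

  # every bundled scenario respects monitoring >> circulation
  for (sc in scens) {
    expect_gte(sc$monitoring$duration_minutes * 60, 10 * sc$segment$t_c)
  }
})

test_that("scenario configs round-trip through YAML and JSON", {
  sc <- builtin_scenarios()$tennis_elbow
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(sc, path)
    back <- load_scenario(path)
    expect_equal(back, sc)
  }
  # flow-mode segments round-trip too
  fsc <- scenario("flow_case",
                  body_segment(50, q_min = 50, q_max = 90,
                               r_min = 0.8, r_max = 1.2),
                  collector_spec(20, "arm"), monitoring_spec(10), 100)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(fsc, path)
  expect_equal(load_scenario(path), fsc)
})

test_that("malformed configs fail with the offending field named", {
  sc <- scenario_fixture_list()
  path <- withr::local_tempfile(fileext = ".yaml")

  broken <- sc; broken$collector$w <- NULL
  yaml::write_yaml(broken, path)
  expect_error(load_scenario(path), "collector.w")

  broken <- sc; broken$segment$t_c <- -5
  yaml::write_yaml(broken, path)
  expect_error(load_scenario(path), "segment")

  broken <- sc; broken$monitoring <- NULL
  yaml::write_yaml(broken, path)
  expect_error(load_scenario(path), "monitoring")

  expect_error(load_scenario(file.path(tempdir(), "nope.yaml")),
               "not found")
})

test_that("the shipped example config loads and is analyzable", {
  path <- system.file("extdata", "wrist_tendonitis.yaml", package = "bsnkit")
  sc <- load_scenario(path)
  expect_equal(sc$collector$site, "wrist")
  report <- run_case_study(sc)
  expect_false(report$feasible$empty)
  expect_identical(report$sss$n, report$feasible$n_min)
})

test_that("case-study reports reproduce the reference design numbers", {
  scens <- builtin_scenarios()
  elbow <- run_case_study(scens$tennis_elbow)
  expect_equal(elbow$max_s_floor, 225L)
  expect_equal(elbow$optimal_n, 25L)
  expect_equal(c(elbow$feasible$n_min, elbow$feasible$n_max), c(6L, 71L))
  expect_equal(elbow$sss$n, 6L)

  shin <- run_case_study(scens$shin_splints)
  expect_equal(shin$max_s_floor, 231L)
  expect_equal(shin$optimal_n, 10L)

  tm12 <- run_case_study(scens$shin_splints_tm12)
  expect_equal(tm12$sss$n, 7L)
  expect_equal(tm12$curve$s_floor[7], 260L)

  # expectation-mode reports are seed-invariant
  expect_equal(run_case_study(scens$tennis_elbow, seed = 1)$curve,
               run_case_study(scens$tennis_elbow, seed = 999)$curve)
})

test_that("a shared pool sized for several sites takes the per-site maximum", {
  scens <- builtin_scenarios()
  trio <- scens[c("runners_knee", "shin_splints", "heel_inflammation")]
  res <- multi_site_minimum(trio, s_min = 100)
  expect_equal(unname(res$per_site), c(8L, 2L, 11L))
  expect_equal(res$n, 11L)
  # single site: the pool is that site's own minimum
  solo <- multi_site_minimum(scens["runners_knee"], s_min = 100)
  expect_equal(solo$n, 8L)
  # monotone: adding a site never shrinks the pool
  expect_gte(res$n, multi_site_minimum(trio[1:2], s_min = 100)$n)
  # an unattainable requirement names the offending site
  expect_error(multi_site_minimum(trio, s_min = 250), "runners_knee")
})

test_that("reports write complete, reproducible CSV and JSON", {
  report <- run_case_study(builtin_scenarios()$tennis_elbow)
  dir <- withr::local_tempdir()
  paths <- write_report(report, dir)
  csv <- read.csv(paths[1])
  expect_named(csv, c("n", "p_s", "s", "s_floor"))
  expect_equal(nrow(csv), nrow(report$curve))
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$optimal_n, 25)
  expect_equal(js$max_readouts_floor, 225)
  expect_equal(js$feasible_range$n_min, 6)
  expect_equal(js$selected_n, 6)
  # byte-identical on re-run apart from the timestamp line
  dir2 <- withr::local_tempdir()
  paths2 <- write_report(report, dir2)
  strip_ts <- function(p) grep("timestamp", readLines(p),
                               invert = TRUE, value = TRUE)
  expect_identical(strip_ts(paths2[2]), strip_ts(paths[2]))
  expect_identical(readLines(paths2[1]), readLines(paths[1]))
})
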