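test_that("the distance kernel interpolates between T0 and stationarity", {
  cfg <- sim_config(seed = 1)
  T0 <- cfg$base_transition
  near <- transition_matrix_at_distance(cfg, 1)
  expect_lt(max(abs(near - T0)), 0.01)
  far <- transition_matrix_at_distance(cfg, 1e7)
  expect_equal(unname(far[1, ]), unname(cfg$stationary), tolerance = 1e-9)
  expect_equal(unname(far[4, ]), unname(cfg$stationary), tolerance = 1e-9)
  expect_error(transition_matrix_at_distance(cfg, 0), "at least 1")

  set.seed(79)
  for (i in 1:100) {
    c2 <- sim_config(decay_length = runif(1, 10, 2000), seed = NULL)
    Td <- transition_matrix_at_distance(c2, runif(1, 1, 5000))
    expect_equal(unname(rowSums(Td)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(Td >= 0))
  }
})

test_that("the stationary vector is a fixed point of T0", {
  cfg <- sim_config()
  pi0 <- cfg$stationary
  expect_equal(unname(as.numeric(pi0 %*% cfg$base_transition)),
               unname(as.numeric(pi0)), tolerance = 1e-10)
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_sites = 500, seed = 7)
  a <- simulate_track(cfg)
  b <- simulate_track(cfg)
  expect_identical(a$track$position, b$track$position)
  expect_identical(a$track$mc_ratio, b$track$mc_ratio)
  expect_identical(a$truth$latent_state, b$truth$latent_state)

  pa <- tempfile(); pb <- tempfile()
  write_annotated_table(annotate_track(a$track), pa)
  write_annotated_table(annotate_track(b$track), pb)
  expect_identical(readLines(pa), readLines(pb))

  # different seeds diverge
  c2 <- simulate_track(sim_config(n_sites = 500, seed = 8))
  expect_false(identical(a$track$mc_ratio, c2$track$mc_ratio))
})

test_that("generated tracks satisfy the input contracts", {
  sim <- simulate_track(sim_config(n_sites = 2000, seed = 3))
  tr <- sim$track
  expect_s3_class(tr, "meth_track")
  expect_true(all(diff(tr$position) >= 2))
  expect_true(all(is.na(tr$mc_ratio) == (tr$coverage == 0)))
  ann <- annotate_track(tr)
  expect_true(all(ann$state[!is.na(ann$state)] %in% meth_states()))
  # round-trips through the io layer
  p <- tempfile()
  write_annotated_table(ann, p)
  expect_equal(nrow(read_methylation_table(p)), nrow(tr))
})

test_that("the noise-free limit recovers latent states almost surely", {
  cfg <- sim_config(n_sites = 10000, coverage_mean = 500,
                    zero_coverage_prob = 0, emission_margin = 0.05,
                    seed = 101)
  sim <- simulate_track(cfg)
  rep <- recovery_report(sim$track, sim$truth)
  expect_gte(rep$state_agreement, 99)
  # confusion concentrates on the diagonal
  conf <- rep$confusion[, meth_states()]
  expect_gte(sum(diag(conf)) / sum(conf), 0.99)
})

test_that("recovery degrades with coverage and improves with track size", {
  rep_at <- function(n, cov, seed) {
    cfg <- sim_config(n_sites = n, coverage_mean = cov,
                      zero_coverage_prob = 0, emission_margin = 0.02,
                      seed = seed)
    sim <- simulate_track(cfg)
    recovery_report(sim$track, sim$truth)
  }
  hi <- rep_at(4000, 200, 5)
  lo <- rep_at(4000, 5, 5)
  expect_gt(hi$state_agreement, lo$state_agreement)

  small <- rep_at(1000, 200, 9)
  big <- rep_at(20000, 200, 9)
  expect_lt(big$overall_max_abs_dev, small$overall_max_abs_dev)

  # truth compared with itself: zero deviation
  cfg <- sim_config(n_sites = 1000, seed = 11)
  sim <- simulate_track(cfg)
  latent <- sim$track
  ann <- annotate_track(latent)
  ann$state <- sim$truth$latent_state
  self <- recovery_report(ann, sim$truth)
  expect_equal(self$overall_max_abs_dev, 0)
  expect_equal(self$state_agreement, 100)

  expect_error(recovery_report(sim$track, sim$truth[-1, ]), "length")
})

test_that("config validation rejects malformed generative parameters", {
  expect_error(sim_config(n_sites = 0), "positive")
  expect_error(sim_config(spacing_mean = 1), "at least 2")
  expect_error(sim_config(decay_length = 0), "positive")
  expect_error(sim_config(emission_margin = 0.2), "0.125")
  bad_T <- matrix(1, 4, 4)
  expect_error(sim_config(base_transition = bad_T), "sum to 1")
})
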