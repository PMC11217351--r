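test_that("trajectories are bit-reproducible given the seed", {
  mask <- rep(c(TRUE, FALSE), 8)
  a <- hp1_simulate(mask, rate_params(), "control", duration = 40,
                    n_replicates = 2, seed = 7)
  b <- hp1_simulate(mask, rate_params(), "control", duration = 40,
                    n_replicates = 2, seed = 7)
  for (r in 1:2) {
    expect_identical(a$trajectories[[r]]$bound, b$trajectories[[r]]$bound)
    expect_identical(a$trajectories[[r]]$methylated,
                     b$trajectories[[r]]$methylated)
    expect_identical(a$trajectories[[r]]$contacts,
                     b$trajectories[[r]]$contacts)
  }
  # replicates use distinct streams
  expect_false(identical(a$trajectories[[1]]$bound,
                         a$trajectories[[2]]$bound))
})

test_that("event choice follows the categorical law (1:3 rates -> 3/4)", {
  # one naive site: first event is methylation (rate 1) or binding (rate 3)
  p <- rate_params(k_m = 1, k_d = 0, k_b = 3, k_u = 0, k_y = 0, k_n = 0,
                   k_c = 0, k_w = 0, k_z = 0)
  n_bind_first <- 0L
  n_trials <- 800L
  for (s in seq_len(n_trials)) {
    sim <- hp1_simulate(FALSE, p, "control", duration = 6,
                        n_replicates = 1, sample_interval = 0.02,
                        seed = 10000 + s)
    tr <- sim$trajectories[[1]]
    t_bind <- tr$times[which(tr$bound[, 1])[1]]
    t_meth <- tr$times[which(tr$methylated[, 1])[1]]
    if (!is.na(t_bind) && (is.na(t_meth) || t_bind < t_meth))
      n_bind_first <- n_bind_first + 1L
  }
  frac <- n_bind_first / n_trials
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n_trials))
})

test_that("binding/unbinding only reaches the closed-form occupancy", {
  p <- rate_params(k_m = 0, k_d = 0, k_b = 0.27, k_u = 0.034, k_y = 0,
                   k_n = 0, k_c = 0, k_w = 0, k_z = 0)
  sim <- hp1_simulate(rep(TRUE, 40), p, "control", duration = 1500,
                      n_replicates = 3, sample_interval = 1, seed = 5)
  occ <- probability_profile(sim, "hp1_binding", burn_in = 100)
  expect_equal(mean(occ), 0.27 / (0.27 + 0.034), tolerance = 0.02)
})

test_that("irreversible binding saturates and the absorbing state is held", {
  p <- rate_params(k_m = 0, k_d = 0, k_b = 0.27, k_u = 0, k_y = 0,
                   k_n = 0, k_c = 0, k_w = 0, k_z = 0)
  sim <- hp1_simulate(rep(FALSE, 20), p, "control", duration = 400,
                      n_replicates = 1, sample_interval = 1, seed = 9)
  tr <- sim$trajectories[[1]]
  expect_equal(length(tr$times), 401L)  # full horizon despite absorption
  expect_true(all(tr$bound[nrow(tr$bound), ]))
  # a totally frozen system still yields a full-length constant trajectory
  p0 <- rate_params(k_m = 0, k_d = 0, k_b = 0, k_u = 0, k_y = 0, k_n = 0,
                    k_c = 0, k_w = 0, k_z = 0)
  frozen <- hp1_simulate(rep(TRUE, 5), p0, "control", duration = 100,
                         n_replicates = 1, seed = 1)
  tr0 <- frozen$trajectories[[1]]
  expect_equal(length(tr0$times), 101L)
  expect_false(any(tr0$bound))
  expect_true(all(tr0$methylated))  # control start: binding sites methylated
})

test_that("TM trajectories never contain a methylated site", {
  sim <- hp1_simulate(rep(c(TRUE, FALSE, FALSE), 10), rate_params(), "TM",
                      duration = 120, n_replicates = 2, seed = 21)
  for (tr in sim$trajectories) expect_false(any(tr$methylated))
})

test_that("incremental caches equal from-scratch recomputation along runs", {
  # check_consistency rebuilds distances and propensity sums after every
  # event and stops on any mismatch
  for (fd in c("shortcut", "genomic")) {
    sim <- hp1_simulate(rep(c(TRUE, FALSE), 12),
                        rate_params(formation_distance = fd), "control",
                        duration = 120, n_replicates = 1, seed = 31,
                        check_consistency = TRUE)
    expect_gt(sim$trajectories[[1]]$n_steps, 100)
  }
})

test_that("state invariants hold across sampled snapshots", {
  sim <- hp1_simulate(rep(c(TRUE, FALSE), 15), rate_params(), "control",
                      duration = 150, n_replicates = 1, seed = 13)
  tr <- sim$trajectories[[1]]
  for (s in seq_along(tr$times)) {
    con <- tr$contacts[[s]]
    if (nrow(con)) {
      expect_true(all(con[, 1] < con[, 2]))
      deg <- tabulate(c(con[, 1], con[, 2]), nbins = 30)
      expect_true(all(deg <= rate_params()$n_val))
    }
  }
})

test_that("the bridging coupling protects a methylated block (control > TM)", {
  mask <- c(rep(TRUE, 20), rep(FALSE, 40))
  ctrl <- hp1_simulate(mask, rate_params(), "control", duration = 200,
                       n_replicates = 3, seed = 55)
  tm <- hp1_simulate(mask, rate_params(), "TM", duration = 200,
                     n_replicates = 3, seed = 56)
  occ_c <- probability_profile(ctrl, burn_in = 50)
  occ_t <- probability_profile(tm, burn_in = 50)
  expect_gt(mean(occ_c[mask]), mean(occ_t[mask]))
})
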