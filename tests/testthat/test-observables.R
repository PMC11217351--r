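test_that("probability profile is the time average of the indicator", {
  # a site bound for exactly half of the sampled time in every replicate
  times <- 0:9
  bound <- matrix(FALSE, 10, 3)
  bound[6:10, 1] <- TRUE                      # site 1: half the samples
  meth <- matrix(FALSE, 10, 3)
  trs <- list(fake_trajectory(times, meth, bound),
              fake_trajectory(times, meth, bound, replicate = 2L))
  prof <- probability_profile(trs, "hp1_binding")
  expect_equal(as.numeric(prof), c(0.5, 0, 0))
  expect_equal(as.numeric(probability_profile(trs, "methylation")),
               c(0, 0, 0))
})

test_that("burn-in restricts the averaging window", {
  times <- 0:4
  bound <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE), 5, 1)
  trs <- list(fake_trajectory(times, bound * FALSE, bound))
  expect_equal(as.numeric(probability_profile(trs, burn_in = 2)), 0)
  expect_equal(as.numeric(probability_profile(trs)), 0.4)
  expect_error(probability_profile(trs, burn_in = 10), "burn_in")
  expect_error(probability_profile(list()), "no trajectories")
})

test_that("least-squares rescaling recovers known factors", {
  sim <- c(0.1, 0.9, 0.4, 0.8, 0.05)
  expect_equal(rescale_experimental(sim, sim)$factor, 1)
  r <- rescale_experimental(59 * sim, sim)
  expect_equal(r$factor, 59)
  expect_equal(r$rescaled, sim)
  expect_equal(rescale_experimental(13 * sim, sim)$factor, 13)
  expect_error(rescale_experimental(rep(0, 5), sim), "all zero")
})

test_that("rescaling factor matches a dense grid-search oracle", {
  set.seed(3)
  for (t in 1:10) {
    ex <- runif(20, 0, 50)
    sim <- runif(20, 0, 1)
    cc <- rescale_experimental(ex, sim)$factor
    obj <- function(c) sum((ex / c - sim)^2)
    grid <- seq(cc * 0.5, cc * 1.5, length.out = 4001)
    c_grid <- grid[which.min(vapply(grid, obj, numeric(1)))]
    # refine around the grid optimum
    expect_lt(abs(cc - c_grid), diff(grid[1:2]) + 1e-6)
    expect_lte(obj(cc), obj(c_grid) + 1e-9)
  }
})

test_that("bound-locus calling is strictly greater-than the threshold", {
  expect_equal(predicted_bound_loci(c(0.49, 0.5, 0.51)),
               c(FALSE, FALSE, TRUE))
  expect_false(any(predicted_bound_loci(rep(0, 10))))
  expect_true(all(predicted_bound_loci(c(0.01, 0.99), threshold = 0)))
})

test_that("accuracy and permutation p-value behave at the extremes", {
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  res <- compare_to_peaks(mask, mask, n_shuffles = 200, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_lt(res$p_value, 0.2)
  # empty peaks: nothing to hit
  res0 <- compare_to_peaks(mask, rep(FALSE, 8), n_shuffles = 200, seed = 1)
  expect_equal(res0$accuracy, 0)
  expect_equal(res0$p_value, 1)
  expect_error(compare_to_peaks(rep(FALSE, 8), mask), "no predicted")
})

test_that("shuffled accuracy matches the hypergeometric null", {
  # 2 predicted loci on a 10-site lattice, peaks cover half the lattice:
  # E[shuffled accuracy] = 0.5; the p-value equals the exact tail mass
  predicted <- c(TRUE, FALSE, TRUE, rep(FALSE, 7))  # both loci on peaks
  peaks <- rep(c(TRUE, FALSE), 5)
  set.seed(4)
  sh <- replicate(4000, mean(peaks[sample.int(10, 2)]))
  expect_equal(mean(sh), 0.5, tolerance = 0.02)
  obs <- compare_to_peaks(predicted, peaks, n_shuffles = 4000, seed = 9)
  # observed accuracy: both loci in peaks -> exact null tail P(X = 2)
  p_exact <- choose(5, 2) / choose(10, 2)
  expect_equal(obs$accuracy, 1)
  expect_equal(obs$p_value, p_exact,
               tolerance = 3 * sqrt(p_exact * (1 - p_exact) / 4000) / p_exact)
})

test_that("balanced accuracy diagnostic is reported on request", {
  predicted <- c(TRUE, TRUE, FALSE, FALSE)
  peaks <- c(TRUE, FALSE, TRUE, FALSE)
  res <- compare_to_peaks(predicted, peaks, n_shuffles = 50, seed = 2,
                          balanced = TRUE)
  expect_equal(res$balanced_accuracy, 0.5)
})

test_that("aggregates are giant components of the bound-site subgraph", {
  bound <- rep(FALSE, 10)
  bound[c(1, 2, 3, 7, 8)] <- TRUE
  con <- rbind(c(1L, 2L), c(2L, 3L), c(7L, 8L))
  tr <- fake_trajectory(0, matrix(FALSE, 1, 10),
                        matrix(bound, 1, 10), list(con))
  agg <- aggregate_distribution(list(tr))
  expect_equal(agg$raw_size, 3L)
  expect_equal(agg$rescaled_size, 3 * 0.096)
  # a contact with an unbound endpoint contributes no edge
  con2 <- rbind(c(4L, 9L))
  tr2 <- fake_trajectory(0, matrix(FALSE, 1, 10),
                         matrix(bound, 1, 10), list(con2))
  expect_equal(nrow(aggregate_distribution(list(tr2))), 0L)
  # bound sites without contacts are all filtered at min_size = 2
  tr3 <- fake_trajectory(0, matrix(FALSE, 1, 10), matrix(bound, 1, 10))
  expect_equal(nrow(aggregate_distribution(list(tr3))), 0L)
  expect_equal(aggregate_distribution(list(tr3), min_size = 1)$raw_size,
               1L)  # giant component of an edgeless graph is a single site
})

test_that("all-components mode keeps every cluster above the size filter", {
  bound <- rep(TRUE, 10)
  con <- rbind(c(1L, 2L), c(4L, 5L), c(5L, 6L), c(9L, 10L))
  tr <- fake_trajectory(0, matrix(FALSE, 1, 10), matrix(bound, 1, 10),
                        list(con))
  agg <- aggregate_distribution(list(tr), all_components = TRUE)
  expect_setequal(agg$raw_size, c(2L, 3L, 2L))
})

test_that("component sizes match a union-find oracle on random states", {
  set.seed(77)
  for (t in 1:40) {
    n <- sample(5:60, 1)
    st <- random_state(n, n_try_contacts = sample(0:20, 1), n_val = n)
    sizes <- sort(hp1sim:::component_sizes(st$hp1_bound, st$contacts))
    expect_equal(sizes, sort(oracle_component_sizes(st$hp1_bound,
                                                    st$contacts)))
  }
})

test_that("PCH occupancy change is the relative decrease of the integral", {
  ctrl <- c(0.9, 0.8, 0.1, 0.2)
  pch <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(pch_occupancy_change(ctrl, ctrl, pch), 0)
  expect_equal(pch_occupancy_change(ctrl, 0.85 * ctrl, pch), 0.15)
  expect_error(pch_occupancy_change(c(0, 0), c(1, 1), c(TRUE, TRUE)),
               "zero")
})

test_that("profiles are invariant to sample-interval refinement", {
  mask <- rep(c(TRUE, FALSE), 10)
  coarse <- hp1_simulate(mask, rate_params(), "control", duration = 150,
                         n_replicates = 2, sample_interval = 5, seed = 61)
  fine <- hp1_simulate(mask, rate_params(), "control", duration = 150,
                       n_replicates = 2, sample_interval = 1, seed = 61)
  pc <- probability_profile(coarse, burn_in = 30)
  pf <- probability_profile(fine, burn_in = 30)
  expect_equal(mean(pc), mean(pf), tolerance = 0.05)
  expect_lt(mean(abs(pc - pf)), 0.1)
})
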