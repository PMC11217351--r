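toy_region <- genome_region("toy", 0, 50000)  # 5 bins of 10 kb

test_that("spike-in normalisation uses the relative dm6/lambda factors", {
  tr <- signal_track(rep(2, 5), toy_region)
  ref <- norm_factors(1e6, 1000)
  self <- spike_in_normalize(tr, ref, ref)
  expect_equal(as.numeric(self), as.numeric(tr))
  halved <- spike_in_normalize(tr, norm_factors(2e6, 1000), ref)
  expect_equal(as.numeric(halved), as.numeric(tr) / 2)
  expect_error(norm_factors(1e6, 0), "spike-in")
})

test_that("H3 correction scales by the factor ratio and commutes", {
  tr <- signal_track(c(1, 2, 3, 4, 5), toy_region)
  expect_equal(as.numeric(h3_correct(tr, 2, 2)), as.numeric(tr))
  expect_equal(as.numeric(h3_correct(tr, 1, 2)), 2 * as.numeric(tr))
  expect_error(h3_correct(tr, 0, 1), "factors")
  # order of scalar normalisations does not matter
  s <- norm_factors(3e6, 1500); r <- norm_factors(1e6, 1000)
  a <- h3_correct(spike_in_normalize(tr, s, r), 2, 3)
  b <- spike_in_normalize(h3_correct(tr, 2, 3), s, r)
  expect_equal(as.numeric(a), as.numeric(b))
  expect_named(attr(a, "provenance"), c("spike_in", "h3_ratio"))
})

test_that("normalisations are linear in the track", {
  t1 <- signal_track(runif(5), toy_region)
  t2 <- signal_track(runif(5), toy_region)
  tsum <- signal_track(as.numeric(t1) + as.numeric(t2), toy_region)
  s <- norm_factors(2e6, 800); r <- norm_factors(1e6, 1000)
  f <- function(x) as.numeric(h3_correct(spike_in_normalize(x, s, r), 3, 2))
  expect_equal(f(tsum), f(t1) + f(t2))
})

test_that("bin_track computes length-weighted means with zero for gaps", {
  iv <- data.frame(chrom = "toy", start = 0, end = 10000, value = 7)
  expect_equal(as.numeric(bin_track(iv, toy_region)), c(7, 0, 0, 0, 0))
  # half-covered bin: length-weighted mean of 4 over half the bin = 2
  iv2 <- data.frame(chrom = "toy", start = 10000, end = 15000, value = 4)
  expect_equal(as.numeric(bin_track(iv2, toy_region))[2], 2)
  # empty input
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  expect_equal(as.numeric(bin_track(empty, toy_region)), rep(0, 5))
  # intervals beyond the region are clipped, other chromosomes dropped
  iv3 <- data.frame(chrom = c("toy", "elsewhere"),
                    start = c(45000, 0), end = c(99000, 10000),
                    value = c(3, 100))
  # clipped interval covers half of the last bin: length-weighted mean 1.5
  expect_equal(as.numeric(bin_track(iv3, toy_region)), c(0, 0, 0, 0, 1.5))
  # an interval straddling bins contributes to each by overlap
  iv4 <- data.frame(chrom = "toy", start = 5000, end = 25000, value = 2)
  expect_equal(as.numeric(bin_track(iv4, toy_region)), c(1, 2, 1, 0, 0))
})

test_that("binding-site calling recovers spikes over Gaussian background", {
  set.seed(15)
  n <- 500
  x <- rnorm(n, 1, 0.1)
  spikes <- sample(n, 10)
  x[spikes] <- 10
  call <- call_binding_sites(x)
  expect_true(all(call$mask[spikes]))
  expect_lte(sum(call$mask) - 10, 1)          # at most a rare false positive
  expect_equal(call$mean, 1, tolerance = 0.05)
  expect_equal(call$sd, 0.1, tolerance = 0.2)
})

test_that("clipped fit resists signal contamination better than moments", {
  set.seed(16)
  x <- rnorm(400, 1, 0.1)
  x[1:40] <- rnorm(40, 8, 0.5)                # 10% contamination
  clipped <- call_binding_sites(x, method = "clipped")
  moments <- call_binding_sites(x, method = "moments")
  expect_lt(abs(clipped$sd - 0.1), abs(moments$sd - 0.1))
  expect_equal(sum(clipped$mask), 40)
})

test_that("degenerate or short tracks are rejected; zero multiplier splits background", {
  expect_error(call_binding_sites(rep(1, 100)), "degenerate")
  expect_error(call_binding_sites(rnorm(10)), "too short")
  set.seed(17)
  x <- rnorm(1000, 5, 1)
  frac <- mean(call_binding_sites(x, n_sigma = 0)$mask)
  expect_equal(frac, 0.5, tolerance = 0.08)
})

test_that("false-positive rate on pure noise matches the Gaussian tail", {
  set.seed(18)
  fp <- vapply(1:300, function(s) {
    sum(call_binding_sites(rnorm(500, 2, 0.3))$mask)
  }, numeric(1))
  # expectation 500 * P(Z > 4) ~ 0.016 per track
  expect_lt(mean(fp), 0.06)
  expect_gte(mean(fp), 0)
})

test_that("peak quantification integrates per-base signal with flanks", {
  tr <- signal_track(c(2, 4, 6, 0, 1), toy_region)
  peaks <- data.frame(chrom = "toy", start = 10000, end = 20000)
  expect_equal(quantify_peaks(tr, peaks, flank = 0), 10000 * 4)
  # straddling peak with flank, against a per-base brute-force sum
  peaks2 <- data.frame(chrom = "toy", start = 8000, end = 21000)
  base_vals <- rep(as.numeric(tr), each = 10000)
  w <- (8000 - 1000 + 1):(21000 + 1000)       # [start-flank, end+flank)
  expect_equal(quantify_peaks(tr, peaks2, flank = 1000),
               sum(base_vals[w]))
  # two identical tracks -> identical integrals; empty peaks -> empty
  expect_equal(quantify_peaks(tr, peaks2), quantify_peaks(tr, peaks2))
  expect_equal(length(quantify_peaks(tr, peaks[0, ])), 0L)
  # off-region peak contributes zero
  peaks3 <- data.frame(chrom = "other", start = 0, end = 1000)
  expect_equal(quantify_peaks(tr, peaks3), 0)
})

test_that("log2 peak ratios handle pseudocounts and misalignment", {
  a <- c(4, 8, 2); b <- c(4, 4, 2)
  expect_equal(log2_peak_ratio(a, b), c(0, 1, 0))
  expect_equal(log2_peak_ratio(2 * b, b), c(1, 1, 1))
  expect_equal(log2_peak_ratio(c(3, 0), c(0, 0), pseudocount = 1),
               c(2, 0))
  expect_error(log2_peak_ratio(c(0, 1), c(0, 2)), "pseudocount")
  expect_error(log2_peak_ratio(1:3, 1:2), "misaligned")
})
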