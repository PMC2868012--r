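test_that("standardize centers and scales, with robust variant", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  x <- rnorm(100)
  z2 <- standardize(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero or non-finite spread")
  expect_error(standardize(1), "at least two")
  zr <- standardize(c(x, 100), robust = TRUE) # outlier barely moves median/MAD
  expect_lt(abs(zr[1] - (x[1] - median(x)) / mad(x)), 0.2)
})

test_that("autocorrelation estimates match the generating process", {
  set.seed(41)
  z <- rnorm(10000)
  rho <- estimate_autocorrelation(z, max_lag = 5)
  expect_lt(max(abs(rho$rho)), 0.03) # ~2/sqrt(n) sampling bound
  # AR(1) with phi = 0.5: rho_1 ~ 0.5
  phi <- 0.5
  ar <- as.numeric(arima.sim(list(ar = phi), 10000))
  rho2 <- estimate_autocorrelation(ar, max_lag = 3)
  expect_gt(rho2$rho[1], 0.45)
  expect_lt(rho2$rho[1], 0.55)
  expect_error(estimate_autocorrelation(rnorm(3), max_lag = 5), "longer than")
  # short chromosomes fall back to the pooled estimate of long ones
  rho3 <- estimate_autocorrelation(list(a = ar, b = rnorm(8)), max_lag = 3)
  expect_equal(length(rho3$rho), 3L)
})

test_that("window variance follows the closed form and its floor", {
  expect_equal(window_variance(1), 1)
  expect_equal(window_variance(3), 1 / 3) # all rho zero
  # w = 1, rho = (0.5, 0.25): (3 + 2*(2*0.5 + 1*0.25)) / 9 = 5.5/9
  expect_equal(window_variance(3, c(0.5, 0.25)), 5.5 / 9)
  # rho beyond the estimated lags treated as zero
  expect_equal(window_variance(5, c(0.5, 0.25)),
               (5 + 2 * (4 * 0.5 + 3 * 0.25)) / 25)
  expect_warning(v <- window_variance(3, c(-0.9, -0.9)), "flooring")
  expect_equal(v, 1 / 36)
})

test_that("closed-form variance matches Monte-Carlo window-mean variance", {
  # stationary process with rho_1 = 0.5, rho_2 = 0.25 (AR(1), phi = 0.5)
  set.seed(42)
  n <- 1e5
  S <- chol(matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  triples <- matrix(rnorm(3 * n), n, 3) %*% S
  mc_var <- var(rowMeans(triples))
  expect_lt(abs(mc_var - 5.5 / 9) / (5.5 / 9), 0.02)
})

test_that("w = 0 reduces the track to the per-probe z-test", {
  set.seed(43)
  z <- rnorm(500)
  pos <- sort(sample(0:100000, 500))
  params <- cmarrt_params(w = 0L, max_lag = 0L)
  tr <- moving_average_stat(z, pos, params, chrom = "c1")
  expect_equal(tr$S_star, z)
  tr <- add_pvalues(tr)
  expect_equal(tr$p, pnorm(z, lower.tail = FALSE))
  expect_equal(tr$p_adj, brute_bh(tr$p))
})

test_that("moving average shrinks windows at chromosome ends", {
  z <- c(1, 2, 3, 4, 5)
  tr <- moving_average_stat(z, c(0L, 10L, 20L, 30L, 40L),
                            cmarrt_params(w = 1L, max_lag = 0L))
  expect_equal(tr$S, c(1.5, 2, 3, 4, 4.5)) # edge windows of size 2
  # interior probes: Var = 1/3 so S* = S * sqrt(3)
  expect_equal(tr$S_star[3], 3 * sqrt(3))
  # edge probes: Var = 1/2 for m = 2
  expect_equal(tr$S_star[1], 1.5 * sqrt(2))
  expect_error(moving_average_stat(numeric(), integer(),
                                   cmarrt_params(w = 1L)),
               "empty chromosome")
})

test_that("normal-tail p-values hit reference quantiles", {
  expect_equal(upper_tail_pvalues(0), 0.5)
  expect_equal(upper_tail_pvalues(Inf), 0)
  expect_lt(abs(upper_tail_pvalues(1.959964) - 0.025), 1e-6)
})

test_that("bh_adjust equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(44)
  for (trial in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  p <- sort(runif(100))
  expect_true(all(diff(bh_adjust(p)) >= 0)) # monotone on sorted input
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("peak merging follows the gap rule between probe intervals", {
  # seeds at 100, 135, 170 merge (gaps 10 bp); singleton at 600 discarded
  tr <- stat_track(rep("c1", 4), c(100L, 135L, 170L, 600L),
                   paste0("p", 1:4), z = 5, S = 5, S_star = 5,
                   p = 1e-8, p_adj = 1e-8)
  params <- cmarrt_params(w = 1L, fdr_q = 0.05, max_gap = 100L,
                          min_probes = 2L)
  peaks <- call_peaks(tr, params, probe_len = 25L)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$start, 100L)
  expect_equal(peaks$end, 195L) # last start 170 + L
  expect_equal(peaks$n_probes, 3L)
  # no seeds -> empty
  tr2 <- tr; tr2$p_adj <- 0.9
  expect_equal(nrow(call_peaks(tr2, params)), 0L)
  # all seeds within gap -> one peak per chromosome
  tr3 <- stat_track(rep("c1", 10), seq(0L, 90L, 10L), paste0("q", 1:10),
                    z = 3, S = 3, S_star = 3, p = 1e-4, p_adj = 1e-4)
  p3 <- call_peaks(tr3, cmarrt_params(w = 1L, max_gap = 50L,
                                      min_probes = 2L), probe_len = 25L)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$end, 115L)
})

test_that("null scores rarely produce peaks and planted blocks are found", {
  # null: modest replicate count here; the acceptance suite runs the full
  # 50-replicate calibration
  set.seed(45)
  params <- cmarrt_params(w = 4L, fdr_q = 0.05, max_gap = 100L,
                          min_probes = 4L)
  pos <- seq(0L, by = 20L, length.out = 5000L)
  n_with_peak <- 0L
  for (i in 1:10) {
    z <- rnorm(5000)
    rho <- estimate_autocorrelation(z, params$max_lag)
    tr <- add_pvalues(moving_average_stat(z, pos, params, rho))
    if (nrow(call_peaks(tr, params, 25L)) > 0) n_with_peak <- n_with_peak + 1L
  }
  expect_lte(n_with_peak, 2L)

  # power: 20 planted blocks of 8 probes shifted +2 sd
  set.seed(46)
  n <- 5000L
  e <- rnorm(n)
  block_starts <- seq(100L, n - 100L, length.out = 20L)
  for (b in block_starts) e[b:(b + 7)] <- e[b:(b + 7)] + 2
  names(e) <- sprintf("p%05d", seq_len(n))
  anno <- probe_annotation("c1", pos, "+", names(e))
  res <- cmarrt_run(e, anno, params, probe_len = 25L)
  peaks <- res$peaks
  found <- vapply(block_starts, function(b) {
    bs <- pos[b]; be <- pos[b + 7] + 25L
    any(peaks$start < be & peaks$end > bs)
  }, logical(1))
  expect_gte(mean(found), 0.9)
  # every called peak overlaps a planted block (no false merges here)
  block_iv <- cbind(pos[block_starts], pos[block_starts + 7] + 25L)
  overlaps_truth <- vapply(seq_len(nrow(peaks)), function(i)
    any(block_iv[, 1] < peaks$end[i] & block_iv[, 2] > peaks$start[i]),
    logical(1))
  expect_true(all(overlaps_truth))
})

test_that("cmarrt_run ties the stages together over multiple chromosomes", {
  set.seed(47)
  n1 <- 400; n2 <- 300
  anno <- probe_annotation(c(rep("c1", n1), rep("c2", n2)),
                           c(seq(0L, by = 20L, length.out = n1),
                             seq(0L, by = 20L, length.out = n2)),
                           "+", sprintf("p%04d", 1:(n1 + n2)))
  e <- rnorm(n1 + n2, sd = 0.1)
  e[51:70] <- e[51:70] + 1 # enriched run on c1
  names(e) <- sprintf("p%04d", 1:(n1 + n2))
  res <- cmarrt_run(e, anno, cmarrt_params(w = 4L, min_probes = 4L),
                    probe_len = 25L)
  expect_s3_class(res$track, "StatTrack")
  expect_equal(nrow(res$track), n1 + n2)
  expect_true(all(res$track$p_adj >= res$track$p))
  expect_gte(nrow(res$peaks), 1L)
  expect_equal(res$peaks$chrom[1], "c1")
  # the planted run is inside the top peak
  top <- res$peaks[which.max(res$peaks$peak_score), ]
  expect_lte(top$start, 50 * 20)
  expect_gte(top$end, 69 * 20 + 25)
  expect_error(cmarrt_run(e[-1], anno, cmarrt_params()), "missing values")
})
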