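# fixture: one chromosome with probes every 10 bp whose value is their
# genomic start, so expected bin means have a closed form
ramp_fixture <- function(chrom_len = 5000L, step = 10L) {
  starts <- seq(0L, chrom_len - 25L, by = step)
  anno <- probe_annotation(rep("c1", length(starts)), starts, "+",
                           sprintf("p%04d", seq_along(starts)))
  list(anno = anno, signal = as.numeric(starts))
}

test_that("aligned profiles reproduce a linear ramp with closed-form bin means", {
  fx <- ramp_fixture()
  feats <- feature_set("f1", "c1", 2000L, 3000L, "+")
  apm <- align_profiles(fx$anno, fx$signal - 2000, feats, "TSS",
                        upstream = 200L, downstream = 400L, bin_size = 50L)
  expect_equal(dim(apm), c(1L, 12L))
  # bin [-200,-150) holds probes at rel -200,...,-160: mean = -180
  expected <- vapply(seq(-200, 350, by = 50), function(b0)
    mean(seq(b0, b0 + 40, by = 10)), numeric(1))
  expect_equal(unname(apm[1, ]), expected)
})

test_that("minus-strand profiles mirror plus-strand profiles", {
  fx <- ramp_fixture()
  # '-' feature whose TSS sits at 2999; value = distance downstream of TSS
  feats <- feature_set(c("fwd", "rev"), "c1", c(2000L, 2000L),
                       c(3000L, 3000L), c("+", "-"))
  sig_fwd <- fx$signal - 2000          # rel coordinate for the + TSS
  apm_f <- align_profiles(fx$anno, sig_fwd, feats[1, ], "TSS",
                          200L, 400L, 50L)
  sig_rev <- 2999 - fx$signal          # oriented rel coordinate for the - TSS
  apm_r <- align_profiles(fx$anno, sig_rev, feats[2, ], "TSS",
                          200L, 400L, 50L)
  # same oriented signal -> near-identical profile (probe starts fall on a
  # shifted lattice on the minus strand, displacing bin means by < bin width)
  expect_equal(unname(apm_r[1, ]), unname(apm_f[1, ]), tolerance = 0.1)
  # exact mirror when the signal is strand-symmetric around the anchors
  const <- rep(7, nrow(fx$anno))
  cf <- align_profiles(fx$anno, const, feats[1, ], "TSS", 200L, 400L, 50L)
  cr <- align_profiles(fx$anno, const, feats[2, ], "TSS", 200L, 400L, 50L)
  expect_equal(unname(cr[1, ]), unname(cf[1, ]))
})

test_that("windows without probes give all-missing rows that are counted", {
  fx <- ramp_fixture()
  feats <- feature_set(c("in", "out"), c("c1", "cX"), c(2000L, 100L),
                       c(3000L, 900L), c("+", "+"))
  apm <- align_profiles(fx$anno, fx$signal, feats, "TSS", 200L, 400L, 50L)
  expect_true(all(is.na(apm[2, ])))
  expect_equal(attr(apm, "n_empty"), 1L)
  expect_error(align_profiles(fx$anno, fx$signal, feats[0, ], "TSS",
                              200L, 400L, 50L),
               "no stranded features")
  expect_error(align_profiles(fx$anno, fx$signal, feats, "TSS",
                              210L, 400L, 50L),
               "divide")
})

test_that("mean_profile averages per bin ignoring missing values", {
  m <- aligned_profile_matrix(rbind(c(1, NA, 3), c(3, NA, 5)), 0, 150, 50)
  mp <- mean_profile(m)
  expect_equal(mp$mean, c(2, NA, 4))
  expect_equal(mp$n, c(2L, 0L, 2L))
  one <- aligned_profile_matrix(matrix(1:3, 1), 0, 150, 50)
  expect_equal(mean_profile(one)$mean, c(1, 2, 3))
})

test_that("quantile profiles match a direct per-column oracle", {
  expect_equal(
    quantile_profiles(aligned_profile_matrix(matrix(1:9, 9, 1), 0, 50, 50),
                      levels = 0.5)$median_line, 5)
  set.seed(51)
  for (trial in 1:100) {
    nr <- sample(3:20, 1); nc <- sample(2:8, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    apm <- aligned_profile_matrix(m, 0, nc * 50, 50)
    lv <- sort(runif(sample(1:5, 1)))
    lv <- pmin(pmax(lv, 0.01), 0.99)
    qp <- quantile_profiles(apm, levels = lv)
    for (j in seq_len(nc)) {
      col <- m[, j][!is.na(m[, j])]
      want <- if (length(col)) quantile(col, lv, type = 7, names = FALSE)
              else rep(NA_real_, length(lv))
      expect_equal(unname(qp$matrix[j, ]), want)
    }
    # non-decreasing across levels within each bin
    if (length(lv) > 1)
      expect_true(all(apply(qp$matrix, 1,
                            function(r) all(diff(r) >= 0 | is.na(diff(r))))))
  }
})

test_that("outlier profiles flag rows outside the quantile band", {
  set.seed(52)
  base <- matrix(rnorm(50 * 10), 50, 10)
  base[1, ] <- 20          # constantly above the 0.95 profile
  base[2, ] <- NA          # all-missing: counted, never flagged
  apm <- aligned_profile_matrix(base, 0, 500, 50)
  fl <- outlier_profiles(apm)
  expect_true(1L %in% fl)
  expect_false(2L %in% fl)
  expect_equal(attr(fl, "n_all_missing"), 1L)
  # the median-like row is not flagged
  med_row <- which.min(rowSums(abs(base - matrix(apply(base, 2, median,
                                                       na.rm = TRUE),
                                                 50, 10, byrow = TRUE))))
  expect_false(med_row %in% fl)
})

test_that("region occupancy averages oriented windows and skips degenerate regions", {
  starts <- c(10L, 50L, 200L)
  anno <- probe_annotation(rep("c1", 3), starts, "+", c("a", "b", "c"))
  feats <- feature_set(c("plus", "minus", "short"), "c1",
                       c(0L, 0L, 300L), c(300L, 300L, 600L),
                       c("+", "-", "+"))
  r <- region_spec("head", "TSS", 0L, "TSS", 100L)
  occ <- region_mean_occupancy(anno, c(1, 3, 5), feats, r)
  expect_equal(unname(occ["plus"]), 2)  # probes at rel 10 and 50
  # '-' TSS at 299: probes at oriented rel 289, 249, 99 -> only "c" inside
  expect_equal(unname(occ["minus"]), 5)
  # degenerate: TSS+500 .. TTS-500 on a 300 bp gene has negative length
  r2 <- region_spec("bad", "TSS", 500L, "TTS", -500L)
  occ2 <- region_mean_occupancy(anno, c(1, 3, 5), feats, r2)
  expect_true(all(is.na(occ2)))
  expect_equal(attr(occ2, "n_skipped"), 3L)
})

test_that("mirrored minus-strand genes give identical region occupancy", {
  # rev gene tiled so each probe sits at the same oriented offset as fwd:
  # fwd TSS = 100 (+), rev TSS = 924 (-); offsets 0, 50, 100, 150
  anno <- probe_annotation(rep("c1", 8),
                           c(100L, 150L, 200L, 250L, 774L, 824L, 874L, 924L),
                           "+", sprintf("p%d", 1:8))
  sig <- c(1, 2, 3, 4, 4, 3, 2, 1)
  feats <- feature_set(c("fwd", "rev"), "c1", c(100L, 625L), c(400L, 925L),
                       c("+", "-"))
  r <- region_spec("head", "TSS", 0L, "TSS", 120L)
  occ <- region_mean_occupancy(anno, sig, feats, r)
  expect_equal(unname(occ["fwd"]), 2) # offsets 0, 50, 100 -> mean(1, 2, 3)
  expect_equal(unname(occ["rev"]), unname(occ["fwd"]))
})

test_that("expression correlation identifies the coupled region", {
  set.seed(53)
  occ <- rbind(r1 = rnorm(200), r2 = rnorm(200))
  colnames(occ) <- sprintf("g%03d", 1:200)
  expr <- setNames(occ["r2", ], colnames(occ))
  res <- region_expression_correlation(occ, expr)
  expect_equal(res$r[res$region_id == "r2"], 1.0)
  expect_lt(abs(res$r[res$region_id == "r1"]), 0.2)
  res2 <- region_expression_correlation(occ, -expr)
  expect_equal(res2$r[res2$region_id == "r2"], -1.0)
  # too few complete pairs -> NA with n reported
  occ3 <- occ; occ3[1, 3:200] <- NA
  res3 <- region_expression_correlation(occ3, expr)
  expect_true(is.na(res3$r[1]))
  expect_equal(res3$n[1], 2L)
})

test_that("a rare strong TSS spike separates mean and median profiles", {
  set.seed(54)
  n_feat <- 200L
  n_bins <- 10L
  # background on the enrichment scale: fluctuations around ~0.01
  base <- matrix(rnorm(n_feat * n_bins, mean = 0.01, sd = 0.02),
                 n_feat, n_bins)
  spiked <- sample(n_feat, round(0.05 * n_feat))
  base[spiked, 5] <- 1.0 # TSS spike 10x the profile dynamic range, 5% of rows
  apm <- aligned_profile_matrix(base, 250, 250, 50)
  mp <- mean_profile(apm)
  qp <- quantile_profiles(apm)
  expect_gt(mp$mean[5], 2 * qp$median_line[5])
  # the spiked features are exactly the flagged outliers at that bin
  expect_true(all(base[spiked, 5] >
                    qp$matrix[5, which(qp$levels == 0.95)]))
})

test_that("expression_groups thresholds by percentile", {
  x <- setNames(1:100, paste0("g", 1:100))
  gr <- expression_groups(x, lower_frac = 0.2, upper_frac = 0.1)
  expect_true(all(x[gr$low] <= quantile(x, 0.2)))
  expect_true(all(x[gr$high] >= quantile(x, 0.9)))
  expect_equal(length(gr$low), 20L)
})
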