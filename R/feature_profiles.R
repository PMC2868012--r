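# Anchor-aligned binding profiles and occupancy/expression correlation.
# Profiles are aligned in transcription direction: the relative coordinate
# of a probe is (start - anchor) on '+' features and (anchor - start) on
# '-' features, so "downstream" always points into the transcript.

oriented_rel <- function(probe_start, anchor, strand) {
  if (strand == "+") probe_start - anchor else anchor - probe_start
}

#' Align probe signal along feature anchors
#'
#' For each feature, probes whose oriented relative start falls in
#' `[-upstream, downstream)` are averaged within consecutive `bin_size`
#' windows; bins without probes are NA. Probe-to-bin assignment uses the
#' probe start coordinate.
#'
#' @param anno a `ProbeAnnotation`.
#' @param signal per-probe numeric vector aligned to `anno` rows.
#' @param features a `FeatureSet`.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param upstream,downstream window extent in bp (must be multiples of
#'   `bin_size`).
#' @param bin_size bin width in bp.
#' @return An `AlignedProfileMatrix` (features x bins, row order =
#'   feature order) with attribute `n_empty` counting all-missing rows.
#' @export
align_profiles <- function(anno, signal, features, anchor = c("TSS", "TTS"),
                           upstream = 500L, downstream = 1500L,
                           bin_size = 50L) {
  anchor <- match.arg(anchor)
  stopifnot(length(signal) == nrow(anno))
  if (nrow(features) == 0L) stop("no stranded features to align")
  if (upstream %% bin_size != 0L || downstream %% bin_size != 0L)
    stop("bin_size must divide upstream and downstream")
  n_bins <- (upstream + downstream) %/% bin_size
  anchors <- feature_anchors(features)
  apos <- if (anchor == "TSS") anchors$tss else anchors$tts
  m <- matrix(NA_real_, nrow(features), n_bins,
              dimnames = list(features$feature_id, NULL))
  by_chr <- split(seq_len(nrow(anno)), anno$chrom)
  for (fi in seq_len(nrow(features))) {
    idx <- by_chr[[features$chrom[fi]]]
    if (is.null(idx)) next
    rel <- oriented_rel(anno$start[idx], apos[fi], features$strand[fi])
    inside <- rel >= -upstream & rel < downstream
    if (!any(inside)) next
    bin <- (rel[inside] + upstream) %/% bin_size + 1L
    v <- signal[idx][inside]
    ok <- !is.na(v)
    if (!any(ok)) next
    sums <- tapply(v[ok], bin[ok], mean)
    m[fi, as.integer(names(sums))] <- as.numeric(sums)
  }
  out <- aligned_profile_matrix(m, upstream, downstream, bin_size, anchor)
  attr(out, "n_empty") <- sum(rowSums(!is.na(m)) == 0L)
  out
}

#' Mean profile across features
#'
#' @param m an `AlignedProfileMatrix`.
#' @return Data frame with columns `bin_start` (relative bp), `mean` and
#'   `n` (features contributing to the bin); bins with `n = 0` have NA
#'   mean.
#' @export
mean_profile <- function(m) {
  if (nrow(m) == 0L) stop("profile matrix has no rows")
  n <- colSums(!is.na(m))
  mu <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  data.frame(bin_start = profile_bin_starts(m), mean = mu, n = n)
}

#' Quantile profiles ("profileplot" summary)
#'
#' Instead of one mean line, the q-quantiles of every bin (column) are
#' computed for a ladder of levels, exposing the distributional spread of
#' the profiles. Missing values are excluded per bin; bins with no data
#' yield NA quantiles.
#'
#' @param m an `AlignedProfileMatrix`.
#' @param levels ordered quantile levels in (0, 1); default 0.05..0.95 in
#'   steps of 0.05.
#' @return A `QuantileProfile`: list with `levels`, `matrix` (bins x
#'   levels), `median_line` and `bin_start`.
#' @export
quantile_profiles <- function(m, levels = seq(0.05, 0.95, by = 0.05)) {
  if (!length(levels) || any(levels <= 0 | levels >= 1))
    stop("levels must lie strictly inside (0, 1)")
  levels <- sort(levels)
  qm <- t(apply(m, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(rep(NA_real_, length(levels)))
    stats::quantile(col, probs = levels, type = 7, names = FALSE)
  }))
  qm <- matrix(qm, nrow = ncol(m), ncol = length(levels),
               dimnames = list(NULL, paste0("q", levels)))
  med <- apply(m, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_real_ else
      stats::quantile(col, probs = 0.5, type = 7, names = FALSE)
  })
  structure(list(levels = levels, matrix = qm, median_line = as.numeric(med),
                 bin_start = profile_bin_starts(m)),
            class = "QuantileProfile")
}

#' Flag outlier profiles
#'
#' A feature is an outlier when more than `min_fraction` of its
#' non-missing bins lie outside the `[q_low, q_high]` quantile band of the
#' whole profile set. All-missing rows are never flagged and are counted
#' separately.
#'
#' @param m an `AlignedProfileMatrix`.
#' @param q_low,q_high band quantile levels.
#' @param min_fraction fraction of out-of-band bins required.
#' @return Integer row indices of flagged features, with attribute
#'   `n_all_missing`.
#' @export
outlier_profiles <- function(m, q_low = 0.05, q_high = 0.95,
                             min_fraction = 0.5) {
  qp <- quantile_profiles(m, levels = c(q_low, q_high))
  lo <- qp$matrix[, 1L]
  hi <- qp$matrix[, 2L]
  n_ok <- rowSums(!is.na(m))
  frac_out <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    ok <- !is.na(v) & !is.na(lo) & !is.na(hi)
    if (!any(ok)) return(0)
    sum(v[ok] < lo[ok] | v[ok] > hi[ok]) / sum(ok)
  }, numeric(1))
  flagged <- which(n_ok > 0L & frac_out > min_fraction)
  attr(flagged, "n_all_missing") <- sum(n_ok == 0L)
  flagged
}

resolve_region_bounds <- function(features, region) {
  len <- features$end - features$start
  a <- function(anchor)
    if (anchor == "TSS") rep(0L, nrow(features)) else len - 1L
  list(start = a(region$start_anchor) + region$start_offset,
       end = a(region$end_anchor) + region$end_offset)
}

#' Mean occupancy within a transcript-relative region
#'
#' Resolves the region against each feature (anchors at TSS/TTS plus
#' signed offsets in transcription-direction bp) and averages the probe
#' signal whose oriented start lies inside `[start, end)`. Features where
#' the region resolves to non-positive length are skipped and counted;
#' features with no probe in the region get NA.
#'
#' @param anno a `ProbeAnnotation`.
#' @param signal per-probe numeric vector aligned to `anno`.
#' @param features a `FeatureSet`.
#' @param region a `RegionSpec`.
#' @return Named per-feature numeric vector with attributes `n_skipped`
#'   (non-positive region length) and `n_no_probes`.
#' @export
region_mean_occupancy <- function(anno, signal, features, region) {
  stopifnot(length(signal) == nrow(anno))
  bounds <- resolve_region_bounds(features, region)
  anchors <- feature_anchors(features)
  out <- rep(NA_real_, nrow(features))
  names(out) <- features$feature_id
  skipped <- bounds$end <= bounds$start
  by_chr <- split(seq_len(nrow(anno)), anno$chrom)
  for (fi in which(!skipped)) {
    idx <- by_chr[[features$chrom[fi]]]
    if (is.null(idx)) next
    rel <- oriented_rel(anno$start[idx], anchors$tss[fi], features$strand[fi])
    inside <- rel >= bounds$start[fi] & rel < bounds$end[fi]
    v <- signal[idx][inside]
    v <- v[!is.na(v)]
    if (length(v)) out[fi] <- mean(v)
  }
  attr(out, "n_skipped") <- sum(skipped)
  attr(out, "n_no_probes") <- sum(!skipped & is.na(out))
  out
}

#' Region x feature occupancy matrix
#'
#' @param anno a `ProbeAnnotation`.
#' @param signal per-probe numeric vector.
#' @param features a `FeatureSet`.
#' @param regions list of `RegionSpec` objects.
#' @return Numeric matrix (regions x features) of mean occupancies.
#' @export
region_occupancy_matrix <- function(anno, signal, features, regions) {
  rows <- lapply(regions, function(r)
    as.numeric(region_mean_occupancy(anno, signal, features, r)))
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(regions, `[[`, character(1), "region_id"),
                      features$feature_id)
  m
}

#' Correlate region occupancy with gene expression
#'
#' Pearson correlation, per region, between the mean occupancies and the
#' expression values of the features present in both inputs (matched by
#' feature id). Regions with fewer than 3 complete pairs give NA.
#'
#' @param occupancy regions x features matrix from
#'   [region_occupancy_matrix()].
#' @param expression named per-feature numeric vector.
#' @return Data frame with columns `region_id`, `r`, `n`; attribute
#'   `n_unmatched` counts features without expression value.
#' @export
region_expression_correlation <- function(occupancy, expression) {
  feats <- colnames(occupancy)
  expr <- expression[feats]
  res <- lapply(rownames(occupancy), function(rid) {
    occ <- occupancy[rid, ]
    ok <- !is.na(occ) & !is.na(expr)
    n <- sum(ok)
    r <- if (n >= 3L) stats::cor(occ[ok], expr[ok]) else NA_real_
    data.frame(region_id = rid, r = r, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_unmatched") <- sum(!feats %in% names(expression))
  out
}

#' Split features into expression percentile groups
#'
#' Generic percentile-threshold grouping, e.g. the bottom 20% and top 10%
#' of genes by expression.
#'
#' @param expression named numeric vector.
#' @param lower_frac fraction forming the low group.
#' @param upper_frac fraction forming the high group.
#' @return List with character vectors `low` and `high` of feature ids.
#' @export
expression_groups <- function(expression, lower_frac = 0.2,
                              upper_frac = 0.1) {
  x <- expression[!is.na(expression)]
  lo_cut <- stats::quantile(x, lower_frac, type = 7, names = FALSE)
  hi_cut <- stats::quantile(x, 1 - upper_frac, type = 7, names = FALSE)
  list(low = names(x)[x <= lo_cut], high = names(x)[x >= hi_cut])
}
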