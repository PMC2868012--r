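# Normalization against a reference immunoprecipitation. The recommended
# route is rank-percentile scaling of experiment and reference arrays
# followed by subtraction of the reference percentile from the experiment
# percentile; the Buck-Lieb median-rank-percentile combination is provided
# for replicate sets.

#' Log2-transform a raw intensity matrix
#'
#' Zeros are replaced by the smallest positive value of their array (and
#' counted) so that the logarithm is defined; negative values are an error.
#'
#' @param im an `IntensityMatrix` with `scale_tag == "raw"`.
#' @return The log2-scale `IntensityMatrix` with attribute `n_zero_replaced`.
#' @export
log2_transform <- function(im) {
  stopifnot(inherits(im, "IntensityMatrix"))
  if (im$scale_tag != "raw") stop("log2_transform expects a raw-scale matrix")
  v <- im$values
  if (any(v < 0, na.rm = TRUE)) stop("negative raw intensity")
  n_zero <- 0L
  for (j in seq_len(ncol(v))) {
    z <- which(!is.na(v[, j]) & v[, j] == 0)
    if (length(z)) {
      pos <- v[, j][!is.na(v[, j]) & v[, j] > 0]
      if (!length(pos)) stop("array ", colnames(v)[j], " is all zero")
      v[z, j] <- min(pos)
      n_zero <- n_zero + length(z)
    }
  }
  out <- intensity_matrix(log2(v), array_meta = im$array_meta,
                          scale_tag = "log2")
  attr(out, "n_zero_replaced") <- n_zero
  out
}

#' Rank-percentile transform of one array
#'
#' Replaces values by `rank / n` with ties given the average rank, mapping
#' each array onto `(0, 1]` and removing between-array scale differences.
#' Missing values (NA/NaN) are excluded from ranking and re-inserted as NA.
#'
#' @param values numeric vector.
#' @return Numeric vector of percentiles in `(0, 1]`.
#' @export
rank_percentile <- function(values) {
  miss <- is.na(values) # covers NA and NaN
  if (all(miss)) stop("rank_percentile: all values are missing")
  out <- rep(NA_real_, length(values))
  x <- values[!miss]
  out[!miss] <- rank(x, ties.method = "average") / length(x)
  out
}

#' Rank-percentile transform of every array of a matrix
#'
#' @param im an `IntensityMatrix` on raw or log2 scale.
#' @return The `IntensityMatrix` with `scale_tag = "percentile"`. Ranking
#'   is invariant under monotone transforms, so raw and log2 inputs give
#'   identical percentiles.
#' @export
percentile_normalize <- function(im) {
  stopifnot(inherits(im, "IntensityMatrix"))
  if (im$scale_tag == "enrichment")
    stop("cannot percentile-normalize an enrichment matrix")
  v <- apply(im$values, 2L, rank_percentile)
  dimnames(v) <- dimnames(im$values)
  intensity_matrix(v, array_meta = im$array_meta, scale_tag = "percentile")
}

#' Subtract reference percentiles from experiment percentiles
#'
#' For each (IP array, reference array) pair the per-probe enrichment is
#' the difference of the two percentile values; with several pairs the
#' per-probe enrichments are averaged. Enrichment therefore lies in
#' `[-1, 1]`.
#'
#' @param ip,ref percentile-scale `IntensityMatrix` objects (same probe
#'   order).
#' @param pairing data frame with columns `ip` and `ref` naming the arrays
#'   of each pair; defaults to all IP columns paired with the single
#'   reference column when `ref` has one array.
#' @return A `NormalizationResult`: list with `enrichment` (named
#'   per-probe vector), `provenance` and `n_pairs`.
#' @export
subtract_reference <- function(ip, ref, pairing = NULL) {
  stopifnot(inherits(ip, "IntensityMatrix"), inherits(ref, "IntensityMatrix"))
  if (ip$scale_tag != "percentile" || ref$scale_tag != "percentile")
    stop("subtract_reference expects percentile-scale matrices")
  if (!identical(rownames(ip$values), rownames(ref$values)))
    stop("probe order of ip and ref differ")
  if (is.null(pairing)) {
    if (ncol(ref$values) == 1L)
      pairing <- data.frame(ip = colnames(ip$values),
                            ref = colnames(ref$values)[1L])
    else stop("pairing must be given when there are several reference arrays")
  }
  if (!all(pairing$ip %in% colnames(ip$values)))
    stop("pairing names unknown IP array: ",
         setdiff(pairing$ip, colnames(ip$values))[1L])
  if (!all(pairing$ref %in% colnames(ref$values)))
    stop("pairing names unknown reference array: ",
         setdiff(pairing$ref, colnames(ref$values))[1L])
  diffs <- matrix(0, nrow(ip$values), nrow(pairing))
  for (i in seq_len(nrow(pairing)))
    diffs[, i] <- ip$values[, pairing$ip[i]] - ref$values[, pairing$ref[i]]
  enrichment <- rowMeans(diffs)
  names(enrichment) <- rownames(ip$values)
  structure(list(enrichment = enrichment,
                 provenance = list(method = "rank-percentile-subtract",
                                   ip_arrays = pairing$ip,
                                   ref_arrays = pairing$ref,
                                   tie_rule = "average"),
                 n_pairs = nrow(pairing)),
            class = "NormalizationResult")
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat(sprintf("NormalizationResult: %s, %d probes, %d pair(s)\n",
              x$provenance$method, length(x$enrichment), x$n_pairs))
  invisible(x)
}

#' Median-rank-percentile combination of replicate arrays
#'
#' Buck-Lieb replicate summary: each array is converted to within-array
#' ranks (average ties), the per-probe median rank across arrays is taken
#' and divided by the probe count, yielding one percentile per probe.
#'
#' @param values numeric probes x arrays matrix (k >= 1 columns).
#' @return Named numeric vector of per-probe percentiles.
#' @export
median_rank_percentile <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("need at least one array")
  ranks <- apply(values, 2L, function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    out[ok] <- rank(x[ok], ties.method = "average")
    out
  })
  med <- apply(as.matrix(ranks), 1L, stats::median, na.rm = TRUE)
  out <- med / nrow(values)
  names(out) <- rownames(values)
  out
}

#' Compute per-probe enrichment from a raw intensity matrix
#'
#' Full normalization pipeline: log2 transform, per-array rank-percentile
#' scaling, then reference subtraction. With
#' `method = "median-rank-percentile"` the IP replicates and the reference
#' replicates are each combined by [median_rank_percentile()] before the
#' subtraction.
#'
#' @param im raw-scale `IntensityMatrix` whose `array_meta$role` marks
#'   arrays as `"ip"` or `"reference"`.
#' @param method normalization method.
#' @param pairing optional explicit IP/reference pairing (see
#'   [subtract_reference()]).
#' @return A `NormalizationResult`.
#' @export
normalize_enrichment <- function(im,
                                 method = c("rank-percentile-subtract",
                                            "median-rank-percentile"),
                                 pairing = NULL) {
  method <- match.arg(method)
  roles <- im$array_meta$role
  ip_names <- im$array_meta$name[roles %in% "ip"]
  ref_names <- im$array_meta$name[roles %in% "reference"]
  if (!length(ip_names)) stop("no arrays with role 'ip'")
  if (!length(ref_names)) stop("no arrays with role 'reference'")
  lg <- if (im$scale_tag == "raw") log2_transform(im) else im
  if (method == "rank-percentile-subtract") {
    pn <- percentile_normalize(lg)
    sub_im <- function(names) intensity_matrix(
      pn$values[, names, drop = FALSE],
      array_meta = pn$array_meta[match(names, pn$array_meta$name), ],
      scale_tag = "percentile")
    if (is.null(pairing))
      pairing <- data.frame(ip = ip_names,
                            ref = rep(ref_names, length.out = length(ip_names)))
    subtract_reference(sub_im(ip_names), sub_im(ref_names), pairing)
  } else {
    ip_p <- median_rank_percentile(lg$values[, ip_names, drop = FALSE])
    ref_p <- median_rank_percentile(lg$values[, ref_names, drop = FALSE])
    structure(list(enrichment = ip_p - ref_p,
                   provenance = list(method = method,
                                     ip_arrays = ip_names,
                                     ref_arrays = ref_names,
                                     tie_rule = "average"),
                   n_pairs = 1L),
              class = "NormalizationResult")
  }
}
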