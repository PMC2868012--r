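# Hybridization-bias diagnostics. Affymetrix oligo probes show an
# intensity bias driven by their sequence: median intensity rises with
# GC-content, and each of the L probe positions carries a
# nucleotide-specific effect. These diagnostics expose both as plot-ready
# tables, before and after normalization, plus the usual array-image and
# MA summaries. Quartiles/quantiles use linear interpolation between order
# statistics (stats::quantile type 7) throughout.

#' GC count of a DNA sequence
#'
#' @param seq character vector of uppercase DNA sequences.
#' @return Integer count of G + C per sequence (N contributes 0).
#' @export
gc_content <- function(seq) {
  nchar(seq) - nchar(gsub("[GC]", "", seq))
}

#' Intensity summary by probe GC-content
#'
#' Groups probes by the GC count of their sequence and summarizes the
#' intensity distribution per group. Probes containing N and probes with
#' missing intensity are excluded (and counted), so the group sizes
#' partition the evaluated probes exactly.
#'
#' @param intensity per-probe numeric vector aligned to `probes`.
#' @param probes a `ProbeSet`.
#' @return A `GCBiasTable` data frame with columns `gc`, `n_probes`,
#'   `mean`, `lower_quartile`, `median`, `upper_quartile`; attributes
#'   `n_excluded_n` and `n_excluded_na`.
#' @export
gc_bias_summary <- function(intensity, probes) {
  stopifnot(length(intensity) == nrow(probes))
  has_n <- grepl("N", probes$sequence, fixed = TRUE)
  ok <- !has_n & !is.na(intensity)
  if (!any(ok)) stop("no probe with defined intensity")
  gc <- gc_content(probes$sequence[ok])
  x <- intensity[ok]
  groups <- sort(unique(gc))
  rows <- lapply(groups, function(g) {
    v <- x[gc == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(gc = g, n_probes = length(v), mean = mean(v),
               lower_quartile = q[1L], median = q[2L], upper_quartile = q[3L])
  })
  tab <- do.call(rbind, rows)
  attr(tab, "n_excluded_n") <- sum(has_n)
  attr(tab, "n_excluded_na") <- sum(!has_n & is.na(intensity))
  class(tab) <- c("GCBiasTable", "data.frame")
  tab
}

#' Position-specific nucleotide intensity bias
#'
#' For every probe position p (1..L) and base b, the mean intensity of all
#' probes carrying base b at position p. Probes containing N (and probes
#' with missing intensity) are excluded so that each position's counts sum
#' to the same number of evaluated probes.
#'
#' @param intensity per-probe numeric vector aligned to `probes`.
#' @param probes a `ProbeSet`.
#' @return A `PositionBiasMatrix`: list with `mean` and `count` (4 x L
#'   matrices, rows A/C/G/T) and exclusion counts.
#' @export
position_nucleotide_bias <- function(intensity, probes) {
  stopifnot(length(intensity) == nrow(probes))
  L <- probe_length(probes)
  has_n <- grepl("N", probes$sequence, fixed = TRUE)
  ok <- !has_n & !is.na(intensity)
  if (!any(ok)) stop("no probe with defined intensity")
  chars <- matrix(unlist(strsplit(probes$sequence[ok], "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  x <- intensity[ok]
  bases <- c("A", "C", "G", "T")
  means <- counts <- matrix(NA_real_, 4L, L, dimnames = list(bases, NULL))
  for (b in bases) {
    mask <- chars == b
    cnt <- colSums(mask)
    sums <- colSums(mask * x)
    counts[b, ] <- cnt
    means[b, ] <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  structure(list(mean = means, count = counts,
                 n_excluded_n = sum(has_n),
                 n_excluded_na = sum(!has_n & is.na(intensity))),
            class = "PositionBiasMatrix")
}

#' Reconstruct the physical array image
#'
#' Places each probe's intensity at its physical (x, y) coordinate; cells
#' without a probe are NA. Flawed array regions show up as spatial
#' patterns in this grid.
#'
#' @param intensity per-probe numeric vector aligned to `probes`.
#' @param probes a `ProbeSet` with unique (x, y) coordinates.
#' @return An `ArrayImage`: numeric `(max_y + 1) x (max_x + 1)` matrix.
#' @export
array_image <- function(intensity, probes) {
  stopifnot(length(intensity) == nrow(probes))
  if (nrow(probes) == 0L) stop("empty probe set")
  key <- paste(probes$array_x, probes$array_y)
  if (anyDuplicated(key))
    stop("duplicate array coordinates: ",
         paste(utils::head(probes$probe_id[key %in% key[duplicated(key)]], 5L),
               collapse = ", "))
  img <- matrix(NA_real_, max(probes$array_y) + 1L, max(probes$array_x) + 1L)
  img[cbind(probes$array_y + 1L, probes$array_x + 1L)] <- intensity
  class(img) <- c("ArrayImage", class(img))
  img
}

#' MA values of an array pair
#'
#' `M = log2(a / b)` and `A = (log2 a + log2 b) / 2` per probe; zeros are
#' replaced by the smallest positive value of their vector as in
#' [log2_transform()].
#'
#' @param a,b positive per-probe intensity vectors.
#' @return Data frame with columns `M` and `A`.
#' @export
ma_values <- function(a, b) {
  stopifnot(length(a) == length(b))
  fix_zero <- function(x) {
    if (any(x < 0, na.rm = TRUE)) stop("negative intensity")
    z <- !is.na(x) & x == 0
    if (any(z)) x[z] <- min(x[!is.na(x) & x > 0])
    x
  }
  la <- log2(fix_zero(a))
  lb <- log2(fix_zero(b))
  data.frame(M = la - lb, A = (la + lb) / 2)
}

#' Write the QC tables for one intensity vector
#'
#' Runs [gc_bias_summary()], [position_nucleotide_bias()] and
#' [array_image()] and writes them as tab-delimited tables under a common
#' prefix; the scale of the analyzed values is recorded alongside.
#'
#' @param intensity per-probe numeric vector.
#' @param probes a `ProbeSet`.
#' @param out_prefix path prefix (e.g. `"qc/raw_"`).
#' @param scale_tag scale label recorded with the tables.
#' @return Invisibly, the paths written.
#' @export
write_qc_tables <- function(intensity, probes, out_prefix,
                            scale_tag = "raw") {
  gc <- gc_bias_summary(intensity, probes)
  pb <- position_nucleotide_bias(intensity, probes)
  paths <- c(gc_bias = paste0(out_prefix, "gc_bias.tsv"),
             position_bias = paste0(out_prefix, "position_bias.tsv"),
             array_image = paste0(out_prefix, "array_image.tsv"))
  writeLines(c(paste0("# scale\t", scale_tag),
               "gc\tn_probes\tmean\tlower_quartile\tmedian\tupper_quartile",
               paste(gc$gc, gc$n_probes, fmt_num(gc$mean),
                     fmt_num(gc$lower_quartile), fmt_num(gc$median),
                     fmt_num(gc$upper_quartile), sep = "\t")),
             paths["gc_bias"], sep = "\n")
  L <- ncol(pb$mean)
  writeLines(c(paste0("# scale\t", scale_tag),
               "base\tposition\tmean\tcount",
               paste(rep(rownames(pb$mean), L),
                     rep(seq_len(L), each = 4L),
                     fmt_num(as.vector(pb$mean)),
                     as.vector(pb$count), sep = "\t")),
             paths["position_bias"], sep = "\n")
  img <- array_image(intensity, probes)
  writeLines(apply(img, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
             paths["array_image"], sep = "\n")
  invisible(paths)
}
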