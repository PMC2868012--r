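# Shared domain containers. Coordinates are 0-based, half-open everywhere
# inside the package; conversion to and from 1-based external conventions
# (GFF, WIG) happens only at the I/O boundary.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a probe set
#'
#' A probe set holds the reporters of a tiling array: one oligonucleotide
#' sequence per probe together with the probe's physical (x, y) position on
#' the array. Sequences are uppercased on ingest, must share a common length
#' and may only use the alphabet A/C/G/T/N.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param sequence character vector of equal-length DNA sequences.
#' @param array_x,array_y non-negative integer physical coordinates. If
#'   omitted, a deterministic row-major grid of width `ceiling(sqrt(n))`
#'   is assigned.
#' @return A `ProbeSet`: a data frame with columns `probe_id`, `sequence`,
#'   `array_x`, `array_y` and attribute `probe_length`.
#' @export
probe_set <- function(probe_id, sequence, array_x = NULL, array_y = NULL) {
  probe_id <- as.character(probe_id)
  sequence <- toupper(as.character(sequence))
  n <- length(probe_id)
  if (n == 0L) stop("probe set is empty")
  if (length(sequence) != n) stop("probe_id and sequence lengths differ")
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids: ",
         paste(unique(probe_id[duplicated(probe_id)])[1:min(5, n)], collapse = ", "))
  lens <- nchar(sequence)
  if (length(unique(lens)) != 1L)
    stop("probe sequences have inconsistent lengths: ",
         paste(sort(unique(lens)), collapse = ", "))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("probe sequence with characters outside {A,C,G,T,N}: ",
         probe_id[which(bad)[1L]])
  if (is.null(array_x) || is.null(array_y)) {
    nx <- ceiling(sqrt(n))
    array_x <- (seq_len(n) - 1L) %% nx
    array_y <- (seq_len(n) - 1L) %/% nx
  }
  array_x <- as.integer(array_x)
  array_y <- as.integer(array_y)
  if (any(array_x < 0L) || any(array_y < 0L))
    stop("array coordinates must be non-negative")
  ps <- data.frame(probe_id = probe_id, sequence = sequence,
                   array_x = array_x, array_y = array_y,
                   stringsAsFactors = FALSE)
  attr(ps, "probe_length") <- unique(lens)
  class(ps) <- c("ProbeSet", "data.frame")
  ps
}

#' Probe length of a probe set
#' @param probes a `ProbeSet`.
#' @return Integer common sequence length L.
#' @export
probe_length <- function(probes) attr(probes, "probe_length")

#' Construct a probe annotation
#'
#' The genomic placement of uniquely matching probes (the corrected
#' annotation a remapping run emits). Entries are sorted by chromosome,
#' then start, then probe id; unsorted input is auto-sorted with a warning.
#'
#' @param chrom,start,strand,probe_id parallel vectors (start is 0-based;
#'   strand in `+`/`-`).
#' @param match_report named integer vector with elements `unique`, `none`,
#'   `multiple` summarizing the remapping classification.
#' @param chrom_lengths optional named vector used to bounds-check starts
#'   (`0 <= start <= length - L` with `probe_len`).
#' @param probe_len optional probe length used for the bounds check.
#' @return A `ProbeAnnotation` data frame with columns
#'   `chrom`, `start`, `strand`, `probe_id`.
#' @export
probe_annotation <- function(chrom, start, strand, probe_id,
                             match_report = NULL, chrom_lengths = NULL,
                             probe_len = NULL) {
  an <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   strand = as.character(strand),
                   probe_id = as.character(probe_id),
                   stringsAsFactors = FALSE)
  if (nrow(an) > 0L) {
    if (!all(an$strand %in% c("+", "-")))
      stop("annotation strand must be '+' or '-'")
    if (any(an$start < 0L)) stop("annotation start < 0")
    if (anyDuplicated(an$probe_id))
      stop("probe appears more than once in annotation: ",
           an$probe_id[duplicated(an$probe_id)][1L])
    o <- order(an$chrom, an$start, an$probe_id, method = "radix")
    if (!identical(o, seq_len(nrow(an)))) {
      warning("annotation was not sorted; sorting by (chrom, start, probe_id)")
      an <- an[o, , drop = FALSE]
      rownames(an) <- NULL
    }
    if (!is.null(chrom_lengths) && !is.null(probe_len)) {
      len <- chrom_lengths[an$chrom]
      if (any(is.na(len))) stop("annotation names a chromosome with unknown length")
      if (any(an$start > len - probe_len))
        stop("annotation start beyond chromosome end")
    }
  }
  if (is.null(match_report))
    match_report <- c(unique = nrow(an), none = 0L, multiple = 0L)
  stopifnot(all(c("unique", "none", "multiple") %in% names(match_report)))
  attr(an, "match_report") <- match_report[c("unique", "none", "multiple")]
  class(an) <- c("ProbeAnnotation", "data.frame")
  an
}

#' Remapping classification report of an annotation
#' @param anno a `ProbeAnnotation`.
#' @return Named integer vector `unique`/`none`/`multiple`.
#' @export
match_report <- function(anno) attr(anno, "match_report")

#' Construct an intensity matrix
#'
#' Probes x arrays measurements plus per-array metadata. `scale_tag` tracks
#' the processing state and only changes through the documented pipeline
#' raw -> log2 -> percentile -> enrichment.
#'
#' @param values numeric matrix with probe ids as row names and array names
#'   as column names.
#' @param array_meta data frame with columns `name`, `role`
#'   (`"ip"`/`"reference"`/NA) and `condition`; defaults are derived from
#'   the column names.
#' @param scale_tag one of `"raw"`, `"log2"`, `"percentile"`, `"enrichment"`.
#' @return An `IntensityMatrix` (list with `values`, `array_meta`,
#'   `scale_tag`).
#' @export
intensity_matrix <- function(values, array_meta = NULL, scale_tag = "raw") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity values must be numeric")
  if (is.null(rownames(values))) stop("intensity matrix needs probe ids as row names")
  if (is.null(colnames(values))) colnames(values) <- paste0("array_", seq_len(ncol(values)))
  scale_tag <- match.arg(scale_tag, c("raw", "log2", "percentile", "enrichment"))
  if (scale_tag == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw-scale intensities must be non-negative")
  if (is.null(array_meta)) {
    array_meta <- data.frame(name = colnames(values),
                             role = NA_character_,
                             condition = NA_character_,
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "role", "condition") %in% names(array_meta)),
            identical(as.character(array_meta$name), colnames(values)))
  structure(list(values = values, array_meta = array_meta,
                 scale_tag = scale_tag),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d probes x %d arrays [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat("arrays:", paste(x$array_meta$name, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a feature set
#'
#' Genomic features (genes/transcripts) with 0-based half-open coordinates
#' and mandatory strand. The transcription start site (TSS) of a `+`
#' feature is `start`, of a `-` feature `end - 1`; the termination site
#' (TTS) is the opposite end.
#'
#' @param feature_id,chrom,start,end,strand parallel vectors.
#' @return A `FeatureSet` data frame.
#' @export
feature_set <- function(feature_id, chrom, start, end, strand) {
  fs <- data.frame(feature_id = as.character(feature_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(fs) > 0L) {
    if (!all(fs$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    if (any(fs$start >= fs$end)) stop("feature with start >= end")
    if (anyDuplicated(fs$feature_id))
      stop("duplicate feature id: ", fs$feature_id[duplicated(fs$feature_id)][1L])
  }
  class(fs) <- c("FeatureSet", "data.frame")
  fs
}

#' Anchor coordinates of features
#'
#' @param features a `FeatureSet`.
#' @return Data frame with columns `tss` and `tts` (0-based genomic base
#'   positions, strand-aware).
#' @export
feature_anchors <- function(features) {
  plus <- features$strand == "+"
  data.frame(tss = ifelse(plus, features$start, features$end - 1L),
             tts = ifelse(plus, features$end - 1L, features$start))
}

#' Peak-calling parameters
#'
#' @param w window half-width in probes (the moving-average window spans
#'   `2w + 1` probes).
#' @param max_lag number of autocorrelation lags used in the variance
#'   correction; defaults to `2w`.
#' @param fdr_q target false-discovery rate for seed probes.
#' @param max_gap largest genomic gap (bp, between probe intervals) bridged
#'   when merging significant probes into a region.
#' @param min_probes minimum number of probes per reported peak.
#' @return A `CmarrtParams` list.
#' @export
cmarrt_params <- function(w = 4L, max_lag = 2L * w, fdr_q = 0.05,
                          max_gap = 250L, min_probes = 4L) {
  w <- as.integer(w); max_lag <- as.integer(max_lag)
  max_gap <- as.integer(max_gap); min_probes <- as.integer(min_probes)
  if (w < 0L) stop("w must be >= 0")
  if (max_lag < 0L) stop("max_lag must be >= 0")
  if (!(fdr_q > 0 && fdr_q < 1)) stop("fdr_q must lie in (0, 1)")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (min_probes < 1L) stop("min_probes must be >= 1")
  structure(list(w = w, max_lag = max_lag, fdr_q = fdr_q,
                 max_gap = max_gap, min_probes = min_probes),
            class = "CmarrtParams")
}

#' Construct a statistic track
#'
#' Per-probe peak-calling statistics in genomic order: standardized scores
#' `z`, moving averages `S`, standardized moving averages `S_star`,
#' upper-tail p-values and BH-adjusted p-values.
#'
#' @param chrom,position,probe_id,z,S,S_star,p,p_adj parallel vectors;
#'   positions must be strictly increasing within each chromosome.
#' @return A `StatTrack` data frame.
#' @export
stat_track <- function(chrom, position, probe_id, z, S, S_star,
                       p = NA_real_, p_adj = NA_real_) {
  tr <- data.frame(chrom = as.character(chrom), position = as.integer(position),
                   probe_id = as.character(probe_id),
                   z = z, S = S, S_star = S_star, p = p, p_adj = p_adj,
                   stringsAsFactors = FALSE)
  incr <- tapply(tr$position, tr$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(incr))) stop("track positions must be strictly increasing per chromosome")
  for (col in c("p", "p_adj")) {
    v <- tr[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(col, " outside [0, 1]")
  }
  class(tr) <- c("StatTrack", "data.frame")
  tr
}

#' Define a transcript-relative region
#'
#' A region is anchored at the TSS or TTS with signed offsets in
#' transcription-direction base pairs, e.g. `region_spec("promoter", "TSS",
#' -200, "TSS", 0)`.
#'
#' @param region_id region label.
#' @param start_anchor,end_anchor `"TSS"` or `"TTS"`.
#' @param start_offset,end_offset signed offsets in bp along the
#'   transcription direction.
#' @return A `RegionSpec` list.
#' @export
region_spec <- function(region_id, start_anchor, start_offset,
                        end_anchor, end_offset) {
  start_anchor <- match.arg(start_anchor, c("TSS", "TTS"))
  end_anchor <- match.arg(end_anchor, c("TSS", "TTS"))
  structure(list(region_id = as.character(region_id),
                 start_anchor = start_anchor,
                 start_offset = as.integer(start_offset),
                 end_anchor = end_anchor,
                 end_offset = as.integer(end_offset)),
            class = "RegionSpec")
}

#' Construct an aligned profile matrix
#'
#' @param m numeric features x bins matrix (NA = bin without probes).
#' @param upstream,downstream,bin_size grid definition in bp.
#' @param anchor `"TSS"` or `"TTS"`.
#' @return An `AlignedProfileMatrix`.
#' @export
aligned_profile_matrix <- function(m, upstream, downstream, bin_size,
                                   anchor = c("TSS", "TTS")) {
  anchor <- match.arg(anchor)
  m <- as.matrix(m)
  n_bins <- (upstream + downstream) / bin_size
  if (n_bins != round(n_bins) || ncol(m) != n_bins)
    stop("bin count must equal (upstream + downstream) / bin_size")
  structure(m, class = c("AlignedProfileMatrix", class(m)),
            grid = list(upstream = upstream, downstream = downstream,
                        bin_size = bin_size),
            anchor = anchor)
}

#' Grid of an aligned profile matrix
#' @param m an `AlignedProfileMatrix`.
#' @return List with `upstream`, `downstream`, `bin_size`.
#' @export
profile_grid <- function(m) attr(m, "grid")

#' Relative start coordinate of each profile bin
#' @param m an `AlignedProfileMatrix`.
#' @return Integer vector of bin start offsets relative to the anchor.
#' @export
profile_bin_starts <- function(m) {
  g <- profile_grid(m)
  seq(-g$upstream, g$downstream - g$bin_size, by = g$bin_size)
}
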