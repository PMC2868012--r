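# Readers and writers for every external format the toolkit touches.
# All text output is UTF-8, LF-terminated and tab-separated; numbers are
# serialized with %.15g so written files are byte-deterministic and
# round-trip doubles to working precision.

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased.
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a probe table
#'
#' Tab-delimited with header `probe_id`, `sequence`, `array_x`, `array_y`
#' (the text equivalent of an Affymetrix BPMAP reporter listing).
#'
#' @param path input path.
#' @return A `ProbeSet`.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "integer", "integer"))
  probe_set(tab$probe_id, tab$sequence, tab$array_x, tab$array_y)
}

#' Write a probe table
#' @param probes a `ProbeSet`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_probe_table <- function(probes, path) {
  lines <- c("probe_id\tsequence\tarray_x\tarray_y",
             paste(probes$probe_id, probes$sequence, probes$array_x,
                   probes$array_y, sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read genomic features from GFF3
#'
#' Coordinates are converted from the 1-based inclusive GFF convention to
#' the internal 0-based half-open one. The feature id is taken from the
#' `ID` attribute, falling back to `seqid:start-end` (original 1-based
#' coordinates). Malformed lines (wrong column count, non-numeric or
#' inverted coordinates, illegal strand) are skipped and reported with
#' their line numbers; strand `"."` features are excluded from the set
#' (they carry no orientation for anchor-aligned analyses) and counted
#' separately.
#'
#' @param path GFF3 file.
#' @return A `FeatureSet` with attributes `skipped` (data frame of line
#'   numbers and reasons) and `n_unstranded`.
#' @export
read_gff <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  skipped <- list()
  n_unstranded <- 0L
  out <- list()
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != 9L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = lineno[i], reason = "expected 9 tab-separated fields")
      next
    }
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = lineno[i], reason = "non-numeric coordinates")
      next
    }
    if (start > end) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = lineno[i], reason = "start > end")
      next
    }
    strand <- f[7L]
    if (!strand %in% c("+", "-", ".")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = lineno[i], reason = paste0("illegal strand '", strand, "'"))
      next
    }
    if (strand == ".") {
      n_unstranded <- n_unstranded + 1L
      next
    }
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9L])
    if (identical(id, f[9L]) || !nzchar(id))
      id <- sprintf("%s:%d-%d", f[1L], start, end)
    out[[length(out) + 1L]] <-
      data.frame(feature_id = id, chrom = f[1L], start = start - 1L,
                 end = end, strand = strand, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  fs <- feature_set(df$feature_id, df$chrom, df$start, df$end, df$strand)
  attr(fs, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(line = integer(), reason = character())
  attr(fs, "n_unstranded") <- n_unstranded
  fs
}

#' Write a feature set as GFF3
#' @param features a `FeatureSet`.
#' @param path output path.
#' @param source,type GFF source and type columns.
#' @return Invisibly, `path`.
#' @export
write_gff <- function(features, path, source = "tilechip", type = "gene") {
  lines <- c("##gff-version 3",
             if (nrow(features) > 0L)
               paste(features$chrom, source, type, features$start + 1L,
                     features$end, ".", features$strand, ".",
                     paste0("ID=", features$feature_id), sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read an intensity table
#'
#' Tab-delimited, first column `probe_id`, remaining columns one array
#' each (the text equivalent of CEL import). Rows are reordered to match
#' the probe set; a probe of the set missing from the table is an error;
#' table rows for unknown probes are dropped and counted.
#'
#' @param path input path.
#' @param probes `ProbeSet` defining the required row order.
#' @param array_meta optional array metadata (see [intensity_matrix()]).
#' @param scale_tag scale of the stored values.
#' @return An `IntensityMatrix` with attribute `n_extra` (dropped rows).
#' @export
read_intensity_table <- function(path, probes, array_meta = NULL,
                                 scale_tag = "raw") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "probe_id") stop("first column must be probe_id")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe row: ", tab$probe_id[duplicated(tab$probe_id)][1L])
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- cells
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- is.na(vals) & !is.na(cells) &
    !toupper(trimws(cells)) %in% c("NA", "NAN")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric intensity for probe ", tab$probe_id[idx[1L]],
         ", array ", colnames(vals)[idx[2L]])
  }
  rownames(vals) <- tab$probe_id
  miss <- setdiff(probes$probe_id, tab$probe_id)
  if (length(miss))
    stop("intensity table is missing probe(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  n_extra <- sum(!tab$probe_id %in% probes$probe_id)
  vals <- vals[probes$probe_id, , drop = FALSE]
  im <- intensity_matrix(vals, array_meta = array_meta, scale_tag = scale_tag)
  attr(im, "n_extra") <- n_extra
  im
}

#' Write an intensity table
#' @param im an `IntensityMatrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(im, path) {
  v <- im$values
  body <- apply(v, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  lines <- c(paste(c("probe_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), body, sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-delimited with header `feature_id`, `expression`.
#'
#' @param path input path.
#' @return Named numeric vector of expression values.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "numeric"))
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write a gene expression table
#' @param expression named numeric vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(expression, path) {
  lines <- c("feature_id\texpression",
             paste(names(expression), fmt_num(expression), sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write called peaks as BED6
#'
#' The BED score is an affine clamp of the peak score (mean standardized
#' moving average): `score = round(100 * peak_score)` truncated to
#' `[0, 1000]`, so a peak score of 10 standard deviations saturates the
#' BED scale. Peak names are `peak_1`, `peak_2`, ... in file order.
#'
#' @param peaks a `PeakCall` data frame from [call_peaks()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    writeLines(character(), path, sep = "\n")
    return(invisible(path))
  }
  score <- pmin(1000L, pmax(0L, as.integer(round(100 * peaks$peak_score))))
  lines <- paste(peaks$chrom, peaks$start, peaks$end,
                 paste0("peak_", seq_len(nrow(peaks))), score, ".",
                 sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write a per-probe signal track as fixed-span WIG
#'
#' variableStep wiggle with `span = L` (the probe length); starts are
#' converted to the 1-based WIG convention. Non-finite values are skipped
#' and counted.
#'
#' @param anno a `ProbeAnnotation`.
#' @param values per-probe numeric vector aligned to `anno` rows.
#' @param path output path.
#' @param span probe length L used as the fixed span.
#' @return Invisibly, the number of skipped (non-finite) values.
#' @export
write_track_wig <- function(anno, values, path, span = 25L) {
  stopifnot(length(values) == nrow(anno))
  con <- file(path, "wb")
  on.exit(close(con))
  n_skipped <- 0L
  for (chr in unique(anno$chrom)) {
    sel <- anno$chrom == chr
    writeLines(sprintf("variableStep chrom=%s span=%d", chr, span), con,
               sep = "\n")
    v <- values[sel]
    pos <- anno$start[sel] + 1L
    ok <- is.finite(v)
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok))
      writeLines(paste(pos[ok], fmt_num(v[ok]), sep = "\t"), con, sep = "\n")
  }
  invisible(n_skipped)
}

#' Read transcript-relative region definitions
#'
#' Tab-delimited with header `region_id`, `start_anchor`, `start_offset`,
#' `end_anchor`, `end_offset`; one region per line (see [region_spec()]).
#' A default set spanning promoter, TSS-proximal, elongation and TTS
#' regions ships with the package
#' (`system.file("extdata", "regions_default.tsv", package = "tilechip")`).
#'
#' @param path input path.
#' @return List of `RegionSpec` objects.
#' @export
read_region_specs <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "integer", "character",
                                                "integer"))
  lapply(seq_len(nrow(tab)), function(i)
    region_spec(tab$region_id[i], tab$start_anchor[i], tab$start_offset[i],
                tab$end_anchor[i], tab$end_offset[i]))
}
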