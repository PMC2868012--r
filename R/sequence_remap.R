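# Remapping of reporter sequences to a genome. Outdated array annotation
# leaves probes matching none or several loci of a current assembly; the
# remapper rebuilds the probe -> coordinate mapping by exact multi-pattern
# matching with an Aho-Corasick automaton and keeps only unique matchers.

#' Build an Aho-Corasick automaton over DNA patterns
#'
#' Constructs the keyword trie with failure links and merged output sets.
#' Duplicate pattern strings share one terminal state but retain every
#' pattern index in its output set, so probes with identical sequences each
#' receive the full match list.
#'
#' @param patterns character vector of uppercase A/C/G/T patterns.
#' @return An `ac_automaton` object.
#' @export
build_automaton <- function(patterns) {
  patterns <- as.character(patterns)
  if (length(patterns) == 0L) stop("pattern list is empty")
  if (any(grepl("[^ACGT]", patterns)))
    stop("pattern with illegal character (alphabet is A/C/G/T); ",
         "exclude N-containing probes before building the automaton")
  ptr <- .ac_build_cpp(patterns)
  structure(list(ptr = ptr, patterns = patterns,
                 n_states = .ac_n_states_cpp(ptr)),
            class = "ac_automaton")
}

#' @export
print.ac_automaton <- function(x, ...) {
  cat(sprintf("Aho-Corasick automaton: %d patterns, %d states\n",
              length(x$patterns), x$n_states))
  invisible(x)
}

#' Number of automaton state transitions performed so far
#'
#' Instrumentation counter: one transition is charged per scanned character,
#' which makes the linear-time behaviour of the scan observable.
#'
#' @param automaton an `ac_automaton`.
#' @param reset if `TRUE`, zero the counter after reading it.
#' @return Numeric transition count.
#' @export
automaton_transitions <- function(automaton, reset = FALSE) {
  n <- .ac_transitions_cpp(automaton$ptr)
  if (reset) .ac_reset_transitions_cpp(automaton$ptr)
  n
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan a genome for probe matches
#'
#' Streams every chromosome through the automaton once. A forward
#' occurrence of pattern i at 0-based position s is reported as
#' `(chrom, s, "+")`. With `both_strands = TRUE` the pattern set is
#' augmented with reverse complements (rather than reverse-complementing
#' the genome), and an occurrence of revcomp(pattern i) covering the
#' forward-strand interval `[s, s + L)` is reported as `(chrom, s, "-")`.
#' `N` (or any non-ACGT symbol) matches nothing and interrupts runs.
#'
#' @param automaton an `ac_automaton` built from the probe sequences.
#' @param genome named character vector of chromosome sequences, or a path
#'   to a FASTA file.
#' @param both_strands scan for reverse-complement matches as well.
#' @return A `MatchList` data frame with columns `probe_index`, `chrom`,
#'   `start`, `strand` and attribute `n_patterns`.
#' @export
scan_genome <- function(automaton, genome, both_strands = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must be a named vector with unique chromosome names")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("chromosome ", names(genome)[which(bad)[1L]],
         " contains characters outside {A,C,G,T,N}")
  np <- length(automaton$patterns)
  scanner <- automaton
  strand_of <- rep("+", np)
  index_of <- seq_len(np)
  if (both_strands) {
    rc <- revcomp(automaton$patterns)
    scanner <- build_automaton(c(automaton$patterns, rc))
    strand_of <- rep(c("+", "-"), each = np)
    index_of <- rep(seq_len(np), 2L)
  }
  res <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    hits <- .ac_scan_cpp(scanner$ptr, genome[[ci]])
    if (length(hits$pattern) == 0L) next
    res[[ci]] <- data.frame(probe_index = index_of[hits$pattern],
                            chrom = names(genome)[ci],
                            start = hits$start,
                            strand = strand_of[hits$pattern],
                            stringsAsFactors = FALSE)
  }
  ml <- do.call(rbind, res)
  if (is.null(ml))
    ml <- data.frame(probe_index = integer(), chrom = character(),
                     start = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  ml <- unique(ml)
  ml <- ml[order(ml$probe_index, ml$chrom, ml$start, ml$strand,
                 method = "radix"), , drop = FALSE]
  rownames(ml) <- NULL
  attr(ml, "n_patterns") <- np
  attr(ml, "transitions") <- automaton_transitions(scanner)
  class(ml) <- c("MatchList", "data.frame")
  ml
}

#' Classify probe matches and emit a corrected annotation
#'
#' Probes matching exactly one genomic locus are retained; probes with no
#' match are dropped and counted as `none`; probes with two or more matches
#' (including one hit on each strand, e.g. a palindromic probe) are dropped
#' and counted as `multiple`. The three counts sum to the probe set size.
#'
#' @param matches a `MatchList` from [scan_genome()], indexed against
#'   `probes` (probes absent from the list have zero matches).
#' @param probes the `ProbeSet` the automaton was built from. Probes listed
#'   in `excluded` (e.g. N-containing probes never scanned) are counted as
#'   `none`.
#' @param excluded integer indices of probes excluded before scanning.
#' @param chrom_lengths optional named vector for bounds checking.
#' @return A `ProbeAnnotation` with a `match_report` attribute.
#' @export
classify_matches <- function(matches, probes, excluded = integer(),
                             chrom_lengths = NULL) {
  n <- nrow(probes)
  counts <- tabulate(matches$probe_index, nbins = n)
  counts[excluded] <- 0L
  uniq <- which(counts == 1L)
  report <- c(unique = length(uniq),
              none = sum(counts == 0L),
              multiple = sum(counts > 1L))
  stopifnot(sum(report) == n)
  keep <- matches[matches$probe_index %in% uniq, , drop = FALSE]
  probe_annotation(chrom = keep$chrom, start = keep$start,
                   strand = keep$strand,
                   probe_id = probes$probe_id[keep$probe_index],
                   match_report = report, chrom_lengths = chrom_lengths,
                   probe_len = probe_length(probes))
}

#' Remap a probe set to a genome
#'
#' Convenience wrapper running the whole correction: N-containing probes
#' are excluded up front (exact matching over N is undefined) and counted
#' as `none`; the remaining sequences are matched with [scan_genome()] and
#' classified with [classify_matches()].
#'
#' @param probes a `ProbeSet`.
#' @param genome named character vector of chromosomes or FASTA path.
#' @param both_strands scan both strands (default) or forward only.
#' @return A `ProbeAnnotation` (the corrected probe -> coordinate mapping).
#' @export
remap_probes <- function(probes, genome, both_strands = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  has_n <- grepl("N", probes$sequence, fixed = TRUE)
  excluded <- which(has_n)
  if (all(has_n)) {
    return(probe_annotation(character(), integer(), character(), character(),
                            match_report = c(unique = 0L, none = nrow(probes),
                                             multiple = 0L)))
  }
  # scan only clean sequences; re-index hits into the full probe set
  clean <- which(!has_n)
  ac <- build_automaton(probes$sequence[clean])
  ml <- scan_genome(ac, genome, both_strands = both_strands)
  ml$probe_index <- clean[ml$probe_index]
  classify_matches(ml, probes, excluded = excluded,
                   chrom_lengths = nchar(genome))
}

#' Write a corrected probe annotation
#'
#' Emits a deterministic, sorted tab-delimited table (`chrom`, `start`,
#' `strand`, `probe_id`; 0-based starts) plus a sidecar report file with
#' the unique/none/multiple classification counts.
#'
#' @param anno a `ProbeAnnotation`.
#' @param path output path; the report is written to `paste0(path, ".report")`
#'   unless `report_path` is given.
#' @param report_path optional explicit report path.
#' @return Invisibly, the two paths written.
#' @export
write_corrected_annotation <- function(anno, path,
                                       report_path = paste0(path, ".report")) {
  lines <- c(paste(c("chrom", "start", "strand", "probe_id"), collapse = "\t"),
             if (nrow(anno) > 0L)
               paste(anno$chrom, anno$start, anno$strand, anno$probe_id,
                     sep = "\t"))
  writeLines(lines, path, sep = "\n")
  rep <- match_report(anno)
  writeLines(c(paste0("unique\t", rep[["unique"]]),
               paste0("none\t", rep[["none"]]),
               paste0("multiple\t", rep[["multiple"]])),
             report_path, sep = "\n")
  invisible(c(annotation = path, report = report_path))
}

#' Read a corrected probe annotation
#'
#' @param path annotation table written by [write_corrected_annotation()].
#' @param report_path sidecar report path (defaults to `paste0(path,
#'   ".report")`; the report is optional on read).
#' @return A `ProbeAnnotation`.
#' @export
read_annotation <- function(path, report_path = paste0(path, ".report")) {
  tab <- utils::read.delim(path, colClasses = c("character", "integer",
                                                "character", "character"))
  rep <- NULL
  if (file.exists(report_path)) {
    rl <- utils::read.delim(report_path, header = FALSE,
                            col.names = c("class", "count"))
    rep <- stats::setNames(as.integer(rl$count), rl$class)
  }
  probe_annotation(tab$chrom, tab$start, tab$strand, tab$probe_id,
                   match_report = rep)
}
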