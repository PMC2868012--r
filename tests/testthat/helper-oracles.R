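# Independent oracles and small fixture builders. The scan oracle works by
# direct k-mer comparison (substring + hashing), sharing no code with the
# automaton; the BH oracle implements the step-up definition directly.

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# naive multi-pattern scan: every k-mer of every chromosome is compared
# against the (possibly reverse-complemented) pattern set
naive_scan <- function(patterns, genome, both_strands = TRUE) {
  entries <- data.frame(pat = patterns, probe_index = seq_along(patterns),
                        strand = "+", stringsAsFactors = FALSE)
  if (both_strands)
    entries <- rbind(entries,
                     data.frame(pat = revcomp_chr(patterns),
                                probe_index = seq_along(patterns),
                                strand = "-", stringsAsFactors = FALSE))
  res <- list()
  for (ci in seq_along(genome)) {
    chr <- genome[[ci]]
    n <- nchar(chr)
    for (len in unique(nchar(entries$pat))) {
      if (n < len) next
      kmers <- substring(chr, 1:(n - len + 1L), len:n)
      sel <- entries[nchar(entries$pat) == len, , drop = FALSE]
      hits <- which(kmers %in% sel$pat)
      for (h in hits) {
        rows <- sel[sel$pat == kmers[h], , drop = FALSE]
        res[[length(res) + 1L]] <-
          data.frame(probe_index = rows$probe_index,
                     chrom = names(genome)[ci], start = h - 1L,
                     strand = rows$strand, stringsAsFactors = FALSE)
      }
    }
  }
  ml <- if (length(res)) do.call(rbind, res) else
    data.frame(probe_index = integer(), chrom = character(),
               start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  ml <- unique(ml)
  ml <- ml[order(ml$probe_index, ml$chrom, ml$start, ml$strand,
                 method = "radix"), , drop = FALSE]
  rownames(ml) <- NULL
  ml
}

as_plain_matchlist <- function(ml) {
  data.frame(probe_index = as.integer(ml$probe_index),
             chrom = as.character(ml$chrom),
             start = as.integer(ml$start),
             strand = as.character(ml$strand),
             stringsAsFactors = FALSE)
}

# step-up Benjamini-Hochberg by definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# pattern set with guaranteed genome hits: half sampled from the genome,
# half random
rand_pattern_set <- function(genome, n_patterns, len) {
  chr <- genome[[sample(length(genome), 1L)]]
  n_plant <- ceiling(n_patterns / 2)
  starts <- sample(nchar(chr) - len + 1L, n_plant, replace = TRUE)
  planted <- substring(chr, starts, starts + len - 1L)
  random <- vapply(seq_len(n_patterns - n_plant), function(i) rand_dna(len),
                   character(1))
  pats <- c(planted, random)
  pats[!grepl("N", pats, fixed = TRUE)]
}
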