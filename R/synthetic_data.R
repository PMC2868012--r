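# Synthetic tiling-array data with known ground truth. One master seed
# fans out to per-component child seeds via fixed offsets, so adding a
# generator never perturbs existing fixtures. Default scale (one 200 kb
# chromosome, 20 bp probe spacing, 2 IP + 1 reference array) runs the
# whole pipeline in seconds.

child_seed <- function(seed, offset) as.integer(seed) + as.integer(offset)

#' Generate a random genome
#'
#' Chromosomes of iid bases with `P(G) + P(C) = gc_fraction`; fully
#' deterministic per seed.
#'
#' @param lengths named integer vector, chromosome name -> length in bp.
#' @param gc_fraction probability of a G or C at each base.
#' @param seed RNG seed.
#' @return Named character vector of chromosome sequences.
#' @export
generate_genome <- function(lengths, gc_fraction = 0.39, seed = 1L) {
  stopifnot(!is.null(names(lengths)), gc_fraction >= 0, gc_fraction <= 1)
  set.seed(child_seed(seed, 0L))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  vapply(as.integer(lengths), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = ""),
    character(1)) -> seqs
  names(seqs) <- names(lengths)
  seqs
}

random_kmer_absent <- function(L, genome, forbidden) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    rc <- revcomp(s)
    hits <- any(vapply(genome, function(chr)
      grepl(s, chr, fixed = TRUE) || grepl(rc, chr, fixed = TRUE),
      logical(1)))
    if (!hits && !(s %in% forbidden)) return(s)
  }
}

#' Plant probes in a genome with known match classes
#'
#' Tiles probes as genome substrings every `spacing` bp. A `dup_fraction`
#' of probes additionally get their sequence copied into an extra
#' chromosome (`chrDup`, copies separated by N runs so no junction
#' matches arise), making them expected "multiple" matchers; a
#' `scramble_fraction` are replaced by random sequences absent from the
#' final genome on both strands, making them expected "none".
#'
#' @param genome named character vector of chromosomes.
#' @param spacing probe start spacing in bp.
#' @param L probe length.
#' @param dup_fraction,scramble_fraction fractions (rounded to counts) of
#'   duplicated resp. scrambled probes.
#' @param seed RNG seed.
#' @return List with `genome` (input plus `chrDup` when duplications were
#'   planted), `probes` (`ProbeSet`) and `truth` (data frame `probe_id`,
#'   `chrom`, `start`, `strand`, `expected_class`).
#' @export
plant_probes <- function(genome, spacing = 20L, L = 25L, dup_fraction = 0,
                         scramble_fraction = 0, seed = 1L) {
  set.seed(child_seed(seed, 1L))
  rows <- list()
  for (chr in names(genome)) {
    starts <- seq(0L, nchar(genome[[chr]]) - L, by = spacing)
    rows[[chr]] <- data.frame(chrom = chr, start = starts,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  tab$probe_id <- sprintf("p%06d", seq_len(n))
  tab$sequence <- substring(genome[tab$chrom], tab$start + 1L,
                            tab$start + L)
  n_dup <- round(n * dup_fraction)
  n_scr <- round(n * scramble_fraction)
  special <- sample(n, n_dup + n_scr)
  dup_idx <- special[seq_len(n_dup)]
  scr_idx <- special[n_dup + seq_len(n_scr)]
  expected <- rep("unique", n)
  expected[dup_idx] <- "multiple"
  expected[scr_idx] <- "none"
  if (n_dup > 0L) {
    sep <- strrep("N", L)
    genome <- c(genome,
                chrDup = paste0(sep,
                                paste(tab$sequence[dup_idx], collapse = sep),
                                sep))
  }
  for (i in scr_idx) {
    tab$sequence[i] <- random_kmer_absent(L, genome, tab$sequence[-i])
  }
  probes <- probe_set(tab$probe_id, tab$sequence)
  truth <- data.frame(probe_id = tab$probe_id, chrom = tab$chrom,
                      start = tab$start, strand = "+",
                      expected_class = expected, stringsAsFactors = FALSE)
  truth$chrom[expected == "none"] <- NA_character_
  truth$start[expected == "none"] <- NA_integer_
  list(genome = genome, probes = probes, truth = truth)
}

default_intensity_model <- function() {
  list(baseline = 8, gc_slope = 0, position_effects = NULL,
       peak_blocks = NULL, noise_sd = 0.25, n_ip = 2L, n_ref = 1L)
}

#' Simulate probe intensities
#'
#' Generates raw-scale intensities from a log2-scale model: baseline +
#' GC-content slope + position-specific nucleotide effects + peak shift
#' (IP arrays only, probes inside planted blocks) + Gaussian noise.
#' Reference arrays share all sequence biases but carry no peak signal,
#' mirroring a control immunoprecipitation that captures unspecific
#' binding only.
#'
#' @param probes a `ProbeSet`.
#' @param anno optional `ProbeAnnotation` used to locate probes inside
#'   peak blocks (required when `model$peak_blocks` is set).
#' @param model list with elements `baseline`, `gc_slope`,
#'   `position_effects` (4 x L matrix, rows A/C/G/T, or NULL),
#'   `peak_blocks` (data frame `chrom`, `start`, `end`, `shift` in log2
#'   units, or NULL), `noise_sd`, `n_ip`, `n_ref`; missing elements take
#'   the defaults of a flat model with sd 0.25 and 2 IP + 1 reference
#'   array.
#' @param seed RNG seed.
#' @return List with `intensities` (raw-scale `IntensityMatrix`) and
#'   `truth` (the resolved model plus the seed and the per-probe true
#'   IP-minus-reference log2 shift).
#' @export
simulate_intensities <- function(probes, anno = NULL, model = list(),
                                 seed = 1L) {
  model <- utils::modifyList(default_intensity_model(), model)
  set.seed(child_seed(seed, 2L))
  n <- nrow(probes)
  L <- probe_length(probes)
  mu <- rep(model$baseline, n) + model$gc_slope * gc_content(probes$sequence)
  if (!is.null(model$position_effects)) {
    pe <- model$position_effects
    stopifnot(nrow(pe) == 4L, ncol(pe) == L)
    rownames(pe) <- c("A", "C", "G", "T")
    chars <- matrix(unlist(strsplit(probes$sequence, "", fixed = TRUE)),
                    ncol = L, byrow = TRUE)
    for (b in c("A", "C", "G", "T"))
      mu <- mu + (chars == b) %*% pe[b, ]
    mu <- as.numeric(mu)
  }
  shift <- rep(0, n)
  if (!is.null(model$peak_blocks)) {
    if (is.null(anno)) stop("peak_blocks require a probe annotation")
    pos <- match(probes$probe_id, anno$probe_id)
    for (bi in seq_len(nrow(model$peak_blocks))) {
      b <- model$peak_blocks[bi, ]
      inside <- !is.na(pos) & anno$chrom[pos] == b$chrom &
        anno$start[pos] >= b$start & anno$start[pos] < b$end
      shift[inside] <- shift[inside] + b$shift
    }
  }
  arrays <- c(paste0("ip_", seq_len(model$n_ip)),
              paste0("ref_", seq_len(model$n_ref)))
  role <- rep(c("ip", "reference"), c(model$n_ip, model$n_ref))
  vals <- sapply(seq_along(arrays), function(j) {
    m <- mu + if (role[j] == "ip") shift else 0
    m + stats::rnorm(n, sd = model$noise_sd)
  })
  vals <- matrix(vals, nrow = n, dimnames = list(probes$probe_id, arrays))
  im <- intensity_matrix(2^vals,
                         array_meta = data.frame(name = arrays, role = role,
                                                 condition = NA_character_,
                                                 stringsAsFactors = FALSE),
                         scale_tag = "raw")
  list(intensities = im,
       truth = c(model, list(seed = seed, true_shift = shift)))
}

#' Generate non-overlapping genomic features
#'
#' Walks each chromosome left to right, alternating random gene lengths
#' and gaps, assigning random strands, until the requested count or the
#' chromosome end is reached.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_features number of features to generate.
#' @param min_len,max_len feature length range in bp.
#' @param min_gap,max_gap intergenic gap range in bp.
#' @param seed RNG seed.
#' @return A `FeatureSet`.
#' @export
generate_features <- function(chrom_lengths, n_features = 60L,
                              min_len = 800L, max_len = 2500L,
                              min_gap = 200L, max_gap = 600L, seed = 1L) {
  set.seed(child_seed(seed, 3L))
  out <- list()
  i <- 0L
  for (chr in names(chrom_lengths)) {
    pos <- sample(min_gap:max_gap, 1L)
    while (i < n_features) {
      len <- sample(min_len:max_len, 1L)
      if (pos + len > chrom_lengths[[chr]] - min_gap) break
      i <- i + 1L
      out[[i]] <- data.frame(feature_id = sprintf("g%04d", i), chrom = chr,
                             start = pos, end = pos + len,
                             strand = sample(c("+", "-"), 1L),
                             stringsAsFactors = FALSE)
      pos <- pos + len + sample(min_gap:max_gap, 1L)
    }
    if (i >= n_features) break
  }
  df <- do.call(rbind, out)
  feature_set(df$feature_id, df$chrom, df$start, df$end, df$strand)
}

#' Simulate expression coupled to region occupancy
#'
#' `expression = slope * occupancy + N(0, noise_sd^2)` per feature, with
#' the occupancy taken from a designated transcript region, emulating
#' expression that tracks polymerase occupancy in that region.
#'
#' @param occupancy named per-feature numeric vector (the source-region
#'   occupancies).
#' @param slope linear coupling coefficient.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return List with `expression` (named numeric vector) and `truth`
#'   (slope, noise_sd, seed).
#' @export
simulate_expression <- function(occupancy, slope = 2, noise_sd = 0.5,
                                seed = 1L) {
  set.seed(child_seed(seed, 4L))
  expr <- slope * occupancy + stats::rnorm(length(occupancy), sd = noise_sd)
  names(expr) <- names(occupancy)
  list(expression = expr,
       truth = list(slope = slope, noise_sd = noise_sd, seed = seed))
}

default_dataset_config <- function() {
  list(chrom_lengths = c(chrI = 200000L),
       gc_fraction = 0.39,
       spacing = 20L, probe_length = 25L,
       dup_fraction = 0, scramble_fraction = 0,
       n_features = 60L,
       n_peaks = 25L, peak_width = 300L, peak_shift = 2,
       baseline = 8, gc_slope = 0.05, noise_sd = 0.25,
       n_ip = 2L, n_ref = 1L,
       expression_region = list(start_anchor = "TSS", start_offset = 500L,
                                end_anchor = "TTS", end_offset = -100L),
       expression_slope = 2, expression_noise_sd = 0.5)
}

#' Generate and write a complete synthetic dataset
#'
#' Fabricates every input the pipeline consumes -- genome FASTA, probe
#' table, intensity table, feature GFF, expression table -- plus a JSON
#' truth file recording the generating model. Peak blocks are placed at
#' evenly spaced, chromosome-interior positions; expression is coupled to
#' the true (noise-free) enrichment inside the configured transcript
#' region.
#'
#' @param out_dir output directory (created if needed).
#' @param config named list overriding entries of the default
#'   configuration (see Details in the package vignette).
#' @param seed master seed.
#' @return Invisibly, a list with the written `paths`, the in-memory
#'   objects and the `truth` list.
#' @export
simulate_dataset <- function(out_dir, config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_dataset_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(cfg$chrom_lengths, cfg$gc_fraction, seed = seed)
  planted <- plant_probes(genome, spacing = cfg$spacing,
                          L = cfg$probe_length,
                          dup_fraction = cfg$dup_fraction,
                          scramble_fraction = cfg$scramble_fraction,
                          seed = seed)
  genome <- planted$genome
  probes <- planted$probes
  anno <- probe_annotation(
    chrom = planted$truth$chrom[planted$truth$expected_class == "unique"],
    start = planted$truth$start[planted$truth$expected_class == "unique"],
    strand = "+",
    probe_id = planted$truth$probe_id[planted$truth$expected_class == "unique"])
  # evenly spaced peak blocks, away from the chromosome ends
  main_chr <- names(cfg$chrom_lengths)[1L]
  span <- cfg$chrom_lengths[[1L]] - 2L * cfg$peak_width
  centers <- round(seq(cfg$peak_width, span,
                       length.out = cfg$n_peaks))
  peak_blocks <- data.frame(chrom = main_chr,
                            start = as.integer(centers),
                            end = as.integer(centers + cfg$peak_width),
                            shift = cfg$peak_shift)
  sim <- simulate_intensities(probes, anno,
                              model = list(baseline = cfg$baseline,
                                           gc_slope = cfg$gc_slope,
                                           peak_blocks = peak_blocks,
                                           noise_sd = cfg$noise_sd,
                                           n_ip = cfg$n_ip,
                                           n_ref = cfg$n_ref),
                              seed = seed)
  features <- generate_features(cfg$chrom_lengths,
                                n_features = cfg$n_features, seed = seed)
  er <- cfg$expression_region
  region <- region_spec("expr_source", er$start_anchor, er$start_offset,
                        er$end_anchor, er$end_offset)
  occ_true <- region_mean_occupancy(anno, sim$truth$true_shift[
    match(anno$probe_id, probes$probe_id)], features, region)
  occ_true[is.na(occ_true)] <- 0
  expr <- simulate_expression(occ_true, slope = cfg$expression_slope,
                              noise_sd = cfg$expression_noise_sd,
                              seed = seed)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             probes = file.path(out_dir, "probes.tsv"),
             intensities = file.path(out_dir, "intensities.tsv"),
             features = file.path(out_dir, "features.gff"),
             expression = file.path(out_dir, "expression.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_fasta(genome, paths["genome"])
  write_probe_table(probes, paths["probes"])
  write_intensity_table(sim$intensities, paths["intensities"])
  write_gff(features, paths["features"])
  write_expression_table(expr$expression, paths["expression"])
  truth <- list(seed = seed, config = cfg,
                peak_blocks = peak_blocks,
                probe_classes = planted$truth,
                expression = expr$truth)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, genome = genome, probes = probes,
                 anno = anno, intensities = sim$intensities,
                 features = features, expression = expr$expression,
                 truth = truth))
}
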