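test_that("automaton construction matches hand-built tries", {
  a <- build_automaton(c("ACG", "GTT"))
  expect_equal(a$n_states, 7L) # root + 3 + 3, no shared prefixes
  b <- build_automaton("A")
  expect_equal(b$n_states, 2L)
  ml <- scan_genome(b, c(chr = "AAA"), both_strands = FALSE)
  expect_equal(ml$start, 0:2) # overlapping single-character matches
  # duplicate patterns share a terminal state but keep both indices
  d <- build_automaton(c("ACGT", "ACGT"))
  expect_equal(d$n_states, 5L)
  md <- scan_genome(d, c(chr = "ACGT"), both_strands = FALSE)
  expect_equal(sort(md$probe_index), c(1L, 2L))
  expect_error(build_automaton(character()), "empty")
  expect_error(build_automaton("ACN"), "illegal")
})

test_that("scan_genome reports forward and reverse matches in forward coordinates", {
  a <- build_automaton(c("ACG", "GTT"))
  ml <- scan_genome(a, c(chr = "AACGTT"), both_strands = FALSE)
  expect_equal(as_plain_matchlist(ml),
               data.frame(probe_index = 1:2, chrom = "chr", start = c(1L, 3L),
                          strand = "+", stringsAsFactors = FALSE))
  # revcomp("AAC") = "GTT" occurs at forward position 3
  b <- build_automaton("AAC")
  mb <- scan_genome(b, c(chr = "AACGTT"), both_strands = TRUE)
  expect_equal(mb$start, c(0L, 3L))
  expect_equal(mb$strand, c("+", "-"))
  # N interrupts runs
  c_ <- build_automaton("AA")
  expect_equal(nrow(scan_genome(c_, c(chr = "ANA"))), 0L)
  expect_error(scan_genome(c_, c(chr = "AXA")), "outside")
})

test_that("classification retains unique matchers and counts the rest", {
  genome <- c(chr1 = "AAAATTTTACGTACGACGGG")
  probes <- probe_set(c("once", "twice", "nowhere"),
                      c("AAAATT", "ACGTAC", "CCCCCC"))
  # "twice": plant the 6-mer again on a second chromosome
  genome <- c(genome, chr2 = paste0("ACGTAC", "TTTTTT"))
  anno <- remap_probes(probes, genome, both_strands = FALSE)
  expect_equal(unname(match_report(anno)[c("unique", "none", "multiple")]),
               c(1L, 1L, 1L))
  expect_equal(anno$probe_id, "once")
  expect_equal(anno$start, 0L)
})

test_that("a palindromic probe matching one locus counts as multiple", {
  # revcomp("ACGT") == "ACGT": one genomic occurrence is hit on both strands
  probes <- probe_set("pal", "ACGT")
  anno <- remap_probes(probes, c(chr = "TTACGTTT"), both_strands = TRUE)
  expect_equal(unname(match_report(anno)[["multiple"]]), 1L)
  expect_equal(nrow(anno), 0L)
})

test_that("probes containing N are excluded and counted as none", {
  probes <- probe_set(c("ok", "hasn"), c("ACGTA", "ACGNA"))
  anno <- remap_probes(probes, c(chr = "GACGTAGG"))
  expect_equal(unname(match_report(anno)[c("unique", "none")]), c(1L, 1L))
})

test_that("identical sequences on two probes are both unique when the locus is unique", {
  probes <- probe_set(c("p1", "p2"), c("ACGTACG", "ACGTACG"))
  anno <- remap_probes(probes, c(chr = "TTTACGTACGTTT"), both_strands = FALSE)
  expect_equal(unname(match_report(anno)[["unique"]]), 2L)
  expect_equal(anno$start, c(3L, 3L))
})

test_that("scan agrees with the naive k-mer oracle on random instances", {
  set.seed(42)
  for (trial in 1:20) {
    genome <- c(c1 = rand_dna(sample(500:3000, 1)),
                c2 = rand_dna(sample(200:1500, 1)))
    len <- sample(6:15, 1)
    pats <- rand_pattern_set(genome, sample(5:60, 1), len)
    a <- build_automaton(pats)
    for (bs in c(TRUE, FALSE)) {
      got <- as_plain_matchlist(scan_genome(a, genome, both_strands = bs))
      want <- naive_scan(pats, genome, both_strands = bs)
      expect_equal(got, want)
    }
  }
})

test_that("planted probes are recovered at their source coordinates", {
  genome <- generate_genome(c(chrA = 30000L, chrB = 12000L), seed = 7)
  planted <- plant_probes(genome, spacing = 40L, L = 25L, seed = 7)
  anno <- remap_probes(planted$probes, planted$genome)
  expect_equal(nrow(anno), nrow(planted$probes))
  m <- merge(as.data.frame(anno), planted$truth, by = "probe_id")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$chrom.x, m$chrom.y)
  expect_true(all(m$strand.x == "+"))
})

test_that("scanning is linear: at most 2 transitions per scanned base", {
  genome <- c(chr = rand_dna(20000))
  a <- build_automaton(c("ACGTACGTAC", "TTTTTTTTTT"))
  automaton_transitions(a, reset = TRUE)
  scan_genome(a, genome, both_strands = FALSE)
  expect_lte(automaton_transitions(a), 2 * nchar(genome[[1]]))
})

test_that("annotation files round-trip and are byte-deterministic", {
  genome <- generate_genome(c(chrA = 5000L, chrB = 3000L), seed = 3)
  planted <- plant_probes(genome, spacing = 100L, seed = 3)
  anno <- remap_probes(planted$probes, planted$genome)
  f1 <- tempfile(); f2 <- tempfile()
  write_corrected_annotation(anno, f1)
  write_corrected_annotation(anno, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_annotation(f1)
  expect_equal(as.data.frame(back), as.data.frame(anno))
  expect_equal(match_report(back), match_report(anno))
  # empty annotation: header-only file plus report
  empty <- probe_annotation(character(), integer(), character(), character(),
                            match_report = c(unique = 0L, none = 2L,
                                             multiple = 0L))
  f3 <- tempfile()
  write_corrected_annotation(empty, f3)
  expect_equal(readLines(f3), "chrom\tstart\tstrand\tprobe_id")
  expect_equal(match_report(read_annotation(f3))[["none"]], 2L)
})
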