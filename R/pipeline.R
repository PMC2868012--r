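# End-to-end workflow driver: remap -> normalize -> qc -> callpeaks ->
# profile -> correlate. Each stage writes its outputs plus a JSON report
# (counts, parameters, package version); outputs are byte-deterministic,
# so rerunning with an identical config reproduces identical files. Any
# suffix of stages can be run from the intermediates of a previous run.

PIPELINE_STAGES <- c("remap", "normalize", "qc", "callpeaks", "profile",
                     "correlate")

default_pipeline_params <- function() {
  list(remap = list(both_strands = TRUE),
       normalize = list(method = "rank-percentile-subtract"),
       peaks = list(w = 4L, fdr_q = 0.05, max_gap = 250L, min_probes = 4L),
       profiles = list(anchor = "TSS", upstream = 500L, downstream = 1500L,
                       bin_size = 50L),
       regions = NULL)
}

check_config <- function(config, stages) {
  req <- list(remap = c("genome", "probes"),
              normalize = c("probes", "intensities"),
              qc = c("probes", "intensities"),
              callpeaks = c("probes"),
              profile = c("features"),
              correlate = c("features", "expression"))
  if (is.null(config$out_dir))
    stop("config schema violation: field 'out_dir' is missing")
  need <- unique(unlist(req[stages]))
  for (f in need) {
    if (is.null(config$inputs[[f]]))
      stop("config schema violation: field 'inputs$", f, "' is missing")
    if (!file.exists(config$inputs[[f]]))
      stop("input file not found: inputs$", f, " = ", config$inputs[[f]])
  }
}

write_report <- function(out_dir, stage, report) {
  path <- file.path(out_dir, paste0("report_", stage, ".json"))
  report$stage <- stage
  report$package_version <- as.character(utils::packageVersion("tilechip"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the ChIP-chip analysis pipeline
#'
#' Executes the standard workflow on the files named in the configuration:
#' probe remapping, reference normalization, hybridization-bias QC,
#' moving-average peak calling, anchor-aligned profiles and
#' occupancy/expression correlation. Stages read the outputs of earlier
#' stages from `out_dir` when run separately, so any suffix of the stage
#' list can be rerun from intermediates.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure: `out_dir`, `inputs` (paths `genome`, `probes`,
#'   `intensities`, `features`, `expression`, optional `array_roles`
#'   mapping array names to `ip`/`reference`) and optional `params`
#'   overriding the stage defaults (`remap`, `normalize`, `peaks`,
#'   `profiles`, `regions`).
#' @param stages subset (suffix) of
#'   `c("remap", "normalize", "qc", "callpeaks", "profile", "correlate")`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  check_config(config, stages)
  params <- utils::modifyList(default_pipeline_params(),
                              if (is.null(config$params)) list() else config$params)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  probes <- if (!is.null(config$inputs$probes))
    read_probe_table(config$inputs$probes)
  L <- if (!is.null(probes)) probe_length(probes) else 25L
  anno_path <- file.path(out_dir, "annotation.tsv")
  enrich_path <- file.path(out_dir, "enrichment.tsv")

  anno <- NULL
  enrich <- NULL

  if ("remap" %in% stages) {
    genome <- read_fasta(config$inputs$genome)
    anno <- remap_probes(probes, genome,
                         both_strands = isTRUE(params$remap$both_strands))
    write_corrected_annotation(anno, anno_path)
    artifacts$annotation <- anno_path
    rep <- as.list(match_report(anno))
    rep$params <- params$remap
    artifacts$report_remap <- write_report(out_dir, "remap", rep)
  }

  load_intensities <- function() {
    im <- read_intensity_table(config$inputs$intensities, probes)
    roles <- config$inputs$array_roles
    if (!is.null(roles)) {
      im$array_meta$role <- unlist(roles)[im$array_meta$name]
    } else {
      # convention of the synthetic fixtures: ip_* / ref_* column names
      im$array_meta$role <- ifelse(grepl("^ip", im$array_meta$name), "ip",
                                   ifelse(grepl("^ref", im$array_meta$name),
                                          "reference", NA))
    }
    im
  }

  if ("normalize" %in% stages) {
    im <- load_intensities()
    nr <- normalize_enrichment(im, method = params$normalize$method)
    enrich <- nr$enrichment
    writeLines(c("probe_id\tenrichment",
                 paste(names(enrich), fmt_num(enrich), sep = "\t")),
               enrich_path, sep = "\n")
    artifacts$enrichment <- enrich_path
    artifacts$report_normalize <-
      write_report(out_dir, "normalize",
                   list(method = nr$provenance$method,
                        n_probes = length(enrich),
                        ip_arrays = nr$provenance$ip_arrays,
                        ref_arrays = nr$provenance$ref_arrays))
  }

  if ("qc" %in% stages) {
    im <- load_intensities()
    qdir <- file.path(out_dir, "qc")
    dir.create(qdir, showWarnings = FALSE)
    raw_first <- im$values[, 1L]
    write_qc_tables(raw_first, probes, file.path(qdir, "raw_"),
                    scale_tag = "raw")
    if (is.null(enrich) && file.exists(enrich_path)) {
      et <- utils::read.delim(enrich_path)
      enrich <- stats::setNames(et$enrichment, et$probe_id)
    }
    if (!is.null(enrich))
      write_qc_tables(as.numeric(enrich[probes$probe_id]), probes,
                      file.path(qdir, "normalized_"),
                      scale_tag = "enrichment")
    artifacts$qc_dir <- qdir
    artifacts$report_qc <- write_report(out_dir, "qc",
                                        list(n_probes = nrow(probes)))
  }

  if ("callpeaks" %in% stages) {
    if (is.null(anno)) anno <- read_annotation(anno_path)
    if (is.null(enrich)) {
      et <- utils::read.delim(enrich_path)
      enrich <- stats::setNames(et$enrichment, et$probe_id)
    }
    cp <- cmarrt_params(w = params$peaks$w, fdr_q = params$peaks$fdr_q,
                        max_gap = params$peaks$max_gap,
                        min_probes = params$peaks$min_probes)
    res <- cmarrt_run(enrich, anno, cp, probe_len = L)
    peaks_path <- file.path(out_dir, "peaks.bed")
    wig_path <- file.path(out_dir, "enrichment.wig")
    write_peaks_bed(res$peaks, peaks_path)
    write_track_wig(anno, res$track$S_star, wig_path, span = L)
    artifacts$peaks <- peaks_path
    artifacts$track <- wig_path
    artifacts$report_callpeaks <-
      write_report(out_dir, "callpeaks",
                   list(params = unclass(cp), n_peaks = nrow(res$peaks),
                        rho = res$rho$rho))
  }

  if ("profile" %in% stages || "correlate" %in% stages) {
    if (is.null(anno)) anno <- read_annotation(anno_path)
    if (is.null(enrich)) {
      et <- utils::read.delim(enrich_path)
      enrich <- stats::setNames(et$enrichment, et$probe_id)
    }
    features <- read_gff(config$inputs$features)
    sig <- as.numeric(enrich[anno$probe_id])

    if ("profile" %in% stages) {
      pp <- params$profiles
      apm <- align_profiles(anno, sig, features, anchor = pp$anchor,
                            upstream = pp$upstream,
                            downstream = pp$downstream,
                            bin_size = pp$bin_size)
      mp <- mean_profile(apm)
      qp <- quantile_profiles(apm)
      prof_path <- file.path(out_dir, "mean_profile.tsv")
      writeLines(c("bin_start\tmean\tn",
                   paste(mp$bin_start, fmt_num(mp$mean), mp$n, sep = "\t")),
                 prof_path, sep = "\n")
      qp_path <- file.path(out_dir, "quantile_profiles.tsv")
      writeLines(c(paste(c("bin_start", colnames(qp$matrix)),
                         collapse = "\t"),
                   paste(qp$bin_start,
                         apply(qp$matrix, 1L, function(r)
                           paste(fmt_num(r), collapse = "\t")),
                         sep = "\t")),
                 qp_path, sep = "\n")
      artifacts$mean_profile <- prof_path
      artifacts$quantile_profiles <- qp_path
      artifacts$report_profile <-
        write_report(out_dir, "profile",
                     list(params = pp, n_features = nrow(features),
                          n_empty = attr(apm, "n_empty")))
    }

    if ("correlate" %in% stages) {
      regions <- if (!is.null(params$regions))
        read_region_specs(params$regions)
      else
        read_region_specs(system.file("extdata", "regions_default.tsv",
                                      package = "tilechip"))
      occ <- region_occupancy_matrix(anno, sig, features, regions)
      expr <- read_expression_table(config$inputs$expression)
      corr <- region_expression_correlation(occ, expr)
      corr_path <- file.path(out_dir, "region_correlation.tsv")
      writeLines(c("region_id\tr\tn",
                   paste(corr$region_id, fmt_num(corr$r), corr$n,
                         sep = "\t")),
                 corr_path, sep = "\n")
      artifacts$region_correlation <- corr_path
      artifacts$report_correlate <-
        write_report(out_dir, "correlate",
                     list(n_regions = length(regions),
                          n_unmatched = attr(corr, "n_unmatched")))
    }
  }

  invisible(artifacts)
}
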