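# Correlation-aware moving-average peak calling. Probe-level enrichment
# scores on tiling arrays are autocorrelated along the genome (shared
# fragments hybridize to neighbouring probes), so the variance of a
# moving-average statistic must include covariance terms. The statistic:
#
#   z_j           standardized per-probe scores
#   S_i           mean of z over the 2w+1 probes centered at probe i
#   Var(S_i)      [m + 2 * sum_{k=1}^{m-1} (m-k) rho_k] / m^2   (window size m)
#   S*_i          S_i / sqrt(Var(S_i))
#
# with rho_k the lag-k autocorrelation of z (0 beyond max_lag). S* is
# referred to the standard normal upper tail, adjusted by Benjamini-
# Hochberg, and significant probes are merged into peak regions.

#' Standardize per-probe scores
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation, or the
#' robust variant `(x - median) / mad` (MAD scaled by 1.4826).
#'
#' @param x numeric vector (length >= 2, non-constant).
#' @param robust use median/MAD instead of mean/sd.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x, robust = FALSE) {
  if (sum(!is.na(x)) < 2L) stop("need at least two values to standardize")
  if (robust) {
    ctr <- stats::median(x, na.rm = TRUE)
    sc <- stats::mad(x, na.rm = TRUE)
  } else {
    ctr <- mean(x, na.rm = TRUE)
    sc <- stats::sd(x, na.rm = TRUE)
  }
  if (!is.finite(sc) || sc <= 0) stop("scores have zero or non-finite spread")
  (x - ctr) / sc
}

#' Estimate the autocorrelation of probe scores
#'
#' Standard sample autocorrelations of the z sequence in genomic probe
#' order, lags 1..max_lag. With several chromosomes, each chromosome with
#' at least `10 * max_lag` probes contributes, and the pooled estimate is
#' their length-weighted average; shorter chromosomes fall back to the
#' pooled value. If no chromosome qualifies, the concatenated sequence is
#' used.
#'
#' @param z numeric vector or per-chromosome list of numeric vectors.
#' @param max_lag number of lags to estimate.
#' @param exclude optional logical vector (or list matching `z`) marking
#'   probes to leave out, e.g. provisionally enriched windows whose signal
#'   would otherwise contaminate the null correlation estimate. Excluded
#'   probes split each chromosome into independent segments; segment
#'   autocorrelations are pooled by length.
#' @return An `AutocorrEstimate`: list with `rho` (length `max_lag`) and
#'   `max_lag`.
#' @export
estimate_autocorrelation <- function(z, max_lag, exclude = NULL) {
  max_lag <- as.integer(max_lag)
  if (max_lag == 0L)
    return(structure(list(rho = numeric(), max_lag = 0L),
                     class = "AutocorrEstimate"))
  if (!is.list(z)) {
    if (length(z) <= max_lag)
      stop("sequence must be longer than max_lag")
    z <- list(z)
    if (!is.null(exclude) && !is.list(exclude)) exclude <- list(exclude)
  }
  # split each chromosome into maximal runs of retained probes
  segments <- list()
  for (ci in seq_along(z)) {
    keep <- if (is.null(exclude)) rep(TRUE, length(z[[ci]])) else
      !exclude[[ci]]
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values))
      segments[[length(segments) + 1L]] <- z[[ci]][starts[ri]:ends[ri]]
  }
  acf1 <- function(x) as.vector(stats::acf(x, lag.max = max_lag,
                                           plot = FALSE,
                                           demean = TRUE)$acf)[-1L]
  lens <- lengths(segments)
  qualify <- lens >= 10L * max_lag & lens > max_lag
  if (!any(qualify)) qualify <- lens > max_lag
  if (!any(qualify)) stop("sequence must be longer than max_lag")
  rhos <- vapply(segments[qualify], acf1, numeric(max_lag))
  rho <- as.vector(matrix(rhos, nrow = max_lag) %*%
                     (lens[qualify] / sum(lens[qualify])))
  structure(list(rho = rho, max_lag = max_lag), class = "AutocorrEstimate")
}

#' Variance of a moving-average window mean
#'
#' Evaluates `[m + 2 * sum_{k=1}^{m-1} (m-k) rho_k] / m^2` for window size
#' `m`, with `rho_k = 0` beyond the estimated lags. If correlation
#' estimates drive the expression to zero or below, the variance is
#' floored at `1 / (4 m^2)` with a warning.
#'
#' @param m window size in probes.
#' @param rho numeric vector of autocorrelations (lag 1 upward).
#' @return Variance of the mean of `m` standardized, correlated scores.
#' @export
window_variance <- function(m, rho = numeric()) {
  if (m < 1L) stop("window size must be >= 1")
  s <- 0
  if (m > 1L && length(rho)) {
    k <- seq_len(m - 1L)
    rk <- numeric(m - 1L)
    take <- k <= length(rho)
    rk[take] <- rho[k[take]]
    s <- sum((m - k) * rk)
  }
  v <- (m + 2 * s) / m^2
  if (v <= 0) {
    warning("window variance <= 0 from autocorrelation estimates; flooring")
    v <- 1 / (4 * m^2)
  }
  v
}

#' Moving-average statistic along a chromosome track
#'
#' Computes the window mean `S` and its standardization `S_star` for every
#' probe. Windows are shrunk at chromosome ends to the available probes
#' and the variance is recomputed for the actual window size, so the track
#' keeps one entry per probe.
#'
#' @param z standardized per-probe scores, in genomic order.
#' @param positions strictly increasing 0-based probe starts.
#' @param params a `CmarrtParams`.
#' @param rho an `AutocorrEstimate` (or numeric vector of lag
#'   correlations).
#' @param chrom chromosome name recorded in the track.
#' @param probe_id optional probe ids.
#' @return A `StatTrack` with `p`/`p_adj` unset.
#' @export
moving_average_stat <- function(z, positions, params, rho = numeric(),
                                chrom = "chr", probe_id = NULL) {
  n <- length(z)
  if (n == 0L) stop("empty chromosome")
  stopifnot(length(positions) == n)
  if (n > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (inherits(rho, "AutocorrEstimate")) rho <- rho$rho
  w <- params$w
  lo <- pmax(1L, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w)
  m <- hi - lo + 1L
  cs <- cumsum(z)
  S <- (cs[hi] - c(0, cs)[lo]) / m
  vtab <- vapply(sort(unique(m)), function(mm) window_variance(mm, rho),
                 numeric(1))
  names(vtab) <- sort(unique(m))
  S_star <- S / sqrt(vtab[as.character(m)])
  if (is.null(probe_id)) probe_id <- paste0(chrom, "_", positions)
  stat_track(chrom = rep(chrom, n), position = positions,
             probe_id = probe_id, z = z, S = S,
             S_star = as.numeric(S_star))
}

#' Upper-tail normal p-values
#'
#' One-sided test for enrichment: `p = P(N(0,1) > s)`.
#'
#' @param s standardized statistic values.
#' @return Numeric p-values in `[0, 1]`.
#' @export
upper_tail_pvalues <- function(s) stats::pnorm(s, lower.tail = FALSE)

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1
#' (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Attach p-values to a statistic track
#'
#' Fills `p` with upper-tail normal probabilities of `S_star` and `p_adj`
#' with their BH adjustment computed across the whole track (all
#' chromosomes jointly).
#'
#' @param track a `StatTrack`.
#' @return The track with `p` and `p_adj` set.
#' @export
add_pvalues <- function(track) {
  track$p <- upper_tail_pvalues(track$S_star)
  track$p_adj <- bh_adjust(track$p)
  track
}

#' Merge significant probes into peak calls
#'
#' Probes with `p_adj <= fdr_q` seed peaks; consecutive seeds on one
#' chromosome merge while the gap between their probe intervals
#' (`next_start - (prev_start + L)`) is at most `max_gap` bp. Regions with
#' fewer than `min_probes` members are discarded. The reported interval is
#' `[first_start, last_start + L)`.
#'
#' @param track a `StatTrack` with `p_adj` computed.
#' @param params a `CmarrtParams`.
#' @param probe_len probe length L in bp.
#' @return A `PeakCall` data frame: `chrom`, `start`, `end`, `n_probes`,
#'   `peak_score` (mean member `S_star`), `min_p_adj`.
#' @export
call_peaks <- function(track, params, probe_len = 25L) {
  if (any(is.na(track$p_adj)))
    stop("track has no adjusted p-values; run add_pvalues() first")
  out <- list()
  for (chr in unique(track$chrom)) {
    tr <- track[track$chrom == chr, , drop = FALSE]
    seed <- which(tr$p_adj <= params$fdr_q)
    if (!length(seed)) next
    pos <- tr$position[seed]
    gap_break <- c(TRUE, pos[-1L] - (pos[-length(pos)] + probe_len) >
                     params$max_gap)
    grp <- cumsum(gap_break)
    for (g in unique(grp)) {
      idx <- seed[grp == g]
      if (length(idx) < params$min_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = tr$position[idx[1L]],
        end = tr$position[idx[length(idx)]] + probe_len,
        n_probes = length(idx),
        peak_score = mean(tr$S_star[idx]),
        min_p_adj = min(tr$p_adj[idx]),
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_probes = integer(), peak_score = numeric(),
               min_p_adj = numeric(), stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, method = "radix"), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("PeakCall", "data.frame")
  peaks
}

#' Run the full peak-calling pipeline on per-probe enrichment
#'
#' Orders the enrichment values along the probe annotation, standardizes
#' them genome-wide, estimates the score autocorrelation, computes the
#' variance-corrected moving-average statistic per chromosome, attaches
#' normal-tail p-values with BH adjustment across the genome, and merges
#' significant probes into peaks.
#'
#' @param enrichment named per-probe numeric vector (names = probe ids).
#' @param anno a `ProbeAnnotation`.
#' @param params a `CmarrtParams`.
#' @param probe_len probe length L in bp.
#' @param robust standardize with median/MAD instead of mean/sd.
#' @param refine_acf re-estimate the autocorrelation after excluding
#'   provisionally significant windows (two-pass). Enriched regions carry
#'   genuine serial correlation that is not part of the null model; leaving
#'   them in inflates the variance correction and costs power.
#' @return List with elements `track` (`StatTrack`), `peaks` (`PeakCall`)
#'   and `rho` (`AutocorrEstimate` used for the final track).
#' @export
cmarrt_run <- function(enrichment, anno, params = cmarrt_params(),
                       probe_len = 25L, robust = FALSE, refine_acf = TRUE) {
  x <- enrichment[anno$probe_id]
  if (any(is.na(names(x)) | is.na(x)))
    stop("enrichment is missing values for annotated probes")
  z <- standardize(as.numeric(x), robust = robust)
  chroms <- unique(anno$chrom)
  chr_f <- factor(anno$chrom, levels = chroms)
  z_by_chr <- split(z, chr_f)
  one_pass <- function(rho) {
    tracks <- lapply(chroms, function(chr) {
      sel <- anno$chrom == chr
      moving_average_stat(z[sel], anno$start[sel], params, rho,
                          chrom = chr, probe_id = anno$probe_id[sel])
    })
    track <- do.call(rbind, tracks)
    class(track) <- c("StatTrack", "data.frame")
    add_pvalues(track)
  }
  rho <- estimate_autocorrelation(z_by_chr, max_lag = params$max_lag)
  track <- one_pass(rho)
  if (refine_acf && params$max_lag > 0L) {
    seed <- track$p_adj <= params$fdr_q
    if (any(seed) && !all(seed)) {
      # excise seed windows (plus the window half-width) per chromosome
      pad <- params$w
      excl <- unlist(lapply(split(seed, chr_f), function(s) {
        hits <- which(s)
        out <- rep(FALSE, length(s))
        for (h in hits)
          out[max(1L, h - pad):min(length(s), h + pad)] <- TRUE
        out
      }), use.names = FALSE)
      rho2 <- tryCatch(
        estimate_autocorrelation(z_by_chr, max_lag = params$max_lag,
                                 exclude = split(excl, chr_f)),
        error = function(e) NULL)
      if (!is.null(rho2)) {
        rho <- rho2
        track <- one_pass(rho)
      }
    }
  }
  list(track = track,
       peaks = call_peaks(track, params, probe_len = probe_len),
       rho = rho)
}
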