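#' Effective number of independent tests (simpleM-style)
#'
#' Processes each chromosome in consecutive windows of \code{window} SNPs,
#' computes the composite-LD (Pearson) correlation matrix of mean-imputed
#' dosages per window, and takes the window's effective test count as the
#' smallest number of leading eigenvalues whose cumulative sum reaches a
#' fraction \code{C} of the total (eigenvalues clipped at zero first). The
#' genome-wide effective number of tests is the sum over windows and sets the
#' significance threshold alpha / M_eff.
#'
#' @param g a \code{genotype_matrix} (QC applied; no monomorphic variants).
#' @param C variance-explained cutoff (default 0.995).
#' @param window window size in SNPs (default 133).
#' @param alpha family-wise rate for the threshold (default 0.05).
#' @return list of class \code{meff_result}: \code{m_eff} (total),
#'   \code{threshold} (= alpha/m_eff), \code{windows} (data.frame chrom,
#'   first, last, n_snps, m_eff), \code{C}, \code{window}, \code{n_variants}.
#' @export
compute_meff <- function(g, C = 0.995, window = 133, alpha = 0.05) {
  if (C <= 0 || C > 1) stop("C must lie in (0, 1]")
  x <- impute_dosages(g)
  if (any(apply(x, 2, stats::var) == 0))
    stop("monomorphic variant(s) present; run qc_filter first")
  chroms <- unique(g$variants$chrom)
  rows <- list()
  for (ch in chroms) {
    vi <- which(g$variants$chrom == ch)
    vi <- vi[order(g$variants$pos[vi])]
    starts <- seq(1, length(vi), by = window)
    for (s in starts) {
      idx <- vi[s:min(s + window - 1, length(vi))]
      me <- if (length(idx) == 1L) 1L else {
        ev <- eigen(stats::cor(x[, idx, drop = FALSE]), symmetric = TRUE,
                    only.values = TRUE)$values
        ev <- pmax(ev, 0)
        which(cumsum(ev) / sum(ev) >= C - 1e-12)[1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, first = idx[1], last = idx[length(idx)],
        n_snps = length(idx), m_eff = as.integer(me))
    }
  }
  windows <- do.call(rbind, rows)
  m_eff <- sum(windows$m_eff)
  structure(list(m_eff = m_eff, threshold = alpha / m_eff,
                 windows = windows, C = C, window = window,
                 n_variants = nrow(g$variants), alpha = alpha),
            class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf(
    "meff_result: M_eff = %d of %d variants (C = %.3f); threshold %.3g\n",
    x$m_eff, x$n_variants, x$C, x$threshold))
  invisible(x)
}

#' Benjamini-Hochberg adjustment with an effective-test-count override
#'
#' Standard step-up adjusted p-values, with the total test count optionally
#' overridden: the GWA stage adjusts with m = M_eff rather than the number of
#' markers tested, while enrichment adjusts with m = number of tested terms.
#' Values are clipped at 1 and monotone in rank.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param m_override total number of tests m (default: length of the vector).
#'   Must be at least the number of p-values supplied.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues, m_override = NULL) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- if (is.null(m_override)) length(pvalues) else m_override
  if (m < length(pvalues))
    stop("m_override must be >= the number of p-values")
  stats::p.adjust(pvalues, method = "BH", n = m)
}

#' Significance thresholds used for hit reporting
#'
#' @param genome_wide adjusted genome-wide threshold; the study value is
#'   0.6e-6 (0.05 / M_eff for its panel); by default derived from a supplied
#'   \code{meff_result}.
#' @param secondary fallback threshold used per trait when nothing reaches
#'   genome-wide significance (default 1e-4).
#' @param raw nominal threshold defining "raw" associated SNPs (default 0.05).
#' @param meff optional \code{meff_result} from which to take genome_wide.
#' @return list of class \code{threshold_set}.
#' @export
threshold_set <- function(genome_wide = 0.6e-6, secondary = 0.1e-3,
                          raw = 0.05, meff = NULL) {
  if (!is.null(meff)) {
    genome_wide <- meff$threshold
    # small panels can push 0.05/M_eff above the fallback tier; the secondary
    # tier then collapses onto the genome-wide one
    secondary <- max(secondary, genome_wide)
  }
  if (!(raw >= secondary && secondary >= genome_wide))
    stop("thresholds must satisfy raw >= secondary >= genome_wide")
  structure(list(genome_wide = genome_wide, secondary = secondary, raw = raw),
            class = "threshold_set")
}

#' Tiered classification of association results
#'
#' Labels each marker genome_wide / secondary / raw / none by comparing its p
#' against a \code{threshold_set} (all comparisons inclusive). The secondary
#' tier follows the per-trait fallback rule: it is only reported for a trait
#' when no marker of that trait reaches the genome-wide threshold.
#'
#' @param results scan data.frame (needs columns trait, p).
#' @param thresholds a \code{\link{threshold_set}}.
#' @return the input with an added \code{tier} factor column.
#' @export
classify_hits <- function(results, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  tier <- rep("none", nrow(results))
  p <- results$p
  tier[!is.na(p) & p <= thresholds$raw] <- "raw"
  for (tr in unique(results$trait)) {
    ti <- results$trait == tr & !is.na(p)
    gw <- ti & p <= thresholds$genome_wide
    if (any(gw)) {
      tier[gw] <- "genome_wide"
    } else {
      tier[ti & p <= thresholds$secondary] <- "secondary"
    }
  }
  results$tier <- factor(tier, levels = c("genome_wide", "secondary",
                                          "raw", "none"))
  results
}
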