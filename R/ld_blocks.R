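#' Two-locus EM haplotype frequency estimation from unphased genotypes
#'
#' All two-SNP genotype classes except the double heterozygote determine
#' their two haplotypes; the double heterozygote's phase is resolved by EM
#' over the AB/ab vs Ab/aB pairing. Samples missing either genotype are
#' excluded. Alleles are labelled by alternate-allele dosage (A/B = alt).
#'
#' @param g a \code{genotype_matrix}.
#' @param v1,v2 variant IDs or indices.
#' @param tol convergence tolerance on the max haplotype-frequency change.
#' @param max_iter EM iteration cap; non-convergence is flagged, not fatal.
#' @return list of class \code{pair_ld}: haplotype freqs p_AB/p_Ab/p_aB/p_ab,
#'   allele freqs, D, Dprime, r2, n_informative (chromosomes), expected
#'   haplotype counts, converged, iterations, loglik trace.
#' @export
em_haplotype_freqs <- function(g, v1, v2, tol = 1e-8, max_iter = 1000) {
  i1 <- if (is.character(v1)) match(v1, g$variants$id) else v1
  i2 <- if (is.character(v2)) match(v2, g$variants$id) else v2
  if (is.na(i1) || is.na(i2)) stop("variant not found")
  d1 <- g$dosages[, i1]; d2 <- g$dosages[, i2]
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (stats::var(d1) == 0 || stats::var(d2) == 0)
    stop("monomorphic variant; two-locus LD is undefined")
  n <- function(a, b) sum(d1 == a & d2 == b)
  fixed <- c(AB = 2 * n(2, 2) + n(2, 1) + n(1, 2),
             Ab = 2 * n(2, 0) + n(2, 1) + n(1, 0),
             aB = 2 * n(0, 2) + n(0, 1) + n(1, 2),
             ab = 2 * n(0, 0) + n(0, 1) + n(1, 0))
  ndh <- n(1, 1)
  chrom_total <- 2 * length(d1)
  p <- (fixed + ndh / 2) / chrom_total     # start: phase split 50/50
  ll <- numeric(0)
  it <- 0L; converged <- ndh == 0L
  repeat {
    it <- it + 1L
    cis <- p["AB"] * p["ab"]; trans <- p["Ab"] * p["aB"]
    alpha <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- fixed + ndh * c(alpha, 1 - alpha, 1 - alpha, alpha)
    p_new <- cnt / chrom_total
    ll <- c(ll, sum(fixed * log(pmax(p_new, 1e-300))) +
              ndh * log(pmax(2 * (p_new["AB"] * p_new["ab"] +
                                    p_new["Ab"] * p_new["aB"]), 1e-300)))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (ndh == 0L || delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  cis <- p["AB"] * p["ab"]; trans <- p["Ab"] * p["aB"]
  alpha <- if (cis + trans > 0) cis / (cis + trans) else 0.5
  counts <- fixed + ndh * c(alpha, 1 - alpha, 1 - alpha, alpha)
  pA <- p["AB"] + p["Ab"]; pB <- p["AB"] + p["aB"]
  D <- unname(p["AB"] - pA * pB)
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
    else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(
    v1 = g$variants$id[i1], v2 = g$variants$id[i2],
    p = p, counts = counts, pA = unname(pA), pB = unname(pB),
    D = D, Dprime = if (Dmax > 0) D / Dmax else 0,
    r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))),
    n_informative = chrom_total, n_double_het = ndh,
    converged = converged, iterations = it, loglik = ll
  ), class = "pair_ld")
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("pair_ld %s-%s: D' = %.3f, r2 = %.3f (%d chromosomes)\n",
              x$v1, x$v2, x$Dprime, x$r2, x$n_informative))
  invisible(x)
}

#' Likelihood-based confidence bounds on |D'| (Wall-Pritchard style)
#'
#' At fixed allele-frequency margins, haplotype frequencies are
#' reparameterized by |D'| on a grid over [0, 1] (in the sign of the
#' estimated D); the multinomial likelihood of the EM-expected haplotype
#' counts is evaluated on the grid and normalized, and the bounds are the
#' grid points where the cumulative likelihood mass crosses (1-conf)/2 and
#' 1-(1-conf)/2. This is the standard Haploview approximation for unphased
#' data.
#'
#' @param pair a \code{pair_ld}.
#' @param conf confidence level (default 0.90, the Gabriel-rule default).
#' @param grid_n number of |D'| grid points (default 1001).
#' @return named numeric c(ci_low, ci_high).
#' @export
dprime_ci <- function(pair, conf = 0.90, grid_n = 1001) {
  pA <- pair$pA; pB <- pair$pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic margin; D' confidence interval undefined")
  s <- if (pair$D >= 0) 1 else -1
  Dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
    else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- seq(0, 1, length.out = grid_n)
  cnt <- pair$counts
  ll <- vapply(dp, function(x) {
    D <- s * x * Dmax
    ph <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
            aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
    ph <- pmax(ph, 1e-12)
    sum(cnt * log(ph))
  }, 1)
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  lo_q <- (1 - conf) / 2
  ci_low <- dp[which(cw >= lo_q)[1]]
  ci_high <- dp[which(cw >= 1 - lo_q)[1]]
  c(ci_low = ci_low, ci_high = ci_high)
}

# classify one pair for the Gabriel rule: "strong", "recomb" or "uninformative"
classify_pair <- function(ci, strong_low, strong_high, recomb_high) {
  if (ci[["ci_low"]] >= strong_low && ci[["ci_high"]] >= strong_high)
    "strong"
  else if (ci[["ci_high"]] < recomb_high) "recomb"
  else "uninformative"
}

#' Gabriel-style confidence-interval LD blocks
#'
#' For every ordered variant pair in the region, two-locus EM haplotype
#' frequencies give a |D'| confidence interval; a pair is "strong LD" when
#' ci_low >= strong_low and ci_high >= strong_high, and shows "strong
#' evidence of recombination" when ci_high < recomb_high. A candidate block
#' is a run of variants whose outermost pair is strong and in which at least
#' \code{frac_strong} of the informative pairs are strong. Overlapping
#' candidates are resolved longest-first (ties: leftmost), the Haploview
#' behavior. Monomorphic variants are excluded up front.
#'
#' @param g a \code{genotype_matrix}.
#' @param region optional "chrom:start-end" (or list) restricting the scan;
#'   default: all variants (must then be a single chromosome).
#' @param strong_low,strong_high CI cut-offs for strong LD (defaults 0.70 and
#'   0.98).
#' @param recomb_high CI upper bound below which a pair evidences
#'   recombination (default 0.90).
#' @param frac_strong minimum fraction of informative pairs that must be
#'   strong (default 0.95).
#' @param conf CI confidence level (default 0.90).
#' @return list of class \code{ld_blocks}: \code{blocks} (data.frame chrom,
#'   first, last, start_pos, end_pos, n_variants, variant ids comma-joined)
#'   and \code{pairs} (data.frame of all pairwise D', CI, class).
#' @export
gabriel_blocks <- function(g, region = NULL, strong_low = 0.70,
                           strong_high = 0.98, recomb_high = 0.90,
                           frac_strong = 0.95, conf = 0.90) {
  if (!is.null(region)) {
    region <- parse_region(region)
    vi <- which(g$variants$chrom == region$chrom &
                  g$variants$pos >= region$start &
                  g$variants$pos <= region$end)
  } else {
    if (length(unique(g$variants$chrom)) > 1)
      stop("give a region, or a single-chromosome genotype matrix")
    vi <- seq_len(nrow(g$variants))
  }
  vi <- vi[order(g$variants$pos[vi])]
  mono <- vapply(vi, function(j)
    stats::var(g$dosages[, j], na.rm = TRUE) == 0, TRUE)
  vi <- vi[!mono]
  m <- length(vi)
  empty <- data.frame(chrom = character(), first = integer(),
                      last = integer(), start_pos = integer(),
                      end_pos = integer(), n_variants = integer(),
                      variants = character(), stringsAsFactors = FALSE)
  if (m < 2)
    return(structure(list(blocks = empty, pairs = NULL),
                     class = "ld_blocks"))
  cls <- matrix(NA_character_, m, m)
  prs <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      pr <- em_haplotype_freqs(g, vi[i], vi[j])
      ci <- dprime_ci(pr, conf = conf)
      cls[i, j] <- classify_pair(ci, strong_low, strong_high, recomb_high)
      prs[[length(prs) + 1L]] <- data.frame(
        v1 = pr$v1, v2 = pr$v2, Dprime = pr$Dprime, r2 = pr$r2,
        ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
        class = cls[i, j], stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, prs)
  # candidate runs: outermost pair strong, >= frac_strong of informative strong
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (!identical(cls[i, j], "strong")) next
      sub <- cls[i:j, i:j]
      v <- sub[upper.tri(sub)]
      inf <- sum(v != "uninformative")
      if (inf == 0L) next
      if (sum(v == "strong") / inf >= frac_strong)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (length(cand) == 0L)
    return(structure(list(blocks = empty, pairs = pairs),
                     class = "ld_blocks"))
  cmat <- do.call(rbind, cand)
  cmat <- cmat[order(-(cmat[, 2] - cmat[, 1]), cmat[, 1]), , drop = FALSE]
  taken <- rep(FALSE, m)
  rows <- list()
  for (r in seq_len(nrow(cmat))) {
    i <- cmat[r, 1]; j <- cmat[r, 2]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    idx <- vi[i:j]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$variants$chrom[idx[1]], first = idx[1],
      last = idx[length(idx)], start_pos = g$variants$pos[idx[1]],
      end_pos = g$variants$pos[idx[length(idx)]],
      n_variants = length(idx),
      variants = paste(g$variants$id[idx], collapse = ","),
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  blocks <- blocks[order(blocks$start_pos), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, pairs = pairs), class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf("ld_blocks: %d block(s)\n", nrow(x$blocks)))
  if (nrow(x$blocks))
    print(x$blocks[, c("chrom", "start_pos", "end_pos", "n_variants")],
          row.names = FALSE)
  invisible(x)
}

#' Write LD blocks as a BED file (0-based half-open)
#' @param lb an \code{ld_blocks} result.
#' @param path output path.
#' @export
write_blocks_bed <- function(lb, path) {
  b <- lb$blocks
  utils::write.table(
    data.frame(b$chrom, b$start_pos - 1L, b$end_pos,
               sprintf("block%d", seq_len(nrow(b)))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
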