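# Align phenotype rows to genotype samples, drop missing trait values,
# and prepare the rotated/whitened regression pieces shared by all scans.
prepare_mm <- function(g, pheno, trait, covariates, vc, grm,
                       extra_covar = NULL) {
  idx <- match(g$samples, pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table is missing sample(s): ",
                       paste(g$samples[is.na(idx)][1:3], collapse = ", "))
  ph <- pheno[idx, , drop = FALSE]
  y <- ph[[trait]]
  if (is.null(y)) stop("trait not in phenotype table: ", trait)
  ok <- !is.na(y)
  X <- build_design(ph, covariates)
  if (!is.null(extra_covar)) X <- cbind(X, extra_covar)
  if (is.null(vc)) {
    if (is.null(grm)) grm <- compute_grm(g)
    vc <- fit_reml(y, X, grm)
  }
  kept <- vc$rotation$samples_kept
  if (!identical(kept, which(ok)))
    stop("variance components were fitted on a different sample subset; ",
         "refit with the current trait/covariates")
  U <- vc$rotation$vectors
  d <- vc$rotation$values
  s <- 1 / sqrt(vc$lambda * d + 1)
  Xr <- X[ok, , drop = FALSE]
  Xr <- Xr[, qr(Xr)$pivot[seq_len(qr(Xr)$rank)], drop = FALSE]
  list(ok = ok, vc = vc,
       ytil = s * crossprod(U, y[ok]),
       Xtil = s * crossprod(U, Xr),
       rotate = function(M) s * crossprod(U, M[ok, , drop = FALSE]))
}

#' Single-marker kinship mixed-model association scan
#'
#' The per-marker test of the pipeline: variance components are estimated
#' once under the null (no-SNP) model, the phenotype covariance
#' sigma2_a G + sigma2_e I is then held fixed, and each variant's dosage is
#' tested by generalized least squares added to the fixed covariates
#' (EMMAX-style one-variance-fit approximation). The test is a 1-df Wald
#' chi-square, two-sided. With sigma2_a = 0 the scan reduces exactly to
#' ordinary least squares. Exact per-marker REML refitting is available
#' behind \code{per_snp_reml}.
#'
#' @param g a \code{genotype_matrix} (QC applied; missing dosages are
#'   mean-imputed for testing).
#' @param pheno phenotype table with \code{sample_id} and the trait column
#'   (already on the analysis scale, see \code{\link{preprocess_trait}}).
#' @param trait trait column name.
#' @param covariates fixed-effect covariate columns (default "year").
#' @param vc optional \code{variance_components} fitted under the null model
#'   with the same trait/covariates; fitted on the fly when NULL.
#' @param grm optional precomputed \code{grm} (used when vc is NULL).
#' @param variants optional variant IDs/indices to test (default all).
#' @param extra_covar optional numeric matrix of additional fixed covariates
#'   aligned to \code{g$samples} (used by the conditional scan).
#' @param per_snp_reml refit lambda by REML for every marker (slow, exact).
#' @return data.frame: variant_id, chrom, pos, trait, beta, se, wald, p,
#'   n, reason (NA p with reason "collinear" for degenerate markers), with
#'   attribute \code{"vc"} carrying the variance components used.
#' @export
mm_scan <- function(g, pheno, trait, covariates = "year", vc = NULL,
                    grm = NULL, variants = NULL, extra_covar = NULL,
                    per_snp_reml = FALSE) {
  vi <- seq_len(nrow(g$variants))
  if (!is.null(variants))
    vi <- if (is.character(variants)) match(variants, g$variants$id)
      else vi[variants]
  if (anyNA(vi)) stop("unknown variant ID(s) in `variants`")
  pm <- prepare_mm(g, pheno, trait, covariates, vc, grm, extra_covar)
  dos <- impute_dosages(g)[, vi, drop = FALSE]
  Wt <- pm$rotate(dos)
  Q <- qr(pm$Xtil)
  ry <- qr.resid(Q, pm$ytil)
  RW <- qr.resid(Q, Wt)
  n <- length(pm$ytil); p <- ncol(pm$Xtil)
  num <- colSums(RW * as.vector(ry))
  den <- colSums(RW^2)
  collinear <- den <= n * 1e-10
  beta <- ifelse(collinear, NA_real_, num / den)
  rss <- sum(ry^2) - ifelse(collinear, 0, beta * num)
  sigma2 <- rss / (n - p - 1)
  se <- ifelse(collinear, NA_real_, sqrt(sigma2 / den))
  wald <- (beta / se)^2
  pval <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  # guard exact zeros from underflow: p-values live in (0, 1]
  pval <- pmax(pval, .Machine$double.xmin)
  out <- data.frame(
    variant_id = g$variants$id[vi], chrom = g$variants$chrom[vi],
    pos = g$variants$pos[vi], trait = trait,
    beta = beta, se = se, wald = wald, p = pval, n = n,
    reason = ifelse(collinear, "collinear", NA_character_),
    stringsAsFactors = FALSE)
  if (per_snp_reml) {
    G <- if (inherits(grm, "grm")) grm$G else grm
    if (is.null(G)) stop("per_snp_reml requires `grm`")
    idx <- match(g$samples, pheno$sample_id)
    ph <- pheno[idx, , drop = FALSE]
    X0 <- build_design(ph, covariates)
    if (!is.null(extra_covar)) X0 <- cbind(X0, extra_covar)
    for (k in seq_along(vi)) {
      if (collinear[k]) next
      Xk <- cbind(X0, snp = dos[, k])
      vck <- fit_reml(ph[[trait]], Xk, G)
      sc <- mm_scan(g, pheno, trait, covariates, vc = vck,
                    variants = vi[k], extra_covar = extra_covar)
      out[k, c("beta", "se", "wald", "p")] <-
        sc[1, c("beta", "se", "wald", "p")]
    }
  }
  attr(out, "vc") <- pm$vc
  out
}

# parse "chrom:start-end" or list(chrom=, start=, end=)
parse_region <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4) stop("region must look like 'chrom:start-end'")
    region <- list(chrom = m[2],
                   start = as.numeric(gsub(",", "", m[3])),
                   end = as.numeric(gsub(",", "", m[4])))
  }
  region
}

#' Conditional association scan
#'
#' Re-scans a region with one SNP's dosage added to the fixed effects, the
#' standard check for a single underlying QTL: if all other associated SNPs
#' in the region lose significance when the peak SNP is conditioned on, one
#' signal explains the region.
#'
#' @inheritParams mm_scan
#' @param condition_on variant ID to fit as a fixed covariate.
#' @param region optional "chrom:start-end" (or list) restricting the scan;
#'   default: the conditioning SNP's chromosome.
#' @return as \code{\link{mm_scan}}; the conditioning SNP is excluded.
#' @export
conditional_scan <- function(g, pheno, trait, condition_on, region = NULL,
                             covariates = "year", vc = NULL, grm = NULL) {
  ci <- match(condition_on, g$variants$id)
  if (is.na(ci)) stop("conditioning SNP not found: ", condition_on)
  cd <- impute_dosages(g)[, ci]
  if (stats::var(cd) == 0) stop("conditioning SNP is monomorphic")
  if (is.null(region))
    region <- list(chrom = g$variants$chrom[ci], start = 1,
                   end = max(g$variants$pos))
  region <- parse_region(region)
  vi <- which(g$variants$chrom == region$chrom &
                g$variants$pos >= region$start &
                g$variants$pos <= region$end)
  vi <- setdiff(vi, ci)
  if (length(vi) == 0L) {
    out <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), trait = character(), beta = numeric(),
                      se = numeric(), wald = numeric(), p = numeric(),
                      n = integer(), reason = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  # the added covariate changes the null model, so refit vc unless supplied
  mm_scan(g, pheno, trait, covariates, vc = vc, grm = grm, variants = vi,
          extra_covar = matrix(cd, ncol = 1,
                               dimnames = list(NULL, "condition_snp")))
}

#' Joint multi-SNP model with backward elimination
#'
#' Fits a set of SNPs (typically one gene's pruned uncorrelated set)
#' simultaneously in the kinship mixed model, then removes the least
#' significant SNP while any joint Wald p exceeds \code{alpha}. Ties are
#' broken by removing the SNP with the larger p, then the larger input
#' index, so the elimination trace is deterministic. SNPs aliased in the
#' joint design are removed first.
#'
#' @inheritParams mm_scan
#' @param snps character vector of variant IDs to fit simultaneously.
#' @param alpha retention threshold on the joint Wald p (default 0.05).
#' @param gene_id optional label carried into the result.
#' @return list of class \code{joint_model}: gene_id, trait, retained
#'   (data.frame variant_id, beta, se, wald, p), trace (data.frame step,
#'   removed, p_at_removal), n_start.
#' @export
joint_fit <- function(g, pheno, trait, snps, covariates = "year",
                      alpha = 0.05, vc = NULL, grm = NULL, gene_id = NA) {
  if (length(snps) == 0L) stop("empty SNP list")
  vi <- match(snps, g$variants$id)
  if (anyNA(vi)) stop("SNP(s) absent from genotype matrix: ",
                      paste(snps[is.na(vi)], collapse = ", "))
  pm <- prepare_mm(g, pheno, trait, covariates, vc, grm)
  dos <- impute_dosages(g)[, vi, drop = FALSE]
  W_all <- pm$rotate(dos)
  colnames(W_all) <- snps
  n <- length(pm$ytil)

  current <- seq_along(snps)
  trace <- data.frame(step = integer(), removed = character(),
                      p_at_removal = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    XX <- cbind(pm$Xtil, W_all[, current, drop = FALSE])
    fit <- stats::lm.fit(XX, as.vector(pm$ytil))
    p_fixed <- ncol(pm$Xtil)
    coefs <- fit$coefficients[p_fixed + seq_along(current)]
    aliased <- is.na(coefs)
    if (any(aliased)) {
      # drop the last aliased SNP (larger index first)
      drop_k <- max(which(aliased))
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, removed = snps[current[drop_k]], p_at_removal = NA_real_))
      current <- current[-drop_k]
      next
    }
    dfres <- n - fit$rank
    sigma2 <- sum(fit$residuals^2) / dfres
    R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    XtXinv <- chol2inv(R)
    se <- sqrt(sigma2 * diag(XtXinv))[p_fixed + seq_along(current)]
    wald <- (coefs / se)^2
    pv <- stats::pchisq(wald, 1, lower.tail = FALSE)
    if (all(pv <= alpha)) {
      retained <- data.frame(variant_id = snps[current], beta = unname(coefs),
                             se = unname(se), wald = unname(wald),
                             p = unname(pv), stringsAsFactors = FALSE)
      return(structure(list(gene_id = gene_id, trait = trait,
                            retained = retained, trace = trace,
                            n_start = length(snps)),
                       class = "joint_model"))
    }
    worst <- which(pv == max(pv))
    drop_k <- max(worst)  # ties: larger p first by construction, then index
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = snps[current[drop_k]],
                                     p_at_removal = pv[drop_k]))
    current <- current[-drop_k]
  }
  structure(list(gene_id = gene_id, trait = trait,
                 retained = data.frame(variant_id = character(),
                                       beta = numeric(), se = numeric(),
                                       wald = numeric(), p = numeric(),
                                       stringsAsFactors = FALSE),
                 trace = trace, n_start = length(snps)),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("joint_model [%s / %s]: %d of %d SNP(s) retained\n",
              x$gene_id, x$trait, nrow(x$retained), x$n_start))
  if (nrow(x$retained)) print(x$retained, row.names = FALSE)
  invisible(x)
}
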