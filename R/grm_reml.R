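# raw VanRaden method-1 GRM on an imputed dosage matrix (internal)
grm_from_dosages <- function(x) {
  p <- colMeans(x) / 2
  w <- sweep(x, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  tcrossprod(w) / denom
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = WW' / (2 * sum p(1-p)), with W the column-centered dosage matrix
#' (w = x - 2p per variant). Missing dosages are mean-imputed per variant.
#' Monomorphic variants carry no information and break the centering, so
#' their presence is an error pointing back at QC.
#'
#' @param g a \code{genotype_matrix} (QC applied).
#' @return list of class \code{grm}: \code{G} (n x n, sample-named),
#'   \code{freqs} (allele frequencies used), \code{n_variants}.
#' @export
compute_grm <- function(g) {
  x <- impute_dosages(g)
  p <- colMeans(x) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic variant(s) present; run qc_filter first")
  G <- grm_from_dosages(x)
  dimnames(G) <- list(g$samples, g$samples)
  structure(list(G = G, freqs = p, n_variants = ncol(x)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d variants, mean diagonal %.3f\n",
              nrow(x$G), x$n_variants, mean(diag(x$G))))
  invisible(x)
}

#' Fixed-effects design matrix from phenotype covariates
#'
#' Expands covariate columns into a model matrix with intercept; year and
#' breed_group are treated as categorical covariates by definition.
#'
#' @param pheno phenotype data.frame.
#' @param covariates covariate column names (empty: intercept only).
#' @return numeric design matrix.
#' @export
build_design <- function(pheno, covariates) {
  if (length(covariates) == 0L)
    return(matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)")))
  for (cc in intersect(covariates, c("year", "breed_group")))
    pheno[[cc]] <- factor(pheno[[cc]])
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  stats::model.matrix(f, data = pheno)
}

# REML profile log-likelihood at a given lambda = sigma2_a / sigma2_e,
# on pre-rotated data (ystar = U'y, Xstar = U'X, d = eigenvalues of G)
reml_loglik_lambda <- function(lambda, ystar, Xstar, d) {
  n <- length(ystar); p <- ncol(Xstar)
  w <- lambda * d + 1
  Xw <- Xstar / w
  XtWX <- crossprod(Xstar, Xw)
  XtWy <- crossprod(Xw, ystar)
  beta <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% beta
  rss <- sum(r^2 / w)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + (n - p) + sum(log(w)) +
                  determinant(XtWX, logarithm = TRUE)$modulus)
  as.numeric(ll)
}

#' REML variance components under the kinship mixed model
#'
#' Fits y = Xb + u + e with u ~ N(0, sigma2_a G), e ~ N(0, sigma2_e I) by
#' restricted maximum likelihood. A single spectral decomposition of G
#' reduces the problem to a one-dimensional profile likelihood in
#' lambda = sigma2_a/sigma2_e, optimized on the log scale over
#' [1e-5, 1e5] (golden-section search with parabolic refinement). Negative
#' eigenvalues from rank-deficient G (e.g. duplicate samples) are clipped
#' at zero.
#'
#' @param y numeric response; samples with missing y are dropped together
#'   with the matching rows of X and G.
#' @param X design matrix of fixed covariates (with intercept), or NULL for
#'   intercept only.
#' @param grm a \code{grm} object or a plain symmetric matrix aligned to y.
#' @return list of class \code{variance_components}: sigma2_a, sigma2_e,
#'   lambda, h2 = sigma2_a/(sigma2_a + sigma2_e), reml_loglik, boundary flag,
#'   and the eigen rotation (for reuse by \code{\link{mm_scan}}).
#' @export
fit_reml <- function(y, X = NULL, grm) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1) else X <- X[ok, , drop = FALSE]
  G <- G[ok, ok, drop = FALSE]
  if (!isTRUE(all.equal(G, t(G), tolerance = 1e-8)))
    stop("G must be symmetric")
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  e <- eigen(G, symmetric = TRUE)
  d <- pmax(e$values, 0)
  ystar <- crossprod(e$vectors, y)
  Xstar <- crossprod(e$vectors, X)

  obj <- function(loglam) -reml_loglik_lambda(exp(loglam), ystar, Xstar, d)
  opt <- stats::optimize(obj, lower = log(1e-5), upper = log(1e5),
                         tol = 1e-8)
  lambda <- exp(opt$minimum)
  boundary <- opt$minimum < log(1e-5) + 1e-3 || opt$minimum > log(1e5) - 1e-3
  # profile sigma2_e at the optimum
  w <- lambda * d + 1
  Xw <- Xstar / w
  beta <- solve(crossprod(Xstar, Xw), crossprod(Xw, ystar))
  r <- ystar - Xstar %*% beta
  s2e <- sum(r^2 / w) / (n - ncol(Xstar))
  # lambda at the lower boundary means sigma2_a ~ 0
  if (lambda <= 1e-5 * (1 + 1e-6)) lambda <- 0
  s2a <- lambda * s2e
  structure(list(
    sigma2_a = s2a, sigma2_e = s2e, lambda = lambda,
    h2 = s2a / (s2a + s2e), reml_loglik = -opt$objective,
    boundary = boundary,
    rotation = list(vectors = e$vectors[, , drop = FALSE], values = d,
                    samples_kept = which(ok))
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: sigma2_a = %.4f, sigma2_e = %.4f, h2 = %.3f%s\n",
    x$sigma2_a, x$sigma2_e, x$h2,
    if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}
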