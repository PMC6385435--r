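#' Rank-based inverse-normal transform
#'
#' Blom-style normal scores: qnorm((rank - 3/8) / (n + 1/4)), ranks averaged
#' over ties, missing values preserved. Strictly monotone in the data values.
#'
#' @param x numeric vector (may contain NA).
#' @return numeric vector of normal scores.
#' @export
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Fit a Johnson SU normalizing transform by quantile matching
#'
#' Slifker-Shapiro quantile selection: with z = 0.524, the four data
#' quantiles matching normal deviates -3z, -z, z, 3z give m, n, p spreads;
#' mn/p^2 > 1 selects the unbounded (SU) family, whose parameters follow in
#' closed form. Returns NULL when the SU fit is infeasible (the data look
#' bounded or lognormal, or parameters degenerate), in which case callers
#' fall back to the rank-based inverse-normal transform.
#'
#' @param x numeric vector, NA allowed.
#' @param z selection deviate (default 0.524).
#' @return list(gamma, delta, xi, lambda, transform) or NULL.
#' @export
fit_johnson_su <- function(x, z = 0.524) {
  x <- x[!is.na(x)]
  if (length(x) < 30) return(NULL)
  q <- stats::quantile(x, stats::pnorm(c(-3, -1, 1, 3) * z), names = FALSE,
                       type = 8)
  m <- q[4] - q[3]; nn <- q[2] - q[1]; p <- q[3] - q[2]
  if (p <= 0 || m <= 0 || nn <= 0) return(NULL)
  ratio <- m * nn / p^2
  if (!is.finite(ratio) || ratio <= 1.001) return(NULL)
  mp <- m / p; np <- nn / p
  delta <- 2 * z / acosh(0.5 * (mp + np))
  gamma <- delta * asinh((np - mp) / (2 * sqrt(ratio - 1)))
  lambda <- 2 * p * sqrt(ratio - 1) / ((mp + np - 2) * sqrt(mp + np + 2))
  xi <- (q[3] + q[2]) / 2 + p * (np - mp) / (2 * (mp + np - 2))
  if (!is.finite(delta) || !is.finite(lambda) || delta <= 0 || lambda <= 0)
    return(NULL)
  list(gamma = gamma, delta = delta, xi = xi, lambda = lambda,
       transform = function(v) gamma + delta * asinh((v - xi) / lambda))
}

#' Per-trait phenotype preprocessing
#'
#' The analysis-scale transforms applied before association: WBSF is analyzed
#' on the natural-log scale; marbling and connective tissue get a
#' Johnson-family normalization (SU by quantile matching, falling back to the
#' rank-based inverse-normal transform when the SU fit is infeasible); all
#' other traits pass through unchanged. Every transform is monotone
#' non-decreasing, so rank order is preserved.
#'
#' @param values numeric trait values (NA allowed).
#' @param trait_name one of the pipeline trait names; matching is on the
#'   lower-cased name ("wbsf", "marbling", "connective_tissue" trigger
#'   transforms).
#' @return numeric vector of transformed values with attribute
#'   \code{"transform"} naming the transform applied.
#' @export
preprocess_trait <- function(values, trait_name) {
  tn <- tolower(trait_name)
  if (tn == "wbsf") {
    if (any(values <= 0, na.rm = TRUE))
      stop("WBSF values must be positive for the log transform")
    out <- log(values)
    attr(out, "transform") <- "log"
    return(out)
  }
  if (tn %in% c("marbling", "connective_tissue")) {
    if (sum(!is.na(values)) < 30)
      stop("need >= 30 non-missing values to fit a normalization")
    fit <- fit_johnson_su(values)
    if (is.null(fit)) {
      out <- inverse_normal(values)
      attr(out, "transform") <- "inverse_normal"
    } else {
      out <- fit$transform(values)
      attr(out, "transform") <- "johnson_su"
    }
    return(out)
  }
  out <- values
  attr(out, "transform") <- "identity"
  out
}

#' Apply per-trait preprocessing to a phenotype table
#'
#' @param pheno phenotype data.frame (as \code{\link{read_phenotypes}}).
#' @param traits trait columns to transform (default: all non-covariate).
#' @return the table with transformed trait columns.
#' @export
preprocess_phenotypes <- function(pheno,
                                  traits = setdiff(names(pheno),
                                                   c("sample_id", "year",
                                                     "breed_group"))) {
  for (tr in traits) pheno[[tr]] <- as.numeric(preprocess_trait(pheno[[tr]], tr))
  pheno
}
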