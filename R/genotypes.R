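#' Construct a genotype matrix object
#'
#' The central genotype container of the pipeline: an n_samples x n_variants
#' allele-dosage matrix (counts of the alternate allele, 0/1/2, \code{NA} for
#' missing) together with per-variant metadata. Only biallelic SNPs are
#' supported; the commercial bovine chips this pipeline targets are biallelic
#' by design.
#'
#' @param samples character vector of sample IDs (unique).
#' @param variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}; \code{id} must be unique.
#' @param dosages integer/numeric matrix, \code{length(samples)} rows and
#'   \code{nrow(variants)} columns; non-missing entries in \{0, 1, 2\}.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(samples, variants, dosages) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(variants), is.matrix(dosages))
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs")
  if (anyDuplicated(variants$id))
    stop("duplicate variant IDs")
  if (any(variants$pos < 1))
    stop("variant positions must be >= 1")
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop("dosage dimensions do not match samples/variants")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "double"
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  variants$pos <- as.integer(variants$pos)
  structure(
    list(samples = samples, variants = variants, dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%d chromosome%s), %.2f%% missing\n",
    length(x$samples), nrow(x$variants),
    length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1) "" else "s",
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param g a \code{genotype_matrix}.
#' @param samples,variants index vectors (logical, integer, or IDs).
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- seq_along(g$samples)
  vi <- seq_len(nrow(g$variants))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample ID(s)")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, g$variants$id) else vi[variants]
    if (anyNA(vi)) stop("unknown variant ID(s)")
  }
  genotype_matrix(g$samples[si], g$variants[vi, , drop = FALSE],
                  g$dosages[si, vi, drop = FALSE])
}

#' Minor allele frequency per variant
#'
#' @param g a \code{genotype_matrix}.
#' @return numeric vector of MAF (on non-missing calls), NA for variants with
#'   no calls.
#' @export
maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Mean-impute missing dosages per variant
#'
#' Missing entries are replaced by the variant mean dosage, the standard
#' preparation for GRM and LD matrix algebra.
#'
#' @param g a \code{genotype_matrix}.
#' @return numeric matrix (no longer constrained to \{0,1,2\}).
#' @export
impute_dosages <- function(g) {
  x <- g$dosages
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x
}

#' Genotype quality control
#'
#' Applies the chip QC used throughout the pipeline: samples with call rate
#' below \code{sample_call_min} are dropped first, then variant MAF and call
#' rate are recomputed on the retained samples and variants failing either
#' filter are dropped. Both variant rules are strict ("lower/smaller than"),
#' so a variant at exactly \code{maf_min} is retained.
#'
#' @param g a \code{genotype_matrix}.
#' @param maf_min drop variants with MAF strictly below this (default 0.05).
#' @param var_call_min drop variants with call rate strictly below this
#'   (default 0.9).
#' @param sample_call_min drop samples with call rate strictly below this
#'   (default 0.85).
#' @return list with \code{genotypes} (filtered \code{genotype_matrix}) and
#'   \code{report} (counts dropped per criterion plus retained totals).
#' @export
qc_filter <- function(g, maf_min = 0.05, var_call_min = 0.9,
                      sample_call_min = 0.85) {
  if (nrow(g$variants) == 0L || length(g$samples) == 0L)
    stop("empty genotype matrix")
  sample_cr <- rowMeans(!is.na(g$dosages))
  keep_s <- sample_cr >= sample_call_min
  n_drop_samples <- sum(!keep_s)
  if (!any(keep_s)) stop("all samples dropped by call-rate filter")
  g2 <- subset_genotypes(g, samples = which(keep_s))

  var_cr <- colMeans(!is.na(g2$dosages))
  mafs <- maf(g2)
  drop_cr <- var_cr < var_call_min
  drop_maf <- !is.na(mafs) & mafs < maf_min
  drop_maf[is.na(mafs)] <- TRUE  # no calls at all
  keep_v <- !(drop_cr | drop_maf)
  if (!any(keep_v))
    stop("empty panel: all variants dropped by QC")
  out <- subset_genotypes(g2, variants = which(keep_v))
  report <- list(
    n_samples_in = length(g$samples),
    n_variants_in = nrow(g$variants),
    dropped_samples_call_rate = n_drop_samples,
    dropped_variants_call_rate = sum(drop_cr),
    dropped_variants_maf = sum(drop_maf & !drop_cr),
    n_samples_out = length(out$samples),
    n_variants_out = nrow(out$variants),
    maf_min = maf_min, var_call_min = var_call_min,
    sample_call_min = sample_call_min
  )
  list(genotypes = out, report = report)
}
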