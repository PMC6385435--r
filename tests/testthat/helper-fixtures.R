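# fixture builders shared across the suite

# wrap a plain dosage matrix (samples x variants) into a genotype_matrix
make_geno <- function(dos, chrom = "1", pos = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    samples = sprintf("s%03d", seq_len(n)),
    variants = data.frame(id = sprintf("v%03d", seq_len(m)),
                          chrom = rep(chrom, length.out = m), pos = pos,
                          ref = "A", alt = "G", stringsAsFactors = FALSE),
    dosages = dos)
}

# small, fast simulation config for unit tests
small_cfg <- function(...,
                      qtl_spec = data.frame(
                        gene_id = c("GENE005", "GENE012"),
                        trait = c("marbling", "cooking_loss"),
                        frac = 0.08, n_causal = c(3L, 2L)),
                      seed = 1) {
  sim_config(n_samples = 240, n_sensory = 180, n_variants = 600,
             n_chromosomes = 2, n_genes = 20, qtl_spec = qtl_spec,
             ..., seed = seed)
}

# variance components equivalent to no kinship (lambda = 0), for GLS = OLS
iid_vc <- function(n) {
  structure(list(sigma2_a = 0, sigma2_e = 1, lambda = 0, h2 = 0,
                 reml_loglik = NA_real_, boundary = FALSE,
                 rotation = list(vectors = diag(n), values = rep(1, n),
                                 samples_kept = seq_len(n))),
            class = "variance_components")
}

# phenotype table with just an intercept-worthy constant covariate
bare_pheno <- function(samples, y, year = 2010) {
  data.frame(sample_id = samples, year = year, breed_group = 1L, y = y,
             stringsAsFactors = FALSE)
}

# exact hypergeometric over-representation tail by enumerating all draws
# (independent oracle, N small)
hyper_over_enum <- function(k, K, n, N) {
  count <- 0
  total <- choose(N, n)
  for (x in max(0, n - (N - K)):min(n, K))
    if (x >= k) count <- count + choose(K, x) * choose(N - K, n - x)
  count / total
}

# reference Benjamini-Hochberg step-up written independently of p.adjust
bh_reference <- function(p, m = length(p)) {
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  i <- length(p):1
  pmin(1, cummin(m / i * p[o]))[ro]
}
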