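test_that("simulation is deterministic under the seed", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  pa <- simulate_phenotypes(a$genotypes, cfg)
  pb <- simulate_phenotypes(b$genotypes, cfg)
  expect_identical(pa$phenotypes, pb$phenotypes)
})

test_that("a two-haplotype founder pool forces |r| = 1 within blocks", {
  # one source population (all groups 100% Angus), pool of 2 haplotypes:
  # every polymorphic SNP pair in a block is a relabeling of the same split
  cfg <- sim_config(n_samples = 120, n_sensory = 100, n_variants = 100,
                    n_chromosomes = 1, n_genes = 3, founder_pool_size = 2,
                    admixture = rep(1, 6), qtl_spec = NULL, seed = 9)
  g <- simulate_genotypes(cfg)$genotypes
  lay <- sim_layout(cfg)
  for (b in 1:5) {
    cols <- lay$blocks$first[b]:lay$blocks$last[b]
    x <- g$dosages[, cols]
    x <- x[, apply(x, 2, var) > 0, drop = FALSE]
    if (ncol(x) < 2) next
    cc <- cor(x)
    expect_true(all(abs(abs(cc[upper.tri(cc)]) - 1) < 1e-12))
  }
})

test_that("between-block LD is far below within-block LD", {
  cfg <- small_cfg(seed = 13)
  g <- simulate_genotypes(cfg)$genotypes
  lay <- sim_layout(cfg)
  x <- impute_dosages(g)
  within <- c(); between <- c()
  for (b in 1:10) {
    c1 <- lay$blocks$first[b]:lay$blocks$last[b]
    c2 <- lay$blocks$first[b + 1]:lay$blocks$last[b + 1]
    p1 <- c1[apply(x[, c1], 2, var) > 0]; p2 <- c2[apply(x[, c2], 2, var) > 0]
    w <- cor(x[, p1]); within <- c(within, w[upper.tri(w)]^2)
    between <- c(between, as.vector(cor(x[, p1], x[, p2]))^2)
  }
  expect_gt(mean(within), 5 * mean(between))
  expect_lt(mean(between), 0.05)
})

test_that("realized heritability tracks the configured values", {
  # var(breeding values) / var(year-adjusted phenotype) on the latent scale
  h2m <- c(); h2w <- c()
  for (s in 1:4) {
    cfg <- small_cfg(seed = 20 + s)
    sim <- simulate_phenotypes(simulate_genotypes(cfg)$genotypes, cfg)
    yr <- factor(sim$phenotypes$year)
    for (tr in c("marbling", "wbsf")) {
      y <- sim$truth$latent[, tr]
      v <- var(resid(lm(y ~ yr)))
      r <- var(sim$truth$breeding_values[, tr]) / v
      if (tr == "marbling") h2m <- c(h2m, r) else h2w <- c(h2w, r)
    }
  }
  expect_lt(abs(mean(h2m) - 0.50), 0.07)
  expect_lt(abs(mean(h2w) - 0.17), 0.07)
})

test_that("breeding-value correlation between WBSF and tenderness is near -0.97", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_phenotypes(simulate_genotypes(cfg)$genotypes, cfg)
  bv <- sim$truth$breeding_values
  expect_lt(abs(cor(bv[, "wbsf"], bv[, "tenderness"]) - (-0.97)), 0.04)
})

test_that("observed-scale emission preserves the intended structure", {
  cfg <- small_cfg(seed = 8)
  g <- simulate_genotypes(cfg)$genotypes
  sim <- simulate_phenotypes(g, cfg)
  ph <- sim$phenotypes; ex <- sim$extras
  # WBSF is exactly the mean of the six core loads
  expect_equal(ph$wbsf, rowMeans(ex$wbsf_cores))
  # cooking loss is exactly 100 * (thaw - cooked) / thaw
  expect_equal(ph$cooking_loss,
               100 * (ex$weights$thaw - ex$weights$cooked) / ex$weights$thaw)
  # sensory traits: integer panel scores on the 1..8 scale, averaged, and
  # only for the sensory subset
  expect_true(all(ex$panel_scores$tenderness %in% 1:8))
  sens <- ph$sample_id %in% sim$truth$sensory_ids
  expect_equal(sum(sens), cfg$n_sensory)
  expect_true(all(is.na(ph$tenderness[!sens])))
  expect_equal(ph$tenderness[sens],
               unname(rowMeans(ex$panel_scores$tenderness)))
  # marbling within grading range
  expect_true(all(ph$marbling >= 100 & ph$marbling <= 999))
  # causal SNPs exist in the emitted genotype matrix
  expect_true(all(sim$truth$causal$variant_id %in% g$variants$id))
})

test_that("stronger QTLs yield stronger causal-SNP association", {
  pmed <- sapply(c(0.02, 0.12), function(f) {
    cfg <- sim_config(n_samples = 300, n_sensory = 200, n_variants = 400,
                      n_chromosomes = 1, n_genes = 10,
                      qtl_spec = data.frame(gene_id = "GENE004",
                                            trait = "marbling",
                                            frac = f, n_causal = 2L),
                      seed = 77)
    sim <- simulate_dataset(cfg)
    qc <- qc_filter(sim$genotypes)$genotypes
    ph <- preprocess_phenotypes(sim$phenotypes)
    sc <- mm_scan(qc, ph, "marbling")
    median(sc$p[sc$variant_id %in% sim$truth$causal$variant_id])
  })
  expect_lt(pmed[2], pmed[1])
})

test_that("emitted files are readable and clean of call-rate QC drops", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  write_sim_dataset(sim, dir)
  g <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_identical(g$dosages, sim$genotypes$dosages)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(nrow(ph), cfg$n_samples)
  genes <- read_bed_genes(file.path(dir, "genes.bed"))
  expect_equal(genes$start1, sim$annotation$genes$start1)
  go <- read_go_map(file.path(dir, "go_map.tsv"))
  expect_setequal(names(go$gene2go), names(sim$annotation$go$gene2go))
  bg <- read_background(file.path(dir, "background.txt"))
  expect_setequal(bg, sim$annotation$background)
  # no missingness simulated -> no call-rate-based drops (MAF drops are
  # expected for rare variants and are unrelated to missingness)
  qc <- qc_filter(g)
  expect_equal(qc$report$dropped_samples_call_rate, 0L)
  expect_equal(qc$report$dropped_variants_call_rate, 0L)
})

test_that("annotation planting behaves at the extremes", {
  cfg <- small_cfg(seed = 41)
  sim <- simulate_phenotypes(simulate_genotypes(cfg)$genotypes, cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  causal <- unique(sim$truth$causal$gene_id)
  # every causal gene carries the planted term and is in the background
  expect_true(all(vapply(causal, function(g)
    cfg$planted_term %in% ann$go$gene2go[[g]], TRUE)))
  expect_true(all(causal %in% ann$background))
  # zero background density: only causal genes carry the planted term
  cfg0 <- small_cfg(planted_term_bg_frac = 0, seed = 41)
  ann0 <- simulate_annotation(cfg0, sim$truth)
  carriers <- names(ann0$go$gene2go)[vapply(ann0$go$gene2go, function(v)
    cfg0$planted_term %in% v, TRUE)]
  expect_setequal(carriers, causal)
})

test_that("infeasible QTL configs are rejected", {
  expect_error(small_cfg(qtl_spec = data.frame(
    gene_id = "GENE005", trait = "flavor", frac = 0.2, n_causal = 1L)),
    "sum below h2")
  # more causal blocks than the panel can host
  cfg <- small_cfg(qtl_spec = data.frame(
    gene_id = "GENE005", trait = "marbling", frac = 0.05, n_causal = 50L))
  expect_error(simulate_genotypes(cfg), "not enough LD blocks")
  expect_error(sim_config(rg = matrix(c(1, 2, 2, 1), 2)), "semi-definite")
})
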