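test_that("with sigma2_a = 0 the mixed-model scan equals OLS exactly", {
  set.seed(15)
  n <- 60
  dos <- sapply(runif(12, 0.2, 0.8), function(p) rbinom(n, 2, p))
  g <- make_geno(dos)
  y <- rnorm(n)
  yr <- sample(2007:2009, n, replace = TRUE)
  ph <- data.frame(sample_id = g$samples, year = yr, breed_group = 1L, y = y)
  sc <- mm_scan(g, ph, "y", covariates = "year", vc = iid_vc(n))
  for (j in c(1, 5, 12)) {
    fit <- summary(lm(y ~ factor(yr) + dos[, j]))$coefficients
    expect_equal(sc$beta[j], fit[nrow(fit), 1], tolerance = 1e-10)
    expect_equal(sc$se[j], fit[nrow(fit), 2], tolerance = 1e-10)
  }
})

test_that("closed-form OLS slope is reproduced (beta = 2 on the 4-point design)", {
  g <- make_geno(matrix(c(0, 0, 1, 1), 4, 1))
  ph <- bare_pheno(g$samples, c(1, 2, 3, 4))
  sc <- mm_scan(g, ph, "y", covariates = character(), vc = iid_vc(4))
  expect_equal(sc$beta, 2.0)
})

test_that("p-values are invariant under affine rescaling of the trait", {
  set.seed(16)
  cfg <- small_cfg(seed = 16)
  sim <- simulate_dataset(cfg)
  qc <- qc_filter(sim$genotypes)$genotypes
  ph <- preprocess_phenotypes(sim$phenotypes)
  grm <- compute_grm(qc)
  vi <- seq(1, 200, by = 10)
  s1 <- mm_scan(qc, ph, "marbling", grm = grm, variants = vi)
  ph2 <- ph
  ph2$marbling <- 3.5 * ph2$marbling - 11
  s2 <- mm_scan(qc, ph2, "marbling", grm = grm, variants = vi)
  expect_equal(s2$p, s1$p, tolerance = 1e-6)
  expect_equal(s2$beta, 3.5 * s1$beta, tolerance = 1e-6)
})

test_that("collinear markers are reported as missing with a reason", {
  set.seed(17)
  n <- 30
  yr <- rep(c(2007, 2008), each = 15)
  dos <- cbind(as.numeric(yr == 2008),           # collinear with year
               rbinom(n, 2, 0.5))
  g <- make_geno(dos)
  ph <- data.frame(sample_id = g$samples, year = yr, breed_group = 1L,
                   y = rnorm(n))
  sc <- mm_scan(g, ph, "y", covariates = "year", vc = iid_vc(n))
  expect_true(is.na(sc$p[1]))
  expect_equal(sc$reason[1], "collinear")
  expect_false(is.na(sc$p[2]))
})

test_that("conditioning on the causal SNP silences its proxies", {
  # mirrors the single-QTL regional analysis: proxies in LD with the peak
  # lose significance once the peak is a fixed effect, while conditioning on
  # an uncorrelated SNP leaves the causal signal unchanged
  set.seed(52)
  pc_all <- c(); shift_ok <- 0; reps <- 10
  n <- 500
  for (s in 1:reps) {
    causal <- rbinom(n, 2, 0.5)
    # proxies: causal dosages with ~7% of entries redrawn (r2 ~ 0.85)
    prox <- sapply(1:3, function(i) {
      flip <- runif(n) < 0.05
      ifelse(flip, rbinom(n, 2, 0.5), causal)
    })
    far <- sapply(1:4, function(i) rbinom(n, 2, 0.5))
    g <- make_geno(cbind(causal, prox, far))
    stopifnot(all(cor(causal, prox)^2 > 0.8))
    y <- 0.35 * causal + rnorm(n)
    ph <- bare_pheno(g$samples, y)
    base <- mm_scan(g, ph, "y", covariates = character(), vc = iid_vc(n))
    cond <- conditional_scan(g, ph, "y", condition_on = "v001",
                             covariates = character(), vc = iid_vc(n))
    pc <- cond$p[match(c("v002", "v003", "v004"), cond$variant_id)]
    pc_all <- c(pc_all, pc[!is.na(pc)])
    # conditioning on an uncorrelated marker leaves the causal p in place
    cond2 <- conditional_scan(g, ph, "y", condition_on = "v008",
                              covariates = character(), vc = iid_vc(n))
    p0 <- base$p[base$variant_id == "v001"]
    p1 <- cond2$p[cond2$variant_id == "v001"]
    shift_ok <- shift_ok + (abs(log10(p1) - log10(p0)) < 0.5)
  }
  # each conditioned proxy is null: silenced in at least 90% of cases
  expect_gte(mean(pc_all > 0.05), 0.9)
  expect_gte(shift_ok, 0.9 * reps)
})

test_that("a region holding only the conditioning SNP yields an empty scan", {
  set.seed(19)
  dos <- sapply(runif(5, 0.3, 0.7), function(p) rbinom(40, 2, p))
  g <- make_geno(dos, pos = c(1000L, 2000L, 3000L, 50000L, 60000L))
  ph <- bare_pheno(g$samples, rnorm(40))
  out <- conditional_scan(g, ph, "y", condition_on = "v001",
                          region = "1:900-1500", covariates = character())
  expect_equal(nrow(out), 0L)
  expect_error(conditional_scan(make_geno(cbind(dos[, 1] * 0, dos[, 2])),
                                ph, "y", condition_on = "v001"),
               "monomorphic")
})

test_that("joint fit keeps independent causal SNPs and sheds noise", {
  set.seed(60)
  n <- 500
  keep_both <- 0; noise_dropped <- 0; reps <- 8
  for (r in 1:reps) {
    x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.4); x3 <- rbinom(n, 2, 0.3)
    y <- 0.35 * x1 + 0.35 * x2 + rnorm(n)
    g <- make_geno(cbind(x1, x2, x3))
    ph <- bare_pheno(g$samples, y)
    jf <- joint_fit(g, ph, "y", c("v001", "v002", "v003"),
                    covariates = character(), vc = iid_vc(n))
    keep_both <- keep_both +
      all(c("v001", "v002") %in% jf$retained$variant_id)
    noise_dropped <- noise_dropped + !("v003" %in% jf$retained$variant_id)
  }
  expect_gte(keep_both, reps - 1)
  expect_gte(noise_dropped, 0.8 * reps)
})

test_that("joint fit trace is deterministic and single significant SNPs survive", {
  set.seed(61)
  n <- 200
  x <- rbinom(n, 2, 0.5)
  y <- 0.5 * x + rnorm(n)
  g <- make_geno(cbind(x, rbinom(n, 2, 0.5)))
  ph <- bare_pheno(g$samples, y)
  j1 <- joint_fit(g, ph, "y", "v001", covariates = character(),
                  vc = iid_vc(n))
  expect_equal(j1$retained$variant_id, "v001")
  expect_equal(nrow(j1$trace), 0L)
  j2 <- joint_fit(g, ph, "y", c("v001", "v002"), covariates = character(),
                  vc = iid_vc(n))
  j3 <- joint_fit(g, ph, "y", c("v001", "v002"), covariates = character(),
                  vc = iid_vc(n))
  expect_identical(j2$trace, j3$trace)
  expect_error(joint_fit(g, ph, "y", character(), vc = iid_vc(n)), "empty")
  # aliased duplicate column is removed first, deterministically
  g2 <- make_geno(cbind(x, x))
  j4 <- joint_fit(g2, ph, "y", c("v001", "v002"), covariates = character(),
                  vc = iid_vc(n))
  expect_equal(j4$trace$removed[1], "v002")
  expect_equal(j4$retained$variant_id, "v001")
})
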