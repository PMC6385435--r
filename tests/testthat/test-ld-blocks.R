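# build a genotype matrix from explicit haplotype pairs at two loci;
# hap codes: 1=AB, 2=Ab, 3=aB, 4=ab (A/B = alt allele)
geno_from_haps <- function(pairs) {
  hap_alleles <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  d <- t(apply(pairs, 1, function(pr)
    hap_alleles[pr[1], ] + hap_alleles[pr[2], ]))
  make_geno(d)
}

test_that("EM reduces to direct counting without double heterozygotes", {
  # 20 AB|AB, 20 ab|ab, 5 Ab|Ab, 5 aB|aB -> counts AB=40, ab=40, Ab=10, aB=10
  pairs <- rbind(matrix(1, 20, 2), matrix(4, 20, 2),
                 matrix(2, 5, 2), matrix(3, 5, 2))
  g <- geno_from_haps(pairs)
  em <- em_haplotype_freqs(g, 1, 2)
  expect_equal(unname(em$p["AB"]), 0.4)
  expect_equal(em$pA, 0.5)
  expect_equal(em$D, 0.15)
  expect_equal(em$Dprime, 0.6)   # Dmax = 0.25
  expect_equal(em$iterations, 1L)
  expect_true(em$converged)
})

test_that("EM fixed point matches a profile-likelihood grid search", {
  # mixed fixture with double heterozygotes: margins are observed, so the
  # genotype likelihood has one free parameter (p_AB); grid-search it
  set.seed(37)
  pairs <- rbind(matrix(1, 30, 2), matrix(4, 25, 2),
                 cbind(rep(1, 20), rep(4, 20)),   # double hets
                 cbind(rep(2, 8), rep(3, 8)),     # double hets, trans
                 matrix(2, 7, 2), matrix(3, 10, 2))
  g <- geno_from_haps(pairs)
  em <- em_haplotype_freqs(g, 1, 2, tol = 1e-12)
  d1 <- g$dosages[, 1]; d2 <- g$dosages[, 2]
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  grid <- seq(max(0, pA + pB - 1) + 1e-6, min(pA, pB) - 1e-6,
              length.out = 20001)
  loglik <- vapply(grid, function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(p <= 0)) return(-Inf)
    hap_prob <- function(a, b) # P(genotype a,b) under HWE from hap freqs
      sum(sapply(1:4, function(h1) sapply(1:4, function(h2) {
        al <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
        if (al[h1, 1] + al[h2, 1] == a && al[h1, 2] + al[h2, 2] == b)
          p[h1] * p[h2] else 0
      })))
    sum(sapply(seq_along(d1), function(i) log(hap_prob(d1[i], d2[i]))))
  }, 1)
  expect_lt(abs(unname(em$p["AB"]) - grid[which.max(loglik)]), 1e-4)
  # EM log-likelihood never decreases
  expect_true(all(diff(em$loglik) >= -1e-10))
})

test_that("D' is invariant under joint allele relabeling and 1 at a zero class", {
  set.seed(38)
  pairs <- rbind(matrix(1, 25, 2), matrix(4, 25, 2),
                 cbind(rep(1, 10), rep(4, 10)), matrix(2, 10, 2))
  g <- geno_from_haps(pairs)
  em <- em_haplotype_freqs(g, 1, 2)
  flip <- g
  flip$dosages <- 2 - flip$dosages   # relabel both loci
  em2 <- em_haplotype_freqs(flip, 1, 2)
  expect_equal(em2$Dprime, em$Dprime, tolerance = 1e-9)
  # no aB haplotype present -> |D'| = 1
  expect_equal(abs(em$Dprime), 1, tolerance = 1e-9)
})

test_that("D' confidence bounds behave across information regimes", {
  # perfect LD, 50 samples = 100 chromosomes: strong-LD interval
  g <- geno_from_haps(rbind(matrix(1, 25, 2), matrix(4, 25, 2)))
  ci <- dprime_ci(em_haplotype_freqs(g, 1, 2))
  expect_gte(ci[["ci_low"]], 0.7)
  expect_gte(ci[["ci_high"]], 0.98)
  # linkage equilibrium at large n: recombination evidence
  set.seed(39)
  n <- 500
  g2 <- make_geno(cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5)))
  ci2 <- dprime_ci(em_haplotype_freqs(g2, 1, 2))
  expect_lt(ci2[["ci_high"]], 0.9)
  # two chromosomes: almost no information, interval spans nearly [0, 1]
  g3 <- make_geno(cbind(c(0, 2), c(0, 2)))
  ci3 <- dprime_ci(em_haplotype_freqs(g3, 1, 2))
  expect_lt(ci3[["ci_low"]], 0.3)
  expect_gte(ci3[["ci_high"]], 0.98)
  # monomorphic margin is an error at the CI stage
  expect_error(em_haplotype_freqs(make_geno(cbind(rep(1, 4), c(0, 1, 2, 1))),
                                  1, 2), "monomorphic")
})

test_that("degenerate regions yield no blocks; a perfect pair yields one", {
  set.seed(40)
  n <- 200
  # independent SNPs: equilibrium everywhere, no blocks
  g <- make_geno(sapply(runif(5, 0.3, 0.7), function(p) rbinom(n, 2, p)))
  gb <- gabriel_blocks(g)
  expect_equal(nrow(gb$blocks), 0L)
  # single pair in perfect LD: one block of 2
  x <- rbinom(n, 2, 0.5)
  g2 <- make_geno(cbind(x, x))
  gb2 <- gabriel_blocks(g2)
  expect_equal(nrow(gb2$blocks), 1L)
  expect_equal(gb2$blocks$n_variants, 2L)
  # fewer than 2 polymorphic variants: empty result
  g3 <- make_geno(cbind(x, rep(0, n)))
  expect_equal(nrow(gabriel_blocks(g3)$blocks), 0L)
})

test_that("blocks partition variants and ignore variants outside blocks", {
  set.seed(43)
  n <- 300
  x1 <- rbinom(n, 2, 0.5)
  x2 <- rbinom(n, 2, 0.4)
  noise <- rbinom(n, 2, 0.5)
  g <- make_geno(cbind(x1, x1, noise, x2, x2),
                 pos = c(1000L, 2000L, 3000L, 4000L, 5000L))
  gb <- gabriel_blocks(g)
  # blocks must not overlap
  if (nrow(gb$blocks) > 1) {
    expect_true(all(gb$blocks$start_pos[-1] >
                      gb$blocks$end_pos[-nrow(gb$blocks)]))
  }
  # removing the outside variant leaves the blocks unchanged
  g2 <- make_geno(cbind(x1, x1, x2, x2),
                  pos = c(1000L, 2000L, 4000L, 5000L))
  gb2 <- gabriel_blocks(g2)
  expect_equal(gb2$blocks$start_pos, gb$blocks$start_pos)
  expect_equal(gb2$blocks$end_pos, gb$blocks$end_pos)
})

test_that("block BED export uses 0-based half-open coordinates", {
  set.seed(44)
  x <- rbinom(100, 2, 0.5)
  g <- make_geno(cbind(x, x), pos = c(1500L, 2500L))
  gb <- gabriel_blocks(g)
  f <- tempfile(fileext = ".bed")
  write_blocks_bed(gb, f)
  bed <- read.table(f)
  expect_equal(bed$V2, 1499)
  expect_equal(bed$V3, 2500)
})
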