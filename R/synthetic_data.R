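#' Configuration for the Angus-Brahman-like synthetic dataset
#'
#' Defines the study conditions every downstream stage is exercised against:
#' a crossbred steer population of 672 animals in 6 breed-composition groups
#' (admixture proportions 0.9, 0.72, 0.625, 0.5, 0.3, 0.1 Angus), a
#' block-structured SNP panel drawn from per-block founder-haplotype pools,
#' seven correlated meat-quality traits with stated heritabilities (marbling
#' 0.50, tenderness 0.47, WBSF 0.17) and a -0.97 additive genetic correlation
#' between WBSF and tenderness, genes with planted QTLs, and a small GO
#' vocabulary with one planted enriched term.
#'
#' Sensory traits (tenderness, juiciness, connective tissue, flavor) are
#' recorded for \code{n_sensory} animals only, mirroring the 495-animal
#' sensory panel subset.
#'
#' @param n_samples number of steers (default 672).
#' @param n_sensory number of animals with sensory-panel records (default 495).
#' @param n_variants SNP panel size (default 3000; the real chip is ~221k,
#'   scaled down for desk-scale analysis).
#' @param n_chromosomes number of chromosomes the panel spans.
#' @param block_length_mean variants per LD block (blocks are this length
#'   exactly, so block boundaries are known to tests).
#' @param founder_pool_size haplotypes per founder pool per population;
#'   smaller pools give stronger within-block LD (size 2 forces |r| = 1).
#' @param within_block_r2 optional target within-block LD; when given, the
#'   pool size is set to \code{max(2, round(1/within_block_r2) + 1)}.
#' @param fst divergence between the two founder populations
#'   (Balding-Nichols allele-frequency model).
#' @param admixture Angus proportion per breed-composition group 1..6.
#' @param n_genes number of gene models tiling the chromosomes.
#' @param n_go_terms GO vocabulary size.
#' @param planted_term GO ID enriched among causal genes.
#' @param planted_term_bg_frac probability a non-causal gene also carries the
#'   planted term (background density).
#' @param background_frac fraction of non-causal genes included in the tissue
#'   background list (causal genes are always included).
#' @param qtl_spec data.frame(gene_id, trait, frac, n_causal): per gene and
#'   trait, the fraction of phenotypic variance explained and the number of
#'   causal SNPs (placed in distinct LD blocks of the gene). Defaults plant
#'   three multi-QTL genes, each affecting marbling, cooking loss and
#'   juiciness, mirroring the multi-trait candidate genes the pipeline is
#'   designed to flag.
#' @param h2 named per-trait heritability.
#' @param rg additive genetic correlation matrix of the polygenic effects
#'   (traits x traits, unit diagonal, positive semi-definite).
#' @param re_wbsf_tenderness residual correlation between WBSF and tenderness
#'   (same-steak measurements share non-genetic variation).
#' @param n_panelists sensory panel size per steak.
#' @param missing_rate genotype missingness rate (default 0: QC-clean panel).
#' @param seed integer seed; all three generators derive their streams from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 672,
                       n_sensory = 495,
                       n_variants = 3000,
                       n_chromosomes = 3,
                       block_length_mean = 10,
                       founder_pool_size = 4,
                       within_block_r2 = NULL,
                       fst = 0.15,
                       admixture = c(0.9, 0.72, 0.625, 0.5, 0.3, 0.1),
                       n_genes = 100,
                       n_go_terms = 60,
                       planted_term = "GO:0000001",
                       planted_term_bg_frac = 0.08,
                       background_frac = 0.9,
                       qtl_spec = default_qtl_spec(),
                       h2 = c(wbsf = 0.17, marbling = 0.50, cooking_loss = 0.30,
                              tenderness = 0.47, juiciness = 0.25,
                              connective_tissue = 0.25, flavor = 0.10),
                       rg = NULL,
                       re_wbsf_tenderness = -0.40,
                       n_panelists = 9,
                       missing_rate = 0,
                       seed = 1) {
  traits <- c("wbsf", "marbling", "cooking_loss", "tenderness", "juiciness",
              "connective_tissue", "flavor")
  if (!all(traits %in% names(h2))) stop("h2 must name all 7 traits")
  h2 <- h2[traits]
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (is.null(rg)) {
    rg <- diag(length(traits))
    dimnames(rg) <- list(traits, traits)
    rg["wbsf", "tenderness"] <- rg["tenderness", "wbsf"] <- -0.97
  }
  if (!isTRUE(all.equal(rg, t(rg))) || any(abs(diag(rg) - 1) > 1e-8))
    stop("rg must be symmetric with unit diagonal")
  if (min(eigen(rg, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("rg is not positive semi-definite")
  if (length(admixture) != 6 || any(admixture < 0 | admixture > 1))
    stop("admixture must give 6 proportions in [0, 1]")
  if (!is.null(within_block_r2))
    founder_pool_size <- max(2L, as.integer(round(1 / within_block_r2)) + 1L)
  if (founder_pool_size < 2) stop("founder_pool_size must be >= 2")
  if (n_sensory > n_samples) stop("n_sensory cannot exceed n_samples")
  qtl_spec <- validate_qtl_spec(qtl_spec, traits, h2)
  cfg <- list(
    n_samples = as.integer(n_samples), n_sensory = as.integer(n_sensory),
    n_variants = as.integer(n_variants),
    n_chromosomes = as.integer(n_chromosomes),
    block_length_mean = as.integer(block_length_mean),
    founder_pool_size = as.integer(founder_pool_size),
    fst = fst, admixture = admixture,
    n_genes = as.integer(n_genes), n_go_terms = as.integer(n_go_terms),
    planted_term = planted_term,
    planted_term_bg_frac = planted_term_bg_frac,
    background_frac = background_frac,
    qtl_spec = qtl_spec, traits = traits, h2 = h2, rg = rg,
    re_wbsf_tenderness = re_wbsf_tenderness,
    n_panelists = as.integer(n_panelists),
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted-QTL specification
#'
#' Three multi-QTL genes, each carrying three causal SNPs in distinct LD
#' blocks; the same SNPs act pleiotropically on marbling, cooking loss and
#' juiciness (5\% of phenotypic variance per gene-trait pair), the
#' multi-trait pattern the gene-trait network is designed to flag. QTLs are
#' kept off WBSF and tenderness so the polygenic -0.97 genetic correlation
#' between them is not diluted by trait-specific QTL variance.
#'
#' @return data.frame(gene_id, trait, frac, n_causal).
#' @export
default_qtl_spec <- function() {
  data.frame(
    gene_id = rep(c("GENE010", "GENE045", "GENE080"), each = 3),
    trait = rep(c("marbling", "cooking_loss", "juiciness"), 3),
    frac = 0.05,
    n_causal = 3L,
    stringsAsFactors = FALSE
  )
}

validate_qtl_spec <- function(q, traits, h2) {
  if (is.null(q) || nrow(as.data.frame(q)) == 0L)
    return(data.frame(gene_id = character(), trait = character(),
                      frac = numeric(), n_causal = integer()))
  q <- as.data.frame(q)
  req <- c("gene_id", "trait", "frac", "n_causal")
  if (!all(req %in% names(q))) stop("qtl_spec needs columns ",
                                    paste(req, collapse = ", "))
  if (!all(q$trait %in% traits)) stop("qtl_spec trait not among the 7 traits")
  if (any(q$frac <= 0) || any(q$n_causal < 1)) stop("invalid qtl_spec values")
  tot <- tapply(q$frac, q$trait, sum)
  bad <- names(tot)[tot[names(tot)] >= h2[names(tot)]]
  if (length(bad))
    stop("QTL variance fractions must sum below h2 for trait(s): ",
         paste(bad, collapse = ", "))
  q
}

#' Deterministic genome layout implied by a sim_config
#'
#' Blocks of exactly \code{block_length_mean} SNPs are laid across
#' chromosomes; genes occupy consecutive blocks (one block by default, enough
#' blocks to host their causal SNPs for planted genes) separated by
#' intergenic blocks, so gene boundaries, block boundaries and SNP positions
#' are all reproducible from the config alone without any random draw.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{variants} (id, chrom, pos, block), \code{blocks}
#'   (block, chrom, first/last variant index and position) and \code{genes}
#'   (gene_id, chrom, start1, end1, blocks list-column).
#' @export
sim_layout <- function(cfg) {
  L <- cfg$block_length_mean
  n_blocks <- cfg$n_variants %/% L
  if (n_blocks < 2L) stop("config implies fewer than 2 LD blocks")
  # blocks per chromosome, as even as possible
  per_chr <- rep(n_blocks %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- n_blocks %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L

  gene_ids <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  need <- rep(1L, cfg$n_genes)
  names(need) <- gene_ids
  if (nrow(cfg$qtl_spec)) {
    mx <- tapply(cfg$qtl_spec$n_causal, cfg$qtl_spec$gene_id, max)
    unknown <- setdiff(names(mx), gene_ids)
    if (length(unknown)) stop("qtl_spec gene(s) outside layout: ",
                              paste(unknown, collapse = ", "))
    need[names(mx)] <- pmax(need[names(mx)], as.integer(mx))
  }

  # walk chromosomes, alternating gene blocks and one intergenic block
  blk_chrom <- integer(n_blocks); blk_gene <- rep(NA_character_, n_blocks)
  b <- 0L; gi <- 1L
  for (ch in seq_len(cfg$n_chromosomes)) {
    left <- per_chr[ch]
    while (left > 0L) {
      if (gi <= cfg$n_genes && need[gi] + 1L <= left) {
        idx <- b + seq_len(need[gi])
        blk_gene[idx] <- gene_ids[gi]
        blk_chrom[idx] <- ch
        b <- b + need[gi]; left <- left - need[gi]; gi <- gi + 1L
        blk_chrom[b + 1L] <- ch  # intergenic separator
        b <- b + 1L; left <- left - 1L
      } else {
        blk_chrom[b + seq_len(left)] <- ch  # trailing intergenic blocks
        b <- b + left; left <- 0L
      }
    }
  }
  if (gi <= cfg$n_genes)
    stop("not enough LD blocks to place all genes; increase n_variants or ",
         "reduce n_genes")

  # positions: 1 kb SNP spacing; 4 kb gap inside genes, 20 kb between
  variants <- NULL
  blocks <- data.frame(block = seq_len(n_blocks), chrom = blk_chrom,
                       gene = blk_gene, first = NA_integer_,
                       last = NA_integer_, start_pos = NA_integer_,
                       end_pos = NA_integer_)
  vid <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    cursor <- 10000L
    for (bi in which(blk_chrom == ch)) {
      pos <- cursor + 1000L * seq_len(L)
      blocks$first[bi] <- vid + 1L
      blocks$last[bi] <- vid + L
      blocks$start_pos[bi] <- pos[1]; blocks$end_pos[bi] <- pos[L]
      variants <- rbind(variants, data.frame(
        id = sprintf("snp%06d", vid + seq_len(L)),
        chrom = as.character(ch), pos = pos, block = bi))
      vid <- vid + L
      same_gene <- !is.na(blk_gene[bi]) && bi < n_blocks &&
        identical(blk_gene[bi + 1L], blk_gene[bi])
      cursor <- pos[L] + if (same_gene) 4000L else 20000L
    }
  }
  genes <- do.call(rbind, lapply(gene_ids, function(gid) {
    bb <- blocks[!is.na(blocks$gene) & blocks$gene == gid, ]
    data.frame(gene_id = gid, chrom = as.character(bb$chrom[1]),
               start1 = min(bb$start_pos) - 500L,
               end1 = max(bb$end_pos) + 500L, stringsAsFactors = FALSE)
  }))
  list(variants = variants, blocks = blocks, genes = genes)
}

#' Simulate genotypes from per-block founder-haplotype pools
#'
#' Each LD block has, per founder population (Angus, Brahman), a small pool
#' of founder haplotypes; sample gametes pick one population (according to
#' the breed group's admixture proportion) and one pool haplotype per block,
#' with free recombination at block boundaries. Small pools force strong
#' within-block LD; between-block LD arises only from the admixture
#' structure. Population allele frequencies diverge by a Balding-Nichols
#' model at the configured Fst.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{genotypes} (a \code{genotype_matrix}) and
#'   \code{truth} (layout, per-sample breed group, haplotype origins).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  L <- cfg$block_length_mean
  K <- cfg$founder_pool_size
  n_blocks <- nrow(lay$blocks)

  # breed-composition groups, near-equal sizes, in order 1..6
  group <- sort(rep(1:6, length.out = n))
  theta <- cfg$admixture[group]

  dos <- matrix(0, n, n_blocks * L)
  for (b in seq_len(n_blocks)) {
    # founder haplotypes under infinite sites: each SNP mutates exactly once
    # on a random genealogy, so every within-block pair satisfies the
    # four-gamete condition (|D'| = 1), as in recombination-free blocks
    H <- matrix(0L, L + 1L, L)
    ord <- sample.int(L)
    for (m in seq_len(L)) {
      src <- sample.int(m, 1)
      H[m + 1L, ] <- H[src, ]
      H[m + 1L, ord[m]] <- 1L
    }
    # population pools: Balding-Nichols-style divergent haplotype weights
    pools <- lapply(1:2, function(pop) {
      wdir <- stats::rgamma(L + 1L, shape = (1 - cfg$fst) / cfg$fst / (L + 1L))
      if (all(wdir == 0)) wdir <- rep(1, L + 1L)
      H[sample.int(L + 1L, K, replace = TRUE, prob = wdir / sum(wdir)), ,
        drop = FALSE]
    })
    cols <- lay$blocks$first[b]:lay$blocks$last[b]
    for (gamete in 1:2) {
      pop <- 2L - stats::rbinom(n, 1, theta)     # 1 = Angus w.p. theta
      hap <- sample.int(K, n, replace = TRUE)
      dos[, cols] <- dos[, cols] + pools[[1]][hap, , drop = FALSE] *
        (pop == 1L) + pools[[2]][hap, , drop = FALSE] * (pop == 2L)
    }
  }
  if (cfg$missing_rate > 0)
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA
  samples <- sprintf("steer%04d", seq_len(n))
  variants <- data.frame(id = lay$variants$id, chrom = lay$variants$chrom,
                         pos = lay$variants$pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(samples, variants, dos)
  truth <- list(layout = lay, breed_group = group,
                admixture = theta, seed = cfg$seed)
  list(genotypes = g, truth = truth)
}

# genetic covariance factor: draws n x T matrix with cov(vec) = Sigma (x) G,
# using eigen decompositions of both
rmatnorm_kron <- function(eG, Sigma) {
  n <- length(eG$values)
  es <- eigen(Sigma, symmetric = TRUE)
  ds <- pmax(es$values, 0)
  Z <- matrix(stats::rnorm(n * ncol(Sigma)), n, ncol(Sigma))
  eG$vectors %*% (sqrt(pmax(eG$values, 0)) * Z) %*%
    (es$vectors %*% (sqrt(ds) * t(es$vectors)))
}

#' Simulate the seven meat-quality phenotypes on simulated genotypes
#'
#' Builds each trait as year effect + planted causal-SNP effects + polygenic
#' breeding value + residual on a unit-variance latent scale, then emits the
#' traits on their observed scales: WBSF as the average peak load (kg) of six
#' cores (analyzed on the log scale downstream), marbling as a right-skewed
#' 100-999 integer score, cooking loss as a percentage derived from thaw and
#' cooked weights, and the four sensory traits as averages of per-panelist
#' integer scores on 8-point scales for the sensory subset only. Polygenic
#' values across traits are drawn from the realized GRM with the configured
#' heritabilities and genetic correlation matrix.
#'
#' @param g a simulated \code{genotype_matrix}.
#' @param cfg the \code{sim_config} used to simulate it.
#' @return list with \code{phenotypes} (data.frame: sample_id, year,
#'   breed_group, 7 trait columns), \code{truth} (causal SNP table, true
#'   breeding values, latent traits, sensory sample IDs) and \code{extras}
#'   (per-core loads, panel scores, thaw/cooked weights).
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  set.seed(cfg$seed + 1L)
  n <- length(g$samples)
  traits <- cfg$traits
  Tn <- length(traits)
  dos <- impute_dosages(g)

  # realized GRM, rescaled to mean diagonal 1 so simulated variances are
  # on the intended scale under population structure
  poly <- which(apply(dos, 2, stats::var) > 0)
  G <- grm_from_dosages(dos[, poly, drop = FALSE])
  G <- G * (n / sum(diag(G)))
  eG <- eigen(G, symmetric = TRUE)

  # causal SNPs: within each planted gene, one per LD block (max-MAF SNP)
  causal <- NULL
  bv_qtl <- matrix(0, n, Tn, dimnames = list(NULL, traits))
  q <- cfg$qtl_spec
  for (gid in unique(q$gene_id)) {
    gblocks <- lay$blocks$block[!is.na(lay$blocks$gene) &
                                  lay$blocks$gene == gid]
    rows <- which(q$gene_id == gid)
    if (max(q$n_causal[rows]) > length(gblocks))
      stop("gene ", gid, " has fewer LD blocks than requested causal SNPs")
    picks <- vapply(gblocks, function(b) {
      cols <- lay$blocks$first[b]:lay$blocks$last[b]
      f <- colMeans(dos[, cols, drop = FALSE]) / 2
      m <- pmin(f, 1 - f)
      if (max(m) < 0.05)
        stop("gene ", gid, " block ", b, " has no common SNP to plant on")
      cols[which.max(m)]
    }, 1L)
    for (r in rows) {
      idx <- picks[seq_len(q$n_causal[r])]
      w <- scale(dos[, idx, drop = FALSE], center = TRUE, scale = FALSE)
      sdv <- apply(w, 2, stats::sd)
      beta <- sqrt(q$frac[r] / q$n_causal[r]) / sdv *
        sample(c(-1, 1), length(idx), replace = TRUE)
      bv_qtl[, q$trait[r]] <- bv_qtl[, q$trait[r]] + as.vector(w %*% beta)
      causal <- rbind(causal, data.frame(
        variant_id = g$variants$id[idx], gene_id = gid, trait = q$trait[r],
        beta = beta, frac_per_snp = q$frac[r] / q$n_causal[r],
        stringsAsFactors = FALSE))
    }
  }

  # polygenic breeding values: variance h2 - planted fraction, correlation rg
  f_tot <- stats::setNames(numeric(Tn), traits)
  if (nrow(q)) {
    tt <- tapply(q$frac, q$trait, sum)
    f_tot[names(tt)] <- tt
  }
  s_poly <- sqrt(pmax(cfg$h2 - f_tot, 0))
  Sg <- diag(s_poly) %*% cfg$rg %*% diag(s_poly)
  u_poly <- rmatnorm_kron(eG, Sg)
  colnames(u_poly) <- traits
  bv <- bv_qtl + u_poly

  # residuals: unit total phenotypic variance target, WBSF-tenderness
  # residual correlation from shared steak handling
  Re <- diag(Tn); dimnames(Re) <- list(traits, traits)
  Re["wbsf", "tenderness"] <- Re["tenderness", "wbsf"] <- cfg$re_wbsf_tenderness
  s_e <- sqrt(1 - cfg$h2)
  Se <- diag(s_e) %*% Re %*% diag(s_e)
  ce <- chol(Se + diag(1e-10, Tn))
  e <- matrix(stats::rnorm(n * Tn), n, Tn) %*% ce
  colnames(e) <- traits

  year <- sample(2007:2014, n, replace = TRUE)
  year_eff <- matrix(stats::rnorm(8 * Tn, 0, 0.25), 8, Tn,
                     dimnames = list(2007:2014, traits))
  latent <- bv + e + year_eff[as.character(year), ]

  # observed-scale emission -------------------------------------------------
  ph <- data.frame(sample_id = g$samples, year = year,
                   breed_group = attr_breed_group(cfg, n),
                   stringsAsFactors = FALSE)
  extras <- list()

  sdlog <- sqrt(log(1 + (1.15 / 4.30)^2))
  logw <- (log(4.30) - sdlog^2 / 2) + sdlog * latent[, "wbsf"]
  w_true <- exp(logw)
  cores <- matrix(stats::rnorm(n * 6, 0, 0.4), n, 6)
  cores <- cores - rowMeans(cores) + w_true      # average = target exactly
  cores <- pmax(cores, 0.2)
  ph$wbsf <- rowMeans(cores)
  extras$wbsf_cores <- cores

  sdm <- sqrt(log(1 + (90.03 / 425.57)^2))
  marb <- exp((log(425.57) - sdm^2 / 2) + sdm * latent[, "marbling"])
  ph$marbling <- pmin(pmax(round(marb), 100), 999)

  loss <- pmin(pmax(23.25 + 5.74 * latent[, "cooking_loss"], 1), 60)
  thaw <- stats::rnorm(n, 340, 25)
  cooked <- thaw * (1 - loss / 100)
  ph$cooking_loss <- 100 * (thaw - cooked) / thaw
  extras$weights <- data.frame(sample_id = g$samples, thaw = thaw,
                               cooked = cooked)

  sens_scale <- list(tenderness = c(5.28, 0.84), juiciness = c(5.01, 0.76),
                     connective_tissue = c(5.81, 0.83), flavor = c(5.56, 0.46))
  sens_ids <- sort(sample.int(n, cfg$n_sensory))
  extras$panel_scores <- list()
  for (tr in names(sens_scale)) {
    target <- sens_scale[[tr]][1] + sens_scale[[tr]][2] * latent[, tr]
    sc <- matrix(stats::rnorm(n * cfg$n_panelists, 0, 0.9),
                 n, cfg$n_panelists) + target
    sc <- pmin(pmax(round(sc), 1), 8)            # 8-point integer scale
    v <- rowMeans(sc)
    v[-sens_ids] <- NA
    ph[[tr]] <- v
    extras$panel_scores[[tr]] <- sc[sens_ids, , drop = FALSE]
  }
  ph <- ph[, c("sample_id", "year", "breed_group", traits)]

  truth <- list(causal = causal, breeding_values = bv, latent = latent,
                polygenic = u_poly, sensory_ids = g$samples[sens_ids],
                planted_term = cfg$planted_term, layout = lay,
                h2 = cfg$h2, f_qtl = f_tot)
  list(phenotypes = ph, truth = truth, extras = extras)
}

attr_breed_group <- function(cfg, n) sort(rep(1:6, length.out = n))

#' Simulate gene models, GO annotation and the tissue background list
#'
#' Gene models come from the deterministic layout (genes span whole LD
#' blocks, so block structure inside genes is known). GO terms are assigned
#' at random, except the planted term, which annotates every causal gene plus
#' a small background fraction of the rest. The background list contains all
#' causal genes plus a configurable fraction of non-causal genes, emulating a
#' tissue expression atlas.
#'
#' @param cfg a \code{sim_config}.
#' @param truth the truth component of \code{\link{simulate_phenotypes}} (for
#'   the causal gene set); NULL plants the term on the qtl_spec genes.
#' @return list with \code{genes} (data.frame gene_id, chrom, start1, end1),
#'   \code{go} (as \code{\link{read_go_map}}), \code{background} (character).
#' @export
simulate_annotation <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  set.seed(cfg$seed + 2L)
  genes <- lay$genes
  causal_genes <- if (!is.null(truth) && !is.null(truth$causal))
    unique(truth$causal$gene_id) else unique(cfg$qtl_spec$gene_id)

  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  if (!cfg$planted_term %in% terms) terms[1] <- cfg$planted_term
  other <- setdiff(terms, cfg$planted_term)
  gene2go <- lapply(genes$gene_id, function(gid) {
    k <- 1L + stats::rpois(1, 2)
    out <- sample(other, min(k, length(other)))
    planted <- gid %in% causal_genes ||
      stats::runif(1) < cfg$planted_term_bg_frac
    if (planted) out <- c(cfg$planted_term, out)
    out
  })
  names(gene2go) <- genes$gene_id
  term_names <- stats::setNames(
    ifelse(terms == cfg$planted_term, "planted pathway",
           paste("synthetic pathway", seq_along(terms))), terms)

  noncausal <- setdiff(genes$gene_id, causal_genes)
  background <- sort(c(causal_genes,
                       noncausal[stats::runif(length(noncausal)) <
                                   cfg$background_frac]))
  list(genes = genes, go = list(gene2go = gene2go, term_names = term_names),
       background = background)
}

#' Simulate a complete dataset (genotypes, phenotypes, annotation)
#'
#' Convenience wrapper running the three generators under one config.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{genotypes}, \code{phenotypes}, \code{annotation}
#'   (genes/go/background) and \code{truth}.
#' @export
simulate_dataset <- function(cfg) {
  gsim <- simulate_genotypes(cfg)
  psim <- simulate_phenotypes(gsim$genotypes, cfg)
  ann <- simulate_annotation(cfg, psim$truth)
  truth <- c(psim$truth, gsim$truth[c("breed_group", "admixture")])
  list(genotypes = gsim$genotypes, phenotypes = psim$phenotypes,
       annotation = ann, truth = truth, extras = psim$extras)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits VCF + dosage TSV genotypes, phenotype TSV, gene BED, GO TSV,
#' background text and a truth JSON, i.e. exactly what the readers in this
#' package consume.
#'
#' @param sim output of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_dosage_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_bed_genes(sim$annotation$genes, file.path(dir, "genes.bed"))
  go <- sim$annotation$go
  df <- do.call(rbind, lapply(names(go$gene2go), function(g)
    data.frame(gene_id = g, go_id = go$gene2go[[g]],
               name = unname(go$term_names[go$gene2go[[g]]]))))
  utils::write.table(df, file.path(dir, "go_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$annotation$background, file.path(dir, "background.txt"))
  jsonlite::write_json(
    list(causal = sim$truth$causal, planted_term = sim$truth$planted_term,
         sensory_ids = sim$truth$sensory_ids),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
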