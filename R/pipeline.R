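#' Run the full association-to-network pipeline
#'
#' Chains every stage on one dataset: genotype QC, phenotype preprocessing,
#' GRM, per-trait REML + single-marker mixed-model scan, effective-number-
#' of-tests thresholds and tiered hits, SNP-to-gene assignment with LD
#' pruning, tissue-restricted enrichment, the gene-trait network with
#' candidate multi-QTL genes, and joint multi-SNP models for the candidate
#' gene-trait pairs.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param phenotypes phenotype table (observed scale; preprocessing applied
#'   internally).
#' @param genes gene models data.frame (gene_id, chrom, start1, end1).
#' @param go GO annotation (gene2go + term_names).
#' @param background tissue background gene IDs.
#' @param traits traits to scan (default: all trait columns present).
#' @param covariates fixed covariates (default "year").
#' @param alpha_raw raw threshold (default 0.05).
#' @param flank,r2_max SNP-gene assignment and pruning parameters.
#' @param meff_window simpleM window (default 133).
#' @param n_candidates candidate multi-QTL genes for joint modelling.
#' @param stages run up to: "scan", "enrichment", or "all".
#' @return list with qc, phenotypes (analysis scale), grm, vc (per trait),
#'   assoc (all traits), meff, thresholds, hits, gene_sets, enrichment,
#'   overlap, network, top30, candidates, joint (list of joint_model).
#' @export
run_pipeline <- function(genotypes, phenotypes, genes = NULL, go = NULL,
                         background = NULL,
                         traits = intersect(
                           c("wbsf", "marbling", "cooking_loss", "tenderness",
                             "juiciness", "connective_tissue", "flavor"),
                           names(phenotypes)),
                         covariates = "year", alpha_raw = 0.05,
                         flank = 3000, r2_max = 0.3, meff_window = 133,
                         n_candidates = 5, stages = c("all", "enrichment",
                                                      "scan")) {
  stages <- match.arg(stages)
  qc <- qc_filter(genotypes)
  g <- qc$genotypes
  ph <- phenotypes[phenotypes$sample_id %in% g$samples, , drop = FALSE]
  ph <- preprocess_phenotypes(ph, traits)
  grm <- compute_grm(g)

  vc <- list(); assoc <- list()
  for (tr in traits) {
    sc <- mm_scan(g, ph, tr, covariates = covariates, grm = grm)
    vc[[tr]] <- attr(sc, "vc")
    assoc[[tr]] <- sc
  }
  assoc <- do.call(rbind, assoc)
  meff <- compute_meff(g, window = meff_window)
  thresholds <- threshold_set(meff = meff)
  hits <- classify_hits(assoc, thresholds)
  out <- list(qc = qc$report, phenotypes = ph, grm = grm, vc = vc,
              assoc = assoc, meff = meff, thresholds = thresholds,
              hits = hits)
  if (stages == "scan" || is.null(genes)) return(out)

  gene_sets <- build_gene_snp_sets(g, assoc, genes, alpha = alpha_raw,
                                   flank = flank, r2_max = r2_max)
  if (!is.null(background))
    gene_sets <- restrict_to_tissue(gene_sets, background)
  out$gene_sets <- gene_sets
  if (!is.null(go) && !is.null(background)) {
    out$enrichment <- enrich_traits(gene_sets, go, background)
    out$overlap <- overlap_summary(out$enrichment, gene_sets, go)
  }
  if (stages == "enrichment") return(out)

  net <- build_network(gene_sets, ph, traits = traits)
  out$network <- net
  out$top30 <- top_genes(net, 30)
  cand <- select_multi_qtl_candidates(net, m = n_candidates)
  out$candidates <- cand
  out$joint <- list()
  for (r in seq_len(nrow(cand$pairs))) {
    gid <- cand$pairs$gene_id[r]; tr <- cand$pairs$trait[r]
    snps <- gene_sets$variant_id[gene_sets$gene_id == gid &
                                   gene_sets$trait == tr & gene_sets$kept]
    out$joint[[paste(gid, tr, sep = ".")]] <-
      joint_fit(g, ph, tr, snps, covariates = covariates, vc = vc[[tr]],
                grm = grm, gene_id = gid)
  }
  out
}
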