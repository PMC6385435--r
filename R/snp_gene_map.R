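#' Assign SNPs to genes with a flanking window
#'
#' A variant belongs to a gene when it lies on the same chromosome within the
#' gene span extended by \code{flank} bases on each side (boundaries
#' inclusive, strand-agnostic). A variant may be assigned to several
#' overlapping genes.
#'
#' @param variants data.frame with id, chrom, pos (e.g.
#'   \code{g$variants}).
#' @param genes data.frame with gene_id, chrom, start1, end1 (1-based
#'   inclusive, as \code{\link{read_bed_genes}}).
#' @param flank symmetric flank in bases (default 3000).
#' @return named list: gene_id -> character vector of variant IDs (position
#'   order); genes with no assigned SNP map to an empty vector.
#' @export
assign_snps <- function(variants, genes, flank = 3000) {
  out <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (k in seq_len(nrow(genes))) {
    hit <- variants$chrom == genes$chrom[k] &
      variants$pos >= genes$start1[k] - flank &
      variants$pos <= genes$end1[k] + flank
    ids <- variants$id[hit]
    out[[k]] <- ids[order(variants$pos[hit])]
  }
  out
}

#' Extract "raw" associated SNPs per trait
#'
#' Raw association is the nominal inclusive rule p <= alpha applied to the
#' single-marker scan; raw SNPs are the inclusion unit of the enrichment
#' pipeline.
#'
#' @param assoc scan data.frame (variant_id, trait, p).
#' @param alpha nominal threshold (default 0.05).
#' @return named list: trait -> data.frame(variant_id, p) ordered by p
#'   ascending (ties by position then ID when available).
#' @export
raw_filter <- function(assoc, alpha = 0.05) {
  traits <- unique(assoc$trait)
  out <- stats::setNames(vector("list", length(traits)), traits)
  for (tr in traits) {
    a <- assoc[assoc$trait == tr & !is.na(assoc$p) & assoc$p <= alpha, ,
               drop = FALSE]
    o <- if ("pos" %in% names(a)) order(a$p, a$pos, a$variant_id)
      else order(a$p, a$variant_id)
    out[[tr]] <- a[o, , drop = FALSE]
  }
  out
}

#' Greedy LD pruning of a gene's raw SNPs
#'
#' Keeps the most significant SNP, then each subsequent SNP (in ascending p,
#' ties broken by position then ID) only if its squared Pearson dosage
#' correlation with every already-kept SNP is at most \code{r2_max}. When all
#' raw SNPs are mutually correlated the single best SNP survives, so the gene
#' enters downstream gene lists once.
#'
#' @param g a \code{genotype_matrix}.
#' @param raw_snps data.frame(variant_id, p) sorted by p ascending (as one
#'   element of \code{\link{raw_filter}}), or a character vector already in
#'   priority order.
#' @param r2_max LD threshold on r^2 (default 0.3; SNPs with r^2 strictly
#'   above it are treated as correlated).
#' @return character vector of kept variant IDs, in p order.
#' @export
prune_uncorrelated <- function(g, raw_snps, r2_max = 0.3) {
  ids <- if (is.data.frame(raw_snps)) raw_snps$variant_id else raw_snps
  if (length(ids) == 0L) return(character())
  vi <- match(ids, g$variants$id)
  if (anyNA(vi)) stop("SNP(s) absent from genotype matrix: ",
                      paste(ids[is.na(vi)], collapse = ", "))
  x <- impute_dosages(g)[, vi, drop = FALSE]
  kept <- 1L
  for (j in seq_along(ids)[-1]) {
    r2 <- suppressWarnings(stats::cor(x[, j], x[, kept, drop = FALSE]))^2
    r2[is.na(r2)] <- 0  # zero-variance column: uncorrelated by convention
    if (all(r2 <= r2_max)) kept <- c(kept, j)
  }
  ids[kept]
}

#' Build per-gene, per-trait raw and pruned SNP sets
#'
#' Combines SNP-to-gene assignment, raw filtering and LD pruning into the
#' gene-level unit used by enrichment and the gene-trait network: for each
#' trait and gene, the raw associated SNPs assigned to the gene and the
#' retained uncorrelated subset.
#'
#' @param g a \code{genotype_matrix}.
#' @param assoc scan results for one or more traits (rbind of
#'   \code{\link{mm_scan}} outputs).
#' @param genes gene models data.frame.
#' @param alpha raw threshold (default 0.05).
#' @param flank SNP-to-gene flank (default 3000).
#' @param r2_max pruning threshold (default 0.3).
#' @return data.frame with one row per (trait, gene, raw SNP): trait,
#'   gene_id, variant_id, p, kept (logical). Genes without raw SNPs are
#'   absent.
#' @export
build_gene_snp_sets <- function(g, assoc, genes, alpha = 0.05, flank = 3000,
                                r2_max = 0.3) {
  gene_map <- assign_snps(g$variants, genes, flank)
  raw <- raw_filter(assoc, alpha)
  rows <- list()
  for (tr in names(raw)) {
    rtab <- raw[[tr]]
    for (gid in names(gene_map)) {
      in_gene <- rtab[rtab$variant_id %in% gene_map[[gid]], , drop = FALSE]
      if (nrow(in_gene) == 0L) next
      kept_ids <- prune_uncorrelated(g, in_gene, r2_max)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, gene_id = gid, variant_id = in_gene$variant_id,
        p = in_gene$p, kept = in_gene$variant_id %in% kept_ids,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(trait = character(), gene_id = character(),
                      variant_id = character(), p = numeric(),
                      kept = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
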