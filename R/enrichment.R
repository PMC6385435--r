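#' Restrict gene-SNP sets to a tissue background
#'
#' Genes absent from the tissue background (e.g. not expressed in skeletal
#' muscle) are removed before gene lists are built; the same background is
#' the population of the hypergeometric test.
#'
#' @param gene_sets data.frame from \code{\link{build_gene_snp_sets}}.
#' @param background character vector of background gene IDs.
#' @return the filtered data.frame, with the background attached as an
#'   attribute.
#' @export
restrict_to_tissue <- function(gene_sets, background) {
  if (length(background) == 0L) stop("background list is empty")
  out <- gene_sets[gene_sets$gene_id %in% background, , drop = FALSE]
  if (nrow(gene_sets) > 0L && nrow(out) == 0L)
    stop("no gene with raw SNPs intersects the background list; ",
         "check that gene IDs use the same vocabulary")
  attr(out, "background") <- background
  out
}

#' Build a trait's multiplicity-expanded gene list
#'
#' A gene enters the list once per retained uncorrelated SNP, so genes with
#' several independent signals count several times; this is the weighting
#' that lets enrichment and the gene-trait network favor genes with possibly
#' multiple functional polymorphisms.
#'
#' @param gene_sets (tissue-restricted) data.frame from
#'   \code{\link{build_gene_snp_sets}}.
#' @param trait trait name.
#' @return list: \code{trait}, \code{entries} (character multiset of gene
#'   IDs), \code{n_list} (total entries incl. repeats), \code{counts}
#'   (named kept-SNP count per gene).
#' @export
build_gene_list <- function(gene_sets, trait) {
  gs <- gene_sets[gene_sets$trait == trait & gene_sets$kept, , drop = FALSE]
  counts <- table(gs$gene_id)
  entries <- rep(names(counts), as.integer(counts))
  if (length(entries) == 0L)
    warning("empty gene list for trait ", trait,
            "; enrichment will be skipped")
  list(trait = trait, entries = entries, n_list = length(entries),
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Hypergeometric enrichment test
#'
#' Exact tail of the hypergeometric distribution for a gene list of size n
#' drawn from a background of N genes of which K carry the term:
#' over-representation is P(X >= k), under-representation P(X <= k).
#'
#' @param k annotated entries in the list (with multiplicity).
#' @param K annotated genes in the background.
#' @param n list size (with multiplicity).
#' @param N background size.
#' @param tail "over" (default) or "under".
#' @return the exact p-value.
#' @export
hypergeom_test <- function(k, K, n, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (K < 0 || K > N || n < 0 || k < 0 || k > min(n, K))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K) <= N)")
  if (tail == "over")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Tissue-restricted gene-set enrichment for one trait
#'
#' Tests every GO term annotating at least \code{min_bg} background genes for
#' over- (and under-) representation in the trait's multiplicity-expanded
#' gene list, with Benjamini-Hochberg adjustment across the tested terms of
#' that trait. List multiplicity enters k and n; the background universe K
#' and N count unique genes.
#'
#' @param gene_list output of \code{\link{build_gene_list}}.
#' @param go GO annotation (list with gene2go and term_names, as
#'   \code{\link{read_go_map}}).
#' @param background character vector of background gene IDs.
#' @param min_bg minimum background genes per tested term (default 2).
#' @param tail "over" (default), "under", or "both" (reports both;
#'   adjustment is applied to the over-representation column).
#' @param unique_genes collapse multiplicity (one entry per gene) before
#'   testing.
#' @return data.frame sorted by p_raw: trait, go_id, name, k, K, n, N,
#'   p_raw, p_adj (and p_under when tail = "both").
#' @export
enrich_all <- function(gene_list, go, background, min_bg = 2,
                       tail = c("over", "under", "both"),
                       unique_genes = FALSE) {
  tail <- match.arg(tail)
  entries <- gene_list$entries
  if (unique_genes) entries <- unique(entries)
  N <- length(unique(background))
  n <- length(entries)
  if (n == 0L)
    return(data.frame(trait = character(), go_id = character(),
                      name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  bg_ann <- go$gene2go[intersect(names(go$gene2go), background)]
  term_K <- table(unlist(bg_ann, use.names = FALSE))
  terms <- names(term_K)[term_K >= min_bg]
  if (length(terms) == 0L) stop("no GO term annotates >= min_bg background genes")
  entry_terms <- go$gene2go[entries]  # one element per list entry
  k_tab <- table(unlist(entry_terms, use.names = FALSE))
  primary <- if (tail == "under") "under" else "over"
  rows <- lapply(terms, function(tm) {
    k <- if (tm %in% names(k_tab)) as.integer(k_tab[[tm]]) else 0L
    K <- as.integer(term_K[[tm]])
    # multiplicity can push k past the hypergeometric support (a repeated
    # gene counts once in K); cap at the support boundary min(n, K)
    k <- min(k, n, K)
    data.frame(trait = gene_list$trait, go_id = tm,
               name = unname(go$term_names[tm]),
               k = k, K = K, n = n, N = N,
               p_raw = hypergeom_test(k, K, n, N, primary),
               p_under = hypergeom_test(k, K, n, N, "under"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw, m_override = nrow(out))
  if (tail != "both") out$p_under <- NULL
  out[order(out$p_raw, out$go_id), , drop = FALSE]
}

#' Enrichment across all traits
#'
#' @param gene_sets tissue-restricted data.frame from
#'   \code{\link{restrict_to_tissue}}.
#' @param go,background,min_bg,tail,unique_genes as \code{\link{enrich_all}}.
#' @param traits traits to test (default: all present).
#' @return data.frame of enrichment records across traits.
#' @export
enrich_traits <- function(gene_sets, go, background,
                          traits = unique(gene_sets$trait), min_bg = 2,
                          tail = "over", unique_genes = FALSE) {
  out <- lapply(traits, function(tr) {
    gl <- build_gene_list(gene_sets, tr)
    if (gl$n_list == 0L) return(NULL)
    enrich_all(gl, go, background, min_bg = min_bg, tail = tail,
               unique_genes = unique_genes)
  })
  do.call(rbind, out)
}

#' Cross-trait overlap of enriched terms
#'
#' For every term passing the reporting threshold in at least two traits,
#' lists the per-trait gene sets (unique genes, multiplicity ignored) and
#' their intersection — the summary behind "pathways influencing several
#' traits simultaneously".
#'
#' @param records enrichment data.frame across traits
#'   (\code{\link{enrich_traits}}).
#' @param gene_sets the tissue-restricted gene-SNP sets (for per-trait gene
#'   membership).
#' @param go GO annotation map.
#' @param alpha reporting threshold (default 0.05).
#' @param use_adjusted threshold on p_adj instead of p_raw (default FALSE;
#'   the descriptive overlap view is customarily on raw p).
#' @return data.frame: go_id, name, n_traits, traits (comma-joined),
#'   shared_genes (comma-joined intersection), genes_by_trait (list-column).
#' @export
overlap_summary <- function(records, gene_sets, go, alpha = 0.05,
                            use_adjusted = FALSE) {
  pcol <- if (use_adjusted) "p_adj" else "p_raw"
  sig <- records[records[[pcol]] <= alpha, , drop = FALSE]
  tab <- table(sig$go_id)
  terms <- names(tab)[tab >= 2]
  rows <- lapply(terms, function(tm) {
    trs <- sig$trait[sig$go_id == tm]
    ann_genes <- names(go$gene2go)[vapply(go$gene2go, function(v)
      tm %in% v, TRUE)]
    by_trait <- lapply(trs, function(tr)
      sort(unique(gene_sets$gene_id[gene_sets$trait == tr & gene_sets$kept &
                                      gene_sets$gene_id %in% ann_genes])))
    names(by_trait) <- trs
    shared <- Reduce(intersect, by_trait)
    data.frame(go_id = tm, name = unname(go$term_names[tm]),
               n_traits = length(trs),
               traits = paste(trs, collapse = ","),
               shared_genes = paste(shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(go_id = character(), name = character(), n_traits = integer(),
               traits = character(), shared_genes = character(),
               stringsAsFactors = FALSE)
  out[order(-out$n_traits, out$go_id), , drop = FALSE]
}
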