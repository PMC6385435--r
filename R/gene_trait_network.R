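#' Build the bipartite gene-trait network
#'
#' Rows are genes, columns are traits; the weight w[g, t] is the number of
#' retained uncorrelated raw-associated SNPs for that gene and trait. Genes
#' with no kept SNP anywhere are absent. Trait-trait edges carry the
#' pairwise-complete Pearson correlation of the analysis-scale phenotypes
#' (sensory traits have fewer records than instrumented ones).
#'
#' @param gene_sets data.frame from \code{\link{build_gene_snp_sets}}
#'   (tissue-restricted or not, as desired).
#' @param pheno phenotype table on the analysis scale
#'   (\code{\link{preprocess_phenotypes}}).
#' @param traits trait columns for the correlation edges (default: the traits
#'   present in gene_sets).
#' @return list of class \code{gene_trait_network}: \code{w} (genes x traits
#'   integer matrix), \code{trait_corr}, \code{gene_connectivity},
#'   \code{trait_connectivity}.
#' @export
build_network <- function(gene_sets, pheno,
                          traits = sort(unique(gene_sets$trait))) {
  kept <- gene_sets[gene_sets$kept & gene_sets$trait %in% traits, ,
                    drop = FALSE]
  genes <- sort(unique(kept$gene_id))
  w <- matrix(0L, length(genes), length(traits),
              dimnames = list(genes, traits))
  if (nrow(kept)) {
    tab <- table(kept$gene_id, kept$trait)
    w[rownames(tab), colnames(tab)] <- tab[, , drop = FALSE]
  }
  miss <- setdiff(traits, names(pheno))
  if (length(miss)) stop("trait column(s) absent from phenotypes: ",
                         paste(miss, collapse = ", "))
  Y <- as.matrix(pheno[, traits, drop = FALSE])
  vars <- apply(Y, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(vars) | vars == 0))
    stop("trait(s) with zero variance: ",
         paste(traits[!is.finite(vars) | vars == 0], collapse = ", "))
  tc <- stats::cor(Y, use = "pairwise.complete.obs")
  structure(list(w = w, trait_corr = tc,
                 gene_connectivity = rowSums(w),
                 trait_connectivity = colSums(w)),
            class = "gene_trait_network")
}

#' @export
print.gene_trait_network <- function(x, ...) {
  cat(sprintf("gene_trait_network: %d genes x %d traits, total weight %d\n",
              nrow(x$w), ncol(x$w), sum(x$w)))
  invisible(x)
}

#' Rank genes by network connectivity
#'
#' Connectivity is the sum of a gene's weights across traits (its total count
#' of uncorrelated associated SNPs). Ties are broken by the number of traits
#' touched (descending), then gene ID, so the ranking is deterministic and
#' independent of input order.
#'
#' @param net a \code{gene_trait_network}.
#' @param k how many genes to return (default 30, the usual figure size);
#'   capped at the gene count.
#' @param by "weight" (default, sum of SNP counts) or "traits" (number of
#'   traits with a nonzero edge).
#' @return data.frame: gene_id, connectivity, n_traits, rank.
#' @export
top_genes <- function(net, k = 30, by = c("weight", "traits")) {
  by <- match.arg(by)
  if (k <= 0) stop("k must be positive")
  conn <- net$gene_connectivity
  n_traits <- rowSums(net$w > 0)
  score <- if (by == "weight") conn else n_traits
  o <- order(-score, -n_traits, names(conn))
  o <- o[seq_len(min(k, length(o)))]
  data.frame(gene_id = names(conn)[o],
             connectivity = as.integer(conn[o]),
             n_traits = as.integer(n_traits[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Select candidate multi-QTL genes for joint modelling
#'
#' Takes the top \code{m} most connected genes and, for each, the traits with
#' at least two kept SNPs — the gene-trait pairs worth a joint multi-SNP
#' model. The connectivity gap (ratio of the m-th to the (m+1)-th
#' connectivity) is reported descriptively alongside.
#'
#' @param net a \code{gene_trait_network}.
#' @param m number of candidate genes (default 5).
#' @return list: \code{genes} (character), \code{pairs} (data.frame gene_id,
#'   trait, w), \code{gap_ratio}.
#' @export
select_multi_qtl_candidates <- function(net, m = 5) {
  if (m <= 0)
    return(list(genes = character(),
                pairs = data.frame(gene_id = character(), trait = character(),
                                   w = integer(), stringsAsFactors = FALSE),
                gap_ratio = NA_real_))
  tg <- top_genes(net, k = min(m + 1, nrow(net$w)))
  sel <- tg$gene_id[seq_len(min(m, nrow(tg)))]
  gap_ratio <- if (nrow(tg) > m && tg$connectivity[m + 1] > 0)
    tg$connectivity[m] / tg$connectivity[m + 1] else NA_real_
  pairs <- do.call(rbind, lapply(sel, function(gid) {
    wt <- net$w[gid, ]
    trs <- names(wt)[wt >= 2]
    if (length(trs) == 0L) return(NULL)
    data.frame(gene_id = gid, trait = trs, w = as.integer(wt[trs]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(gene_id = character(), trait = character(),
                        w = integer(), stringsAsFactors = FALSE)
  list(genes = sel, pairs = pairs, gap_ratio = gap_ratio)
}

#' Export the network as an edge list and GraphML
#'
#' Gene-trait edges carry the SNP-count weight; trait-trait edges carry the
#' signed phenotypic correlation; node size attributes carry connectivity.
#' The edge list TSV round-trips the weight matrix exactly.
#'
#' @param net a \code{gene_trait_network}.
#' @param path_edges TSV path (NULL to skip).
#' @param path_graphml GraphML path (NULL to skip).
#' @param top_k restrict to the top_k most connected genes (NULL = all).
#' @return the edge data.frame, invisibly.
#' @export
export_network <- function(net, path_edges = NULL, path_graphml = NULL,
                           top_k = NULL) {
  w <- net$w
  if (!is.null(top_k) && nrow(w) > 0)
    w <- w[top_genes(net, top_k)$gene_id, , drop = FALSE]
  ge <- which(w > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(w)[ge[, 1]], to = colnames(w)[ge[, 2]],
    type = rep("gene_trait", nrow(ge)), weight = w[ge],
    stringsAsFactors = FALSE)
  tc <- net$trait_corr
  ut <- which(upper.tri(tc), arr.ind = TRUE)
  edges <- rbind(edges, data.frame(
    from = rownames(tc)[ut[, 1]], to = colnames(tc)[ut[, 2]],
    type = rep("trait_trait", nrow(ut)), weight = tc[ut],
    stringsAsFactors = FALSE))
  if (!is.null(path_edges))
    utils::write.table(edges, path_edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_graphml)) {
    nodes <- data.frame(
      name = c(rownames(w), colnames(w)),
      kind = c(rep("gene", nrow(w)), rep("trait", ncol(w))),
      connectivity = c(rowSums(w), net$trait_connectivity[colnames(w)]),
      stringsAsFactors = FALSE)
    gph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
    igraph::write_graph(gph, path_graphml, format = "graphml")
  }
  invisible(edges)
}

#' Re-import an exported edge list into a weight matrix
#' @param path edge-list TSV from \code{\link{export_network}}.
#' @return integer genes x traits matrix.
#' @export
import_network_edges <- function(path) {
  edges <- utils::read.delim(path)
  ge <- edges[edges$type == "gene_trait", , drop = FALSE]
  genes <- sort(unique(ge$from)); traits <- sort(unique(ge$to))
  w <- matrix(0L, length(genes), length(traits),
              dimnames = list(genes, traits))
  w[cbind(match(ge$from, genes), match(ge$to, traits))] <- ge$weight
  w
}
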