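make_sets <- function(df) {
  df$variant_id <- sprintf("v%03d", seq_len(nrow(df)))
  df$p <- 0.01
  df$kept <- TRUE
  df
}

test_that("network weights count kept SNPs and connectivity sums them", {
  sets <- make_sets(data.frame(
    trait = c(rep("tenderness", 2), rep("cooking_loss", 3),
              rep("juiciness", 3), "flavor"),
    gene_id = c(rep("EVC2L", 8), "OTHER")))
  ph <- data.frame(sample_id = sprintf("s%d", 1:50), year = 2010,
                   breed_group = 1,
                   tenderness = rnorm(50), cooking_loss = rnorm(50),
                   juiciness = rnorm(50), flavor = rnorm(50))
  net <- build_network(sets, ph,
                       traits = c("tenderness", "cooking_loss", "juiciness",
                                  "flavor"))
  # the 2/3/3 multi-trait pattern gives connectivity 8
  expect_equal(unname(net$gene_connectivity["EVC2L"]), 8)
  expect_equal(unname(net$w["EVC2L", c("tenderness", "cooking_loss",
                                       "juiciness")]), c(2L, 3L, 3L))
  # bipartite degree conservation
  expect_equal(sum(net$gene_connectivity), sum(net$trait_connectivity))
  expect_equal(sum(net$gene_connectivity), sum(net$w))
  # genes without kept SNPs are absent
  sets2 <- sets; sets2$kept[sets2$gene_id == "OTHER"] <- FALSE
  net2 <- build_network(sets2, ph, traits = "tenderness")
  expect_false("OTHER" %in% rownames(net2$w))
})

test_that("trait correlations come from the phenotypes, pairwise complete", {
  sets <- make_sets(data.frame(trait = c("a", "b"), gene_id = c("G1", "G1")))
  ph <- data.frame(sample_id = sprintf("s%d", 1:30), year = 2010,
                   breed_group = 1, a = rnorm(30))
  ph$b <- ph$a
  ph$b[1:5] <- NA
  net <- build_network(sets, ph, traits = c("a", "b"))
  expect_equal(net$trait_corr["a", "b"], 1.0)
  ph$b <- 2.5  # zero variance
  expect_error(build_network(sets, ph, traits = c("a", "b")), "zero variance")
})

test_that("gene ranking is deterministic with documented tie-breaks", {
  # equal connectivity, different trait spread: the broader gene ranks first
  sets <- make_sets(data.frame(
    trait = c("a", "a", "a", "a", "b", "c"),
    gene_id = c("NARROW", "NARROW", "NARROW", "BROAD", "BROAD", "BROAD")))
  ph <- data.frame(sample_id = sprintf("s%d", 1:20), year = 2010,
                   breed_group = 1, a = rnorm(20), b = rnorm(20),
                   c = rnorm(20))
  net <- build_network(sets, ph, traits = c("a", "b", "c"))
  tg <- top_genes(net, 2)
  expect_equal(tg$gene_id, c("BROAD", "NARROW"))
  expect_equal(tg$connectivity, c(3L, 3L))
  # input order must not matter
  net2 <- build_network(sets[rev(seq_len(nrow(sets))), ], ph,
                        traits = c("a", "b", "c"))
  expect_equal(top_genes(net2, 2), tg)
  # k larger than the gene count returns everything
  expect_equal(nrow(top_genes(net, 50)), 2L)
  expect_error(top_genes(net, 0), "positive")
})

test_that("candidate selection forwards only gene-trait pairs with >= 2 SNPs", {
  sets <- make_sets(data.frame(
    trait = c("a", "a", "b", "a", "b", "c"),
    gene_id = c("G1", "G1", "G1", "G2", "G2", "G3")))
  ph <- data.frame(sample_id = sprintf("s%d", 1:20), year = 2010,
                   breed_group = 1, a = rnorm(20), b = rnorm(20),
                   c = rnorm(20))
  net <- build_network(sets, ph, traits = c("a", "b", "c"))
  cand <- select_multi_qtl_candidates(net, m = 2)
  expect_equal(cand$genes, c("G1", "G2"))
  expect_equal(cand$pairs$gene_id, "G1")  # only G1/a has w >= 2
  expect_equal(cand$pairs$trait, "a")
  expect_equal(select_multi_qtl_candidates(net, 0)$genes, character())
  # all genes at weight 1: selection still returns m genes, gap ratio 1
  sets1 <- make_sets(data.frame(trait = "a", gene_id = c("G1", "G2", "G3")))
  net1 <- build_network(sets1, ph, traits = "a")
  c1 <- select_multi_qtl_candidates(net1, m = 2)
  expect_equal(length(c1$genes), 2L)
  expect_equal(c1$gap_ratio, 1.0)
})

test_that("network export round-trips and preserves correlation signs", {
  sets <- make_sets(data.frame(
    trait = c("a", "a", "b"), gene_id = c("G1", "G1", "G2")))
  ph <- data.frame(sample_id = sprintf("s%d", 1:40), year = 2010,
                   breed_group = 1, a = rnorm(40))
  ph$b <- -ph$a + rnorm(40, 0, 0.1)
  net <- build_network(sets, ph, traits = c("a", "b"))
  fe <- tempfile(fileext = ".tsv"); fg <- tempfile(fileext = ".graphml")
  edges <- export_network(net, fe, fg)
  w2 <- import_network_edges(fe)
  expect_equal(w2, net$w[rownames(w2), colnames(w2)])
  tt <- edges[edges$type == "trait_trait", ]
  expect_lt(tt$weight, 0)  # negative correlation keeps its sign
  gr <- igraph::read_graph(fg, format = "graphml")
  expect_equal(sort(igraph::V(gr)$name), sort(c("G1", "G2", "a", "b")))
  # empty network: header-only edge list
  net0 <- build_network(sets[0, ], ph, traits = c("a", "b"))
  f0 <- tempfile()
  export_network(net0, f0)
  e0 <- utils::read.delim(f0)
  expect_equal(nrow(e0[e0$type == "gene_trait", ]), 0L)
})

test_that("planted multi-QTL genes out-connect single-QTL genes", {
  cfg <- small_cfg(seed = 55)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$genotypes, sim$phenotypes, sim$annotation$genes,
                      sim$annotation$go, sim$annotation$background)
  conn <- res$network$gene_connectivity
  planted <- intersect(c("GENE005", "GENE012"), names(conn))
  expect_gt(length(planted), 0)
  others <- setdiff(names(conn), c("GENE005", "GENE012"))
  expect_gt(mean(conn[planted]), mean(conn[others]))
})
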