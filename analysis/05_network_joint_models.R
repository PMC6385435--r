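#!/usr/bin/env Rscript
# Stage 5: the bipartite gene-trait network weighted by uncorrelated-SNP
# counts, the top-30 connectivity ranking, candidate multi-QTL genes, and
# joint multi-SNP models with backward elimination for every candidate
# gene-trait pair with >= 2 kept SNPs. Also demonstrates the conditional
# scan on the strongest hit region.
#
# Reads results/data + previous stages, writes results/network_edges.tsv,
# results/network.graphml, results/top_genes.tsv, results/joint_models.json.

suppressPackageStartupMessages(library(beefgwas))

g <- qc_filter(read_vcf("results/data/genotypes.vcf"))$genotypes
pheno <- read_phenotypes("results/data/phenotypes.tsv")
ph <- preprocess_phenotypes(pheno)
sets <- read.delim("results/gene_sets.tsv")
assoc <- read.delim("results/assoc.tsv", colClasses = c(chrom = "character"))

net <- build_network(sets, ph, traits = unique(sets$trait))
print(net)
top30 <- top_genes(net, 30)
write.table(top30, "results/top_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
export_network(net, "results/network_edges.tsv", "results/network.graphml",
               top_k = 30)

cand <- select_multi_qtl_candidates(net, m = 5)
message("top-5 candidate genes: ", paste(cand$genes, collapse = ", "),
        sprintf(" (connectivity gap ratio %.2f)", cand$gap_ratio))

grm <- compute_grm(g)
joint <- list()
for (r in seq_len(nrow(cand$pairs))) {
  gid <- cand$pairs$gene_id[r]; tr <- cand$pairs$trait[r]
  snps <- sets$variant_id[sets$gene_id == gid & sets$trait == tr & sets$kept]
  jf <- joint_fit(g, ph, tr, snps, covariates = "year", grm = grm,
                  gene_id = gid)
  print(jf)
  joint[[paste(gid, tr, sep = ".")]] <- list(
    gene_id = gid, trait = tr, n_start = jf$n_start,
    retained = jf$retained, trace = jf$trace)
}
jsonlite::write_json(joint, "results/joint_models.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")

# conditional scan on the single strongest association
best <- assoc[which.min(assoc$p), ]
message(sprintf("conditioning the %s scan on top SNP %s (p = %.2e)",
                best$trait, best$variant_id, best$p))
win <- 30000
cond <- conditional_scan(g, ph, best$trait, condition_on = best$variant_id,
                         region = sprintf("%s:%d-%d", best$chrom,
                                          max(1, best$pos - win),
                                          best$pos + win),
                         covariates = "year", grm = grm)
n_sig_before <- sum(assoc$trait == best$trait & assoc$chrom == best$chrom &
                      abs(assoc$pos - best$pos) <= win & assoc$p <= 0.05)
message(sprintf("region SNPs at p <= 0.05: %d before conditioning, %d after",
                n_sig_before - 1, sum(cond$p <= 0.05, na.rm = TRUE)))
write.table(cond, "results/conditional_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
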