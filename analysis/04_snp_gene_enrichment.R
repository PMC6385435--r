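#!/usr/bin/env Rscript
# Stage 4: assign raw associated SNPs (p <= 0.05) to genes with a 3 kb flank,
# prune to uncorrelated SNPs per gene (r2 <= 0.3), restrict to the tissue
# background, and run the multiplicity-weighted hypergeometric enrichment
# per trait with BH adjustment across tested terms, plus the cross-trait
# pathway overlap summary.
#
# Reads results/data + results/assoc.tsv, writes results/gene_sets.tsv,
# results/enrichment.tsv and results/overlap.tsv.

suppressPackageStartupMessages(library(beefgwas))

g <- qc_filter(read_vcf("results/data/genotypes.vcf"))$genotypes
assoc <- read.delim("results/assoc.tsv", colClasses = c(chrom = "character"))
genes <- read_bed_genes("results/data/genes.bed")
go <- read_go_map("results/data/go_map.tsv")
background <- read_background("results/data/background.txt")

sets <- build_gene_snp_sets(g, assoc, genes, alpha = 0.05, flank = 3000,
                            r2_max = 0.3)
sets <- restrict_to_tissue(sets, background)
write.table(sets, "results/gene_sets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
kept <- sets[sets$kept, ]
message(sprintf("gene lists: %d kept SNP entries across %d genes and %d traits",
                nrow(kept), length(unique(kept$gene_id)),
                length(unique(kept$trait))))
message("largest per-gene multiplicity: ",
        max(table(kept$trait, kept$gene_id)))

enr <- enrich_traits(sets, go, background, tail = "both")
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top enriched term per trait:")
print(do.call(rbind, lapply(split(enr, enr$trait), function(d)
  d[1, c("trait", "go_id", "name", "k", "K", "n", "N", "p_raw", "p_adj")])),
  row.names = FALSE)

ov <- overlap_summary(enr, sets, go, alpha = 0.05)
write.table(ov, "results/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(ov), " term(s) pass the reporting threshold in >= 2 traits")
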