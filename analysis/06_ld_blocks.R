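#!/usr/bin/env Rscript
# Stage 6: Gabriel-style confidence-interval LD blocks (two-locus EM
# haplotype frequencies, Wall-Pritchard D' likelihood bounds) around the
# most connected candidate gene, mirroring the LD characterization of
# candidate multi-QTL loci.
#
# Reads results/data + results/top_genes.tsv, writes results/ld_blocks.bed
# and results/ld_pairs.tsv.

suppressPackageStartupMessages(library(beefgwas))

g <- qc_filter(read_vcf("results/data/genotypes.vcf"))$genotypes
genes <- read_bed_genes("results/data/genes.bed")
top <- read.delim("results/top_genes.tsv")

gid <- top$gene_id[1]
gi <- genes[genes$gene_id == gid, ]
region <- sprintf("%s:%d-%d", gi$chrom, gi$start1 - 3000, gi$end1 + 3000)
message("LD blocks for top gene ", gid, " (", region, ")")

lb <- gabriel_blocks(g, region, strong_low = 0.70, strong_high = 0.98,
                     recomb_high = 0.90, frac_strong = 0.95, conf = 0.90)
print(lb)
write_blocks_bed(lb, "results/ld_blocks.bed")
write.table(lb$pairs, "results/ld_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d strong / %d recomb / %d uninformative pairs",
                sum(lb$pairs$class == "strong"),
                sum(lb$pairs$class == "recomb"),
                sum(lb$pairs$class == "uninformative")))
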