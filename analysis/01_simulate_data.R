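#!/usr/bin/env Rscript
# Stage 1: generate the synthetic Angus-Brahman study dataset.
#
# 672 steers in 6 breed-composition groups, a 3,000-SNP block-structured
# panel, 7 correlated meat-quality traits (sensory traits on 495 animals),
# three planted multi-QTL genes and one planted GO term. Everything below is
# written in the pipeline's standard input formats under results/data/.

suppressPackageStartupMessages(library(beefgwas))

cfg <- sim_config(seed = 11)
sim <- simulate_dataset(cfg)
dir <- "results/data"
write_sim_dataset(sim, dir)

message("dataset written to ", dir)
print(sim$genotypes)
message("traits: ", paste(cfg$traits, collapse = ", "))
message("planted genes: ", paste(unique(cfg$qtl_spec$gene_id), collapse = ", "),
        " (term ", cfg$planted_term, ")")
message("sensory records: ", length(sim$truth$sensory_ids), " of ",
        cfg$n_samples)
bv <- sim$truth$breeding_values
message(sprintf("realized WBSF-tenderness breeding-value correlation: %.3f",
                cor(bv[, "wbsf"], bv[, "tenderness"])))
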