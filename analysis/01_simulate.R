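#!/usr/bin/env Rscript
# Generate the synthetic multi-study shark-skin survey: 17 host samples
# (9 species, 6 studies) plus 5 seawater controls, 20 planted
# phylosymbiotic OTUs among 280 study-confounded noise OTUs, and the host
# tree/distances that constitute the ground truth. Writes plain-text inputs
# for the downstream steps.

suppressMessages(library(phylofrac))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_paper_layout(seed = 1)
sim <- simulate_table(cfg)

write_otu_table(sim$table,
                file.path(out, "counts.tsv"),
                file.path(out, "taxonomy.tsv"),
                file.path(out, "metadata.tsv"))
write_newick(sim$truth$host_tree, file.path(out, "host.nwk"))
write_dist_matrix(sim$truth$host_dist, file.path(out, "host_dist.tsv"))
truth <- data.frame(otu_id = names(sim$truth$otu_role),
                    role = as.character(sim$truth$otu_role))
write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

print(sim$table)
cat(sprintf("planted phylosymbiotic OTUs: %d; noise: %d; contaminants: %d; singletons: %d\n",
            sum(truth$role == "phylo"), sum(truth$role == "noise"),
            sum(truth$role == "contaminant"), sum(truth$role == "singleton")))
cat(sprintf("read depths span %s-%s\n",
            format(min(sim$truth$depths), big.mark = ","),
            format(max(sim$truth$depths), big.mark = ",")))
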