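#!/usr/bin/env Rscript
# Table preparation: agglomerate features to genus rank, drop singletons and
# contaminant lineages, rarefy every sample to the lowest observed depth,
# and summarize alpha diversity and core-OTU sharing.

suppressMessages(library(phylofrac))

dirs <- "results/data"
tab <- read_otu_table(file.path(dirs, "counts.tsv"),
                      file.path(dirs, "taxonomy.tsv"),
                      file.path(dirs, "metadata.tsv"))

agg <- agglomerate(tab, "genus")
filt <- filter_otus(agg, min_total = 2)
rare <- rarefy(filt, depth = "auto", seed = 101)
cat(sprintf("%d input features -> %d genera -> %d after filtering; rarefied to %s reads\n",
            ncol(tab$counts), ncol(agg$counts), ncol(filt$counts),
            format(attr(rare, "depth"), big.mark = ",")))

write_otu_table(rare, file.path(dirs, "rarefied_counts.tsv"),
                file.path(dirs, "rarefied_taxonomy.tsv"),
                file.path(dirs, "rarefied_metadata.tsv"))

alpha <- alpha_diversity(rare)
write.table(alpha, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(alpha)

shark <- rare$samples$sample_id[rare$samples$sample_type != "seawater"]
shark_tab <- subset_table(rare, samples = shark)
core_all <- core_otus(shark_tab)
core_study <- core_otus(shark_tab, group_by = "study")
cat(sprintf("core OTUs shared by all %d host samples: %d of %d (%.1f%%)\n",
            length(shark), length(core_all), ncol(shark_tab$counts),
            100 * length(core_all) / ncol(shark_tab$counts)))
cat(sprintf("OTUs present in at least one host sample of every study: %d\n",
            length(core_study)))
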