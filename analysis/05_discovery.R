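#!/usr/bin/env Rscript
# Fraction discovery: subsample ten OTUs without replacement 10,000 times on
# the core panel, score each replicate by CID against the host tree and by
# Mantel correlation with host distances, collect the OTUs of qualifying
# replicates (perfect congruence; r >= 0.9), intersect the criteria, and
# re-evaluate the consensus set on the full multi-study panel. With the
# ground truth from step 01 we can also measure recovery of the planted
# phylosymbiotic fraction.

suppressMessages(library(phylofrac))

dirs <- "results/data"
rare <- read_otu_table(file.path(dirs, "rarefied_counts.tsv"),
                       file.path(dirs, "rarefied_taxonomy.tsv"),
                       file.path(dirs, "rarefied_metadata.tsv"))
host_tree <- read_newick(file.path(dirs, "host.nwk"))
host_dist <- read_dist_matrix(file.path(dirs, "host_dist.tsv"))
truth <- read.delim(file.path(dirs, "truth.tsv"))
tax <- read.delim(file.path(dirs, "taxonomy.tsv"))
planted <- tax$genus[match(truth$otu_id[truth$role == "phylo"], tax$otu_id)]

panel <- function(ids) {
  sub <- subset_table(rare, samples = ids)
  subset_table(sub, otus = colnames(sub$counts)[colSums(sub$counts) > 0])
}
shark <- rare$samples$sample_id[rare$samples$sample_type != "seawater"]
core <- panel(rare$samples$sample_id[rare$samples$sample_type != "seawater" &
                                       rare$samples$study == "study1"])
full <- panel(shark)

reps <- score_replicates(core, host_tree, host_dist, design = NULL,
                         mode = "subsample", n_reps = 10000, k = 10,
                         seed = 108, outgroup = "outgroup")
print(reps)
write.table(reps$scores, "results/replicate_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

qual <- qualifying_otus(reps, cid_max = 0, r_min = 0.9)
print(qual)
cons <- consensus_sets(list(cid = qual$otus_cid, mantel = qual$otus_mantel))
print(cons)

sets <- rbind(data.frame(otu_id = qual$otus_cid, criterion = "cid"),
              data.frame(otu_id = qual$otus_mantel, criterion = "mantel"),
              data.frame(otu_id = cons$intersections$consensus,
                         criterion = "consensus"))
write.table(sets, "results/otu_sets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (nm in c("otus_cid", "otus_mantel")) {
  set <- qual[[nm]]
  K <- sum(planted %in% colnames(core$counts))
  x <- length(intersect(set, planted))
  p <- phyper(x - 1, K, ncol(core$counts) - K, length(set), lower.tail = FALSE)
  cat(sprintf("%s: %d OTUs, %d of %d planted recovered (recall %.2f), hypergeometric p = %.3g\n",
              nm, length(set), x, K, x / K, p))
}

consensus <- cons$intersections$consensus
if (length(consensus) >= 2) {
  cat(sprintf("re-evaluating the %d-OTU consensus set on the full panel:\n",
              length(consensus)))
  rv <- reevaluate(consensus, full, host_tree, host_dist,
                   design = build_design_matrix(full$samples, "study"),
                   n_perm = 1000, seed = 109, outgroup = "outgroup",
                   panel_id = "full")
  print(rv)
}
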