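test_that("the reference layout matches the emulated survey design", {
  cfg <- default_paper_layout(seed = 1)
  meta <- cfg$species_study_assignment
  expect_equal(sum(meta$sample_type == "shark"), 17)
  expect_equal(sum(meta$sample_type == "seawater"), 5)
  shark <- meta[meta$sample_type == "shark", ]
  expect_equal(length(unique(shark$species)), 9)
  expect_equal(length(unique(shark$study)), 6)
  # the core study holds six species from one location
  core <- shark[shark$study == "study1", ]
  expect_equal(nrow(core), 6)
  expect_equal(length(unique(core$species)), 6)
  expect_equal(length(unique(core$location)), 1)
  # at least two species replicated across two studies
  studies_per_species <- tapply(shark$study, shark$species,
                                function(s) length(unique(s)))
  expect_gte(sum(studies_per_species >= 2), 2)
  # every sample belongs to exactly one study
  expect_false(anyNA(meta$study))
  expect_equal(anyDuplicated(meta$sample_id), 0L)
})

test_that("simulated host trees are ultrametric with oracle-checked patristic distances", {
  host <- simulate_host_tree(6, seed = 2)
  expect_s3_class(host$tree, "phylo")
  expect_true(ape::is.ultrametric(host$tree, tol = 1e-8))
  # 4 species: a single nontrivial split
  h4 <- simulate_host_tree(4, seed = 3)
  expect_length(tree_splits(h4$tree), 1)
  # metric properties
  d <- unclass(host$dist)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # patristic oracle: shortest paths on the edge graph
  g <- igraph::graph_from_edgelist(host$tree$edge, directed = FALSE)
  igraph::E(g)$weight <- host$tree$edge.length
  sp <- igraph::distances(g)[seq_len(6), seq_len(6)]
  dimnames(sp) <- list(host$tree$tip.label, host$tree$tip.label)
  expect_equal(d, sp[rownames(d), colnames(d)], tolerance = 1e-9)
})

test_that("simulated counts are integral with totals equal to the drawn depths", {
  cfg <- default_paper_layout(seed = 4)
  cfg$depth_range <- c(2000, 8000)   # small depths for speed
  sim <- simulate_table(cfg)
  expect_true(all(sim$table$counts == floor(sim$table$counts)))
  expect_true(all(sim$table$counts >= 0))
  expect_equal(unname(rowSums(sim$table$counts)), unname(sim$truth$depths))
  expect_true(all(sim$truth$depths >= 2000 & sim$truth$depths <= 8000))
  # roles partition the OTUs; contaminants carry flagged lineages
  expect_setequal(names(sim$truth$otu_role), colnames(sim$table$counts))
  contam <- names(sim$truth$otu_role)[sim$truth$otu_role == "contaminant"]
  lin <- apply(sim$table$taxonomy[match(contam, sim$table$taxonomy$otu_id),
                                  -1], 1, paste, collapse = " ")
  expect_true(all(grepl("Mitochondria", lin)))
  singles <- names(sim$truth$otu_role)[sim$truth$otu_role == "singleton"]
  expect_true(all(colSums(sim$table$counts[, singles, drop = FALSE]) == 1))
  # determinism
  sim2 <- simulate_table(cfg)
  expect_identical(sim$table$counts, sim2$table$counts)
})

test_that("Brownian tip covariance matches sigma2 times shared path length", {
  # fixed tree, many independent trait draws: 2000 planted OTUs give 2000
  # independent Brownian realizations over the same phylogeny
  cfg3 <- default_paper_layout(seed = 11)
  cfg3$n_otus_noise <- 0; cfg3$singleton_rate <- 0; cfg3$contaminant_rate <- 0
  cfg3$unassigned_rate <- 0; cfg3$depth_range <- c(100, 100)
  cfg3$n_otus_phylo <- 2000
  sim <- simulate_table(cfg3)
  z <- sim$truth$z
  V3 <- cfg3$sigma2_phylo * ape::vcv(sim$truth$host_tree)[rownames(z), rownames(z)]
  emp <- tcrossprod(z) / ncol(z)
  # each entry is a mean of 2000 products; tolerance 3 standard errors
  for (i in c(1, 3, 5)) for (j in c(2, 4)) {
    se <- stats::sd(z[i, ] * z[j, ]) / sqrt(ncol(z))
    expect_lt(abs(emp[i, j] - V3[i, j]), 3 * se + 1e-9)
  }
})

test_that("the no-signal limit gives near-identical compositions", {
  cfg <- default_paper_layout(seed = 5)
  cfg$sigma2_phylo <- 0; cfg$sigma2_study <- 0; cfg$sigma2_sample <- 0
  cfg$sigma2_resid <- 0; cfg$phylo_baseline_shift <- 0
  cfg$singleton_rate <- 0; cfg$contaminant_rate <- 0
  cfg$depth_range <- c(5e4, 5e4)
  sim <- simulate_table(cfg)
  d <- suppressWarnings(bray_curtis(sim$table))
  expect_lt(max(d), 0.06)   # only multinomial noise remains
})

test_that("phylosymbiotic signal strengthens with the Brownian rate", {
  grid <- c(0.5, 4, 16)
  mean_r <- vapply(grid, function(s2p) {
    rs <- vapply(1:12, function(s) {
      cfg <- default_paper_layout(seed = 200 + s)
      cfg$sigma2_phylo <- s2p; cfg$n_otus_noise <- 0
      cfg$singleton_rate <- 0; cfg$contaminant_rate <- 0
      cfg$unassigned_rate <- 0
      cfg$depth_range <- c(20000, 20000)
      sim <- simulate_table(cfg)
      shark <- sim$table$samples$sample_id[sim$table$samples$sample_type == "shark"]
      tab <- subset_table(sim$table, samples = shark)
      ex <- expand_host_to_samples(sim$truth$host_tree, sim$truth$host_dist,
                                   tab$samples)
      mantel(suppressWarnings(bray_curtis(tab)), ex$dist,
             n_perm = 9, seed = 1)$r
    }, 0)
    mean(rs)
  }, 0)
  expect_true(all(diff(mean_r) > 0) || (mean_r[3] > mean_r[1] + 0.1))
  expect_gt(mean_r[3], 0.3)
})

test_that("study effects alone make study structure detectable by PERMANOVA", {
  hits <- vapply(1:30, function(s) {
    cfg <- default_paper_layout(seed = 300 + s)
    cfg$sigma2_phylo <- 0; cfg$phylo_baseline_shift <- 0
    cfg$sigma2_study <- 1; cfg$sigma2_sample <- 0; cfg$sigma2_resid <- 0.1
    cfg$singleton_rate <- 0; cfg$contaminant_rate <- 0
    cfg$depth_range <- c(20000, 20000)
    sim <- simulate_table(cfg)
    d <- suppressWarnings(bray_curtis(sim$table))
    g <- stats::setNames(sim$table$samples$study, sim$table$samples$sample_id)
    permanova(d, g, n_perm = 99, seed = 1)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
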