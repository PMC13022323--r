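test_that("TSV write/read round-trips a valid table", {
  tab <- toy_table(matrix(c(3, 0, 1, 4, 2, 5), 2, 3), study = c("s1", "s2"))
  paths <- file.path(tempdir(), c("c.tsv", "t.tsv", "m.tsv"))
  write_otu_table(tab, paths[1], paths[2], paths[3])
  back <- read_otu_table(paths[1], paths[2], paths[3])
  expect_equal(back$counts, tab$counts)
  expect_equal(back$taxonomy, tab$taxonomy)
  expect_equal(back$samples$species, tab$samples$species)
  # transposed dialect
  tc <- utils::read.delim(paths[1], check.names = FALSE, row.names = 1)
  utils::write.table(data.frame(otu_id = colnames(tc), t(as.matrix(tc)),
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_otu_table(paths[1], paths[2], paths[3], transpose = TRUE)
  expect_equal(back2$counts, tab$counts)
})

test_that("invalid inputs fail with informative errors", {
  cts <- matrix(c(3.5, 1, 2, 0), 2, 2,
                dimnames = list(c("sa", "sb"), c("o1", "o2")))
  expect_error(toy_table(cts), "sa.*o1|o1.*sa")
  cts2 <- matrix(1:4, 2, 2, dimnames = list(c("sa", "sb"), c("o1", "o2")))
  tab <- toy_table(cts2)
  expect_error(otu_table(cts2, tab$taxonomy, tab$samples[1, , drop = FALSE]),
               "sb")
  expect_error(otu_table(cts2, tab$taxonomy[1, , drop = FALSE], tab$samples),
               "o2")
  expect_error(otu_table(-cts2, tab$taxonomy, tab$samples), "non-negative")
})

test_that("agglomeration pools counts within a rank and drops unassigned", {
  cts <- matrix(c(3, 4, 1, 0, 2, 2, 1, 1, 5, 0), 2, 5,
                dimnames = list(c("sa", "sb"),
                                paste0("asv", 1:5)))
  tab <- toy_table(cts, genus = c("Alcaligenes", "Alcaligenes", "Vibrio",
                                  NA, ""))
  agg <- agglomerate(tab, "genus")
  # two OTUs with the same genus, counts (3,4) and (1,0) -> (4,4)
  expect_equal(unname(agg$counts[, "Alcaligenes"]), c(4, 4))
  # 5 features, 2 unassigned -> 2 surviving groups here (Alcaligenes, Vibrio)
  expect_equal(ncol(agg$counts), 2)
  # totals conserved up to dropped unassigned features
  dropped <- sum(cts[, 4:5])
  expect_equal(sum(agg$counts) + dropped, sum(cts))
  # idempotence: a table already at genus resolution is unchanged
  agg2 <- agglomerate(agg, "genus")
  expect_equal(unname(agg2$counts), unname(agg$counts))
  expect_equal(colnames(agg2$counts), colnames(agg$counts))
  expect_error(agglomerate(tab, "kingdom"))
})

test_that("agglomeration at a higher rank yields hand-counted groups", {
  cts <- matrix(1, 2, 5, dimnames = list(c("sa", "sb"), paste0("asv", 1:5)))
  tab <- toy_table(cts)
  tab$taxonomy$family <- c("f1", "f1", "f2", NA, "f3")
  agg <- agglomerate(tab, "family")
  expect_setequal(colnames(agg$counts), c("f1", "f2", "f3"))
  expect_equal(unname(agg$counts[, "f1"]), c(2, 2))
  expect_true(all(is.na(agg$taxonomy$genus)))
})

test_that("filtering removes singletons and contaminant lineages, preserving order", {
  cts <- matrix(c(1, 0, 5, 3, 2, 2, 9, 9), 2, 4,
                dimnames = list(c("sa", "sb"), paste0("o", 1:4)))
  tab <- toy_table(cts)
  tab$taxonomy$class[3] <- "Chloroplast"
  filt <- filter_otus(tab, min_total = 2,
                      contaminant_terms = c("archaea", "chloroplast", "mitochondria"))
  expect_equal(colnames(filt$counts), c("o2", "o4"))  # o1 singleton, o3 contaminant
  # identity when thresholds disabled
  ident <- filter_otus(tab, min_total = 0, contaminant_terms = character(0))
  expect_equal(ident$counts, tab$counts)
  # idempotence
  expect_equal(filter_otus(filt)$counts, filt$counts)
  tab$taxonomy$class <- "Chloroplast"
  tab$taxonomy$order <- NA
  expect_warning(filter_otus(tab), "all OTUs removed")
})

test_that("rarefaction preserves totals, is reproducible, and is hypergeometric", {
  cts <- matrix(c(10, 8, 0, 3, 0, 9), 2, 3,
                dimnames = list(c("sa", "sb"), c("o1", "o2", "o3")))
  tab <- toy_table(cts)
  r <- rarefy(tab, depth = 5, seed = 1)
  expect_equal(unname(rowSums(r$counts)), c(5, 5))
  expect_true(all(r$counts <= tab$counts))
  expect_equal(rarefy(tab, depth = 5, seed = 1)$counts, r$counts)
  # single-OTU sample: all depth goes to that OTU
  one <- toy_table(matrix(c(10, 0, 0), 1, 3))
  expect_equal(unname(rarefy(one, depth = 5, seed = 2)$counts[1, ]), c(5, 0, 0))
  # auto depth = lowest sample total (10, sample sa), leaving sa unchanged
  expect_equal(rarefy(tab, depth = "auto", seed = 3)$counts["sa", ],
               tab$counts["sa", ])
  expect_error(rarefy(tab, depth = 13, seed = 1), "exceeds")
  # (2,2) at depth 2: outcomes follow the multivariate hypergeometric
  # {(2,0): 1/6, (1,1): 4/6, (0,2): 1/6} (all 2-subsets of 4 reads)
  two <- toy_table(matrix(c(2, 2), 1, 2))
  draws <- vapply(1:3000, function(s) rarefy(two, 2, seed = s)$counts[1, 1], 0)
  freq <- table(factor(draws, levels = 0:2)) / 3000
  se <- sqrt(c(1/6 * 5/6, 4/6 * 2/6, 1/6 * 5/6) / 3000)
  expect_true(all(abs(freq - c(1/6, 4/6, 1/6)) < 3 * se + 1e-9))
})

test_that("rarefied column totals match depth-weighted expectation", {
  cts <- matrix(c(40, 10, 30, 60, 30, 30), 2, 3,
                dimnames = list(c("sa", "sb"), c("o1", "o2", "o3")))
  tab <- toy_table(cts)
  draws <- sapply(1:400, function(s) rarefy(tab, 20, seed = s)$counts["sa", ])
  expected <- 20 * cts["sa", ] / sum(cts["sa", ])
  se <- apply(draws, 1, stats::sd) / sqrt(400)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("core OTUs respect the presence rule, overall and by group", {
  cts <- rbind(s1 = c(1, 1, 0, 2),
               s2 = c(2, 1, 1, 0),
               s3 = c(3, 0, 1, 0),
               s4 = c(4, 1, 1, 0))
  colnames(cts) <- paste0("o", 1:4)
  tab <- toy_table(cts, study = c("A", "A", "B", "B"))
  expect_equal(core_otus(tab), "o1")
  # group rule: present in >= 1 sample of each study
  expect_setequal(core_otus(tab, group_by = "study"), c("o1", "o2", "o3"))
  expect_setequal(core_otus(tab, group_by = "study", min_groups = 1),
                  paste0("o", 1:4))
  expect_error(core_otus(tab, group_by = "nope"), "unknown")
})

test_that("replicate libraries merge by summing counts", {
  cts <- rbind(s1 = c(1, 2), s2 = c(3, 4), s3 = c(5, 6))
  colnames(cts) <- c("o1", "o2")
  tab <- toy_table(cts, species = c("sp1", "sp1", "sp2"),
                   study = c("A", "A", "A"))
  tab$samples$location <- "x"
  tab$samples$year <- 2020
  m <- merge_libraries(tab)
  expect_equal(nrow(m$counts), 2)
  expect_equal(unname(m$counts[1, ]), c(4, 6))
})
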