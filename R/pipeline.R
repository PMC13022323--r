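#' Pipeline configuration
#'
#' Bundles inputs and settings for [run_pipeline()]. Inputs may be
#' in-memory objects (an [otu_table()], [ape::phylo], [dist_matrix()]) or
#' file paths (TSV trio / Newick / square TSV). The analysis follows a
#' two-tier panel design: discovery on the single-study "core" panel (no
#' between-study confounding), validation on the full multi-study panel
#' with study-conditioned partial Mantel tests.
#'
#' @param table an [otu_table()], or NULL with `counts_path` etc. given.
#' @param counts_path,taxonomy_path,metadata_path TSV paths (used when
#'   `table` is NULL).
#' @param host_tree species-level [ape::phylo] or a Newick path.
#' @param host_dist species-level [dist_matrix()] or a square-TSV path.
#' @param rank agglomeration rank (default "genus").
#' @param min_total singleton threshold (default 2).
#' @param contaminant_terms lineage substrings to remove.
#' @param rarefy_depth "auto" (lowest sample total) or an integer.
#' @param outgroup species excluded from Mantel tests.
#' @param design_field metadata field for the binary design matrix
#'   (default "study").
#' @param core_study study id defining the core panel; NULL disables the
#'   core tier.
#' @param n_perm permutations for CID/Mantel tests (default 1000).
#' @param n_perm_permanova permutations for PERMANOVA (default 9999).
#' @param boot_reps OTU-bootstrap replicates for branch support (default
#'   1000).
#' @param discovery list(mode, n_reps, k, cid_max, r_min) or NULL to skip
#'   fraction discovery.
#' @param seed master seed; every stochastic stage gets a child seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, counts_path = NULL,
                            taxonomy_path = NULL, metadata_path = NULL,
                            host_tree, host_dist,
                            rank = "genus", min_total = 2,
                            contaminant_terms = c("archaea", "chloroplast", "mitochondria"),
                            rarefy_depth = "auto", outgroup = NULL,
                            design_field = "study", core_study = NULL,
                            n_perm = 1000, n_perm_permanova = 9999,
                            boot_reps = 1000,
                            discovery = list(mode = "subsample", n_reps = 10000,
                                             k = 10, cid_max = 0, r_min = 0.9),
                            seed = 1) {
  if (is.character(host_tree)) host_tree <- read_newick(host_tree)
  if (is.character(host_dist)) host_dist <- read_dist_matrix(host_dist)
  structure(list(table = table, counts_path = counts_path,
                 taxonomy_path = taxonomy_path, metadata_path = metadata_path,
                 host_tree = host_tree, host_dist = host_dist,
                 rank = rank, min_total = min_total,
                 contaminant_terms = contaminant_terms,
                 rarefy_depth = rarefy_depth, outgroup = outgroup,
                 design_field = design_field, core_study = core_study,
                 n_perm = n_perm, n_perm_permanova = n_perm_permanova,
                 boot_reps = boot_reps, discovery = discovery,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Restrict a table to a sample panel, dropping OTUs absent from the panel.
panel_table <- function(table, sample_ids) {
  sub <- subset_table(table, samples = sample_ids)
  keep <- colnames(sub$counts)[colSums(sub$counts) > 0]
  subset_table(sub, otus = keep)
}

#' Run the full phylosymbiosis analysis
#'
#' Executes, in order: taxonomic agglomeration, singleton/contaminant
#' filtering, rarefaction to common depth, alpha diversity, Jaccard and
#' Bray-Curtis dissimilarities, Ward dendrograms with OTU-bootstrap branch
#' support, PERMANOVA on the study factor, tip-shuffle CID tests and
#' (partial) Mantel tests of phylosymbiosis on the core and full panels,
#' then OTU fraction discovery on the core panel with consensus sets and
#' re-evaluation of the consensus on the full panel. Every stochastic stage
#' records its child seed; rerunning with the same config is bit-for-bit
#' reproducible.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, a JSON summary and
#'   per-stage TSV/Newick files are written (text formats only).
#' @return list of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  seeds <- split_seed(cfg$seed, 10)
  report <- list(stage_order = c("prepare", "alpha", "distances", "clustering",
                                 "permanova", "congruence", "mantel",
                                 "discovery", "consensus", "reevaluation"),
                 seeds = list(master = cfg$seed))

  raw <- stage("read", cfg$table %||%
                 read_otu_table(cfg$counts_path, cfg$taxonomy_path, cfg$metadata_path))
  agg <- stage("agglomerate", agglomerate(raw, cfg$rank))
  filt <- stage("filter", filter_otus(agg, cfg$min_total, cfg$contaminant_terms))
  rare <- stage("rarefy", suppressMessages(
    rarefy(filt, cfg$rarefy_depth, seed = seeds[1])))
  report$seeds$rarefy <- seeds[1]
  report$prepare <- list(n_input_otus = ncol(raw$counts),
                         n_agglomerated = ncol(agg$counts),
                         n_filtered = ncol(filt$counts),
                         depth = attr(rare, "depth"))

  report$alpha <- stage("alpha", alpha_diversity(rare))

  jac <- stage("distances", jaccard(rare))
  meta <- rare$samples
  host_ids <- meta$sample_id[meta$sample_type != "seawater"]
  full <- stage("panel_full", panel_table(rare, host_ids))
  bc_full <- stage("distances", suppressWarnings(bray_curtis(full)))
  report$panels <- list(all = meta$sample_id, full = host_ids)

  report$clustering <- stage("clustering", list(
    jaccard_tree = bootstrap_support(rare, "jaccard", reps = cfg$boot_reps,
                                     seed = seeds[2]),
    bray_tree = suppressWarnings(
      bootstrap_support(full, "bray_curtis", reps = cfg$boot_reps,
                        seed = seeds[3]))))
  report$seeds$bootstrap <- seeds[2:3]

  grp_all <- stats::setNames(meta[[cfg$design_field]], meta$sample_id)
  report$permanova <- stage("permanova", list(
    jaccard_study = permanova(jac, grp_all, n_perm = cfg$n_perm_permanova,
                              seed = seeds[4]),
    bray_study = permanova(bc_full, grp_all[host_ids],
                           n_perm = cfg$n_perm_permanova, seed = seeds[5])))
  report$seeds$permanova <- seeds[4:5]

  report$core_otus <- list(
    all_samples = core_otus(full),
    per_study = core_otus(full, group_by = cfg$design_field))

  design_full <- build_design_matrix(full$samples, cfg$design_field)
  report$congruence <- list()
  report$mantel <- list()
  report$congruence$full <- stage("congruence", reevaluate(
    colnames(full$counts), full, cfg$host_tree, cfg$host_dist,
    design = design_full, n_perm = cfg$n_perm, seed = seeds[6],
    outgroup = cfg$outgroup, panel_id = "full"))
  report$seeds$congruence_full <- seeds[6]

  core <- NULL
  if (!is.null(cfg$core_study)) {
    core_ids <- meta$sample_id[meta$sample_type != "seawater" &
                                 meta[[cfg$design_field]] == cfg$core_study]
    core <- stage("panel_core", panel_table(rare, core_ids))
    report$panels$core <- core_ids
    report$congruence$core <- stage("congruence", reevaluate(
      colnames(core$counts), core, cfg$host_tree, cfg$host_dist,
      design = NULL, n_perm = cfg$n_perm, seed = seeds[7],
      outgroup = cfg$outgroup, panel_id = "core"))
    report$seeds$congruence_core <- seeds[7]
  }

  if (!is.null(cfg$discovery)) {
    dv <- cfg$discovery
    disc_table <- core %||% full
    disc_design <- if (is.null(core)) design_full else NULL
    reps <- stage("discovery", score_replicates(
      disc_table, cfg$host_tree, cfg$host_dist, design = disc_design,
      mode = dv$mode %||% "subsample", n_reps = dv$n_reps %||% 10000,
      k = dv$k %||% 10, seed = seeds[8], outgroup = cfg$outgroup))
    qual <- qualifying_otus(reps, cid_max = dv$cid_max %||% 0,
                            r_min = dv$r_min %||% 0.9)
    report$discovery <- qual
    report$discovery_scores <- reps$scores
    report$seeds$discovery <- seeds[8]
    sets <- list(cid = qual$otus_cid, mantel = qual$otus_mantel)
    if (length(sets$cid) > 0 && length(sets$mantel) > 0) {
      report$consensus <- consensus_sets(sets)
      cons <- report$consensus$intersections$consensus
      if (length(cons) >= 2) {
        report$reevaluation <- tryCatch(
          reevaluate(cons, full, cfg$host_tree, cfg$host_dist,
                     design = design_full, n_perm = cfg$n_perm,
                     seed = seeds[9], outgroup = cfg$outgroup,
                     panel_id = "full"),
          error = function(e) paste("re-evaluation failed:", conditionMessage(e)))
        report$seeds$reevaluation <- seeds[9]
      }
    }
  }

  report$tables <- list(rarefied = rare, full = full, core = core)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Flatten the stochastic-stage results into a JSON-serializable summary.
report_summary <- function(report) {
  num <- function(x) if (is.null(x)) NULL else unclass(x)
  s <- list(stage_order = report$stage_order,
            seeds = report$seeds,
            prepare = report$prepare,
            permanova = lapply(report$permanova, function(p)
              p[c("pseudo_f", "r2", "df_model", "df_resid", "p_value", "n_perm")]),
            core_otus = lapply(report$core_otus, length))
  for (panel in names(report$congruence)) {
    rv <- report$congruence[[panel]]
    s$congruence[[panel]] <- list(
      cid = rv$cid_test$cid, p_value = rv$cid_test$p_value,
      n_otus = rv$n_otus,
      mantel_r = rv$mantel_test$r, mantel_p = rv$mantel_test$p_value,
      conditioned = rv$mantel_test$conditioned)
  }
  if (!is.null(report$discovery)) {
    q <- report$discovery
    s$discovery <- list(mode = q$mode, n_reps = q$n_reps, n_failed = q$n_failed,
                        n_qualifying_cid = q$n_qualifying_cid,
                        n_qualifying_mantel = q$n_qualifying_mantel,
                        n_otus_cid = length(q$otus_cid),
                        n_otus_mantel = length(q$otus_mantel))
  }
  if (!is.null(report$consensus)) {
    s$consensus <- list(sizes = as.list(report$consensus$sizes),
                        consensus_size = length(report$consensus$intersections$consensus),
                        recovery_pct = report$consensus$recovery_pct)
  }
  if (!is.null(report$reevaluation) && inherits(report$reevaluation, "reevaluation")) {
    rv <- report$reevaluation
    s$reevaluation <- list(panel = rv$panel_id, n_otus = rv$n_otus,
                           cid = rv$cid_test$cid, cid_p = rv$cid_test$p_value,
                           mantel_r = rv$mantel_test$r,
                           mantel_p = rv$mantel_test$p_value)
  }
  s
}

#' Write a pipeline report to disk
#'
#' One JSON summary plus per-stage TSVs and support-annotated Newick
#' dendrograms; all plain text, byte-identical across reruns with the same
#' config and seed.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  utils::write.table(report$alpha, file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$discovery_scores))
    utils::write.table(report$discovery_scores,
                       file.path(out_dir, "replicate_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$discovery)) {
    sets <- data.frame(
      otu_id = c(report$discovery$otus_cid, report$discovery$otus_mantel),
      criterion = rep(c("cid", "mantel"),
                      c(length(report$discovery$otus_cid),
                        length(report$discovery$otus_mantel))))
    utils::write.table(sets, file.path(out_dir, "otu_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_newick(report$clustering$jaccard_tree,
               file.path(out_dir, "jaccard_dendrogram.nwk"))
  write_newick(report$clustering$bray_tree,
               file.path(out_dir, "bray_dendrogram.nwk"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phylosymbiosis pipeline report\n")
  cat(sprintf("  prepared: %d -> %d -> %d OTUs, rarefied to depth %d\n",
              x$prepare$n_input_otus, x$prepare$n_agglomerated,
              x$prepare$n_filtered, x$prepare$depth))
  for (p in names(x$permanova)) {
    pm <- x$permanova[[p]]
    cat(sprintf("  PERMANOVA %s: F_%d,%d = %.3f, R2 = %.3f, P = %.4g\n", p,
                pm$df_model, pm$df_resid, pm$pseudo_f, pm$r2, pm$p_value))
  }
  for (p in names(x$congruence)) {
    rv <- x$congruence[[p]]
    cat(sprintf("  %s panel (%d OTUs): CID = %.3f (P = %.3g), Mantel r = %.3f (P = %.3g)\n",
                p, rv$n_otus, rv$cid_test$cid, rv$cid_test$p_value,
                rv$mantel_test$r, rv$mantel_test$p_value))
  }
  if (!is.null(x$discovery)) print(x$discovery)
  if (!is.null(x$reevaluation) && inherits(x$reevaluation, "reevaluation"))
    print(x$reevaluation)
  invisible(x)
}
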