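#' Agglomerate OTUs at a taxonomic rank
#'
#' Features sharing the same non-empty lineage value at `rank` are pooled by
#' summing their counts, which makes tables comparable across studies that
#' used different primer pairs. Features unassigned at `rank` are dropped
#' (cross-study comparability requires named taxa); ranks below `rank` are
#' blanked in the output taxonomy.
#'
#' @param table an [otu_table()].
#' @param rank one of "phylum", "class", "order", "family", "genus".
#' @return An `otu_table` whose OTUs are the distinct assigned values at
#'   `rank`; sample set unchanged.
#' @export
agglomerate <- function(table, rank = "genus") {
  stopifnot(inherits(table, "otu_table"))
  rank <- match.arg(rank, tax_ranks[-1])
  val <- table$taxonomy[[rank]]
  assigned <- !is.na(val) & val != ""
  if (!any(assigned)) stop("no OTU assigned at rank ", rank, call. = FALSE)
  val <- val[assigned]
  counts <- table$counts[, assigned, drop = FALSE]
  # sum columns within each rank value, preserving first-appearance order
  grp <- factor(val, levels = unique(val))
  agg <- t(rowsum(t(counts), grp))
  colnames(agg) <- levels(grp)
  keep_ranks <- tax_ranks[seq_len(match(rank, tax_ranks))]
  tax_first <- table$taxonomy[assigned, , drop = FALSE][!duplicated(val), , drop = FALSE]
  tax <- data.frame(otu_id = levels(grp))
  for (r in tax_ranks)
    tax[[r]] <- if (r %in% keep_ranks) tax_first[[r]] else NA_character_
  otu_table(agg, tax, table$samples)
}

#' Remove rare and contaminant OTUs
#'
#' Drops OTUs whose total count across samples is below `min_total`
#' (singletons at the default) and OTUs whose lineage matches any contaminant
#' term (case-insensitive substring at any rank — "chloroplast" floats
#' between ranks across taxonomy database versions).
#'
#' @param table an [otu_table()].
#' @param min_total minimum total count to retain an OTU (default 2, i.e.
#'   singletons removed).
#' @param contaminant_terms character vector of lineage substrings flagging
#'   non-bacterial or organellar reads.
#' @return A filtered `otu_table`; OTU order preserved. An empty result is
#'   allowed (with a warning).
#' @export
filter_otus <- function(table, min_total = 2,
                        contaminant_terms = c("archaea", "chloroplast", "mitochondria")) {
  stopifnot(inherits(table, "otu_table"), min_total >= 0)
  keep <- colSums(table$counts) >= min_total
  if (length(contaminant_terms) > 0) {
    lin <- tolower(do.call(paste, table$taxonomy[tax_ranks]))
    contam <- Reduce(`|`, lapply(tolower(contaminant_terms),
                                 function(t) grepl(t, lin, fixed = TRUE)))
    keep <- keep & !contam
  }
  if (!any(keep)) warning("all OTUs removed by filtering", call. = FALSE)
  otu_table(table$counts[, keep, drop = FALSE],
            table$taxonomy[keep, , drop = FALSE],
            table$samples)
}

#' Rarefy to equal read depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw from the sample's count multiset) down to a common
#' depth, removing depth as a confounder before dissimilarity analyses. OTUs
#' that drop to zero everywhere are retained in the matrix so OTU sets stay
#' aligned across analyses; presence-based computations ignore them via the
#' count > 0 rule.
#'
#' @param table an [otu_table()].
#' @param depth target depth, or "auto" for the lowest sample total.
#' @param seed integer seed (mandatory: rarefaction is stochastic).
#' @return An `otu_table` with attributes `depth` and `seed`; every sample
#'   total equals `depth`.
#' @export
rarefy <- function(table, depth = "auto", seed) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (identical(depth, "auto")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  low <- totals < depth
  if (any(low))
    stop("depth ", depth, " exceeds total counts of sample(s): ",
         paste(rownames(table$counts)[low], collapse = ", "), call. = FALSE)
  rare <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(table$counts, depth),
    # vegan's heuristic "smallest count is ..." warning misfires on tables
    # whose rarest OTU exceeds one read; integrality is already validated
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  zeroed <- colnames(rare)[colSums(rare) == 0 & colSums(table$counts) > 0]
  if (length(zeroed) > 0)
    message(length(zeroed), " OTU(s) have zero counts after rarefaction (retained)")
  out <- otu_table(rare, table$taxonomy, table$samples)
  attr(out, "depth") <- depth
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Core OTUs: shared across all samples or across groups
#'
#' An OTU is present in a sample when its count is > 0. With `group_by =
#' NULL` the core is the set of OTUs present in every sample; with a metadata
#' field, an OTU counts toward a group when present in at least one of the
#' group's samples, and the core is the set present in at least `min_groups`
#' groups.
#'
#' @param table an [otu_table()].
#' @param group_by NULL, or a sample-metadata field (e.g. "study").
#' @param min_groups minimum number of groups (default: all of them).
#' @return Character vector of core OTU ids.
#' @export
core_otus <- function(table, group_by = NULL, min_groups = NULL) {
  stopifnot(inherits(table, "otu_table"))
  pres <- table$counts > 0
  if (is.null(group_by)) {
    return(colnames(pres)[colSums(pres) == nrow(pres)])
  }
  if (!group_by %in% names(table$samples))
    stop("unknown metadata field: ", group_by, call. = FALSE)
  g <- table$samples[[group_by]]
  grp_pres <- rowsum(pres + 0, g) > 0
  min_groups <- min_groups %||% nrow(grp_pres)
  colnames(grp_pres)[colSums(grp_pres) >= min_groups]
}
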