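#' Simulate a host phylogeny and its patristic distance matrix
#'
#' Pure-birth (Yule) ingroup tree scaled to unit root-to-tip height, with an
#' outgroup attached at the root on a branch of the same height (so the tree
#' stays ultrametric). Stands in for a multi-locus host phylogeny when only
#' synthetic data are used.
#'
#' @param n_species total number of species including the outgroup (>= 4).
#' @param seed integer seed.
#' @param outgroup_label tip label of the outgroup (default "outgroup").
#' @param ingroup_height height of the ingroup crown relative to the root
#'   (default 0.75).
#' @return list with `tree` ([ape::phylo], ultrametric, unit height) and
#'   `dist` ([dist_matrix()] of patristic distances).
#' @export
simulate_host_tree <- function(n_species, seed, outgroup_label = "outgroup",
                               ingroup_height = 0.75) {
  stopifnot(n_species >= 4, ingroup_height > 0, ingroup_height < 1)
  ingroup <- with_seed(seed, ape::rphylo(n_species - 1, birth = 1, death = 0))
  ingroup$tip.label <- sprintf("species_%02d", seq_len(n_species - 1))
  depth <- max(ape::node.depth.edgelength(ingroup))
  ingroup$edge.length <- ingroup$edge.length / depth * ingroup_height
  nwk <- sub(";$", "", ape::write.tree(ingroup))
  tree <- ape::read.tree(text = sprintf("(%s:1,%s:%s)root;", outgroup_label,
                                        nwk, format(1 - ingroup_height)))
  d <- dist_matrix(ape::cophenetic.phylo(tree))
  list(tree = tree, dist = d)
}

#' Study layout emulating a multi-study shark skin survey
#'
#' Simulation configuration for the package's reference scenario: 9 host
#' species (8 ingroup + 1 outgroup) sampled as 17 host-skin samples across 6
#' studies — one "core" study holding 6 species from a single location,
#' three species replicated across two studies — plus 5 seawater control
#' samples (one per study for the first five studies). Defaults plant 20
#' phylosymbiotic OTUs among 280 study-confounded noise OTUs; read depths
#' span 30,185 to 1,677,653 as in typical amplicon meta-analyses.
#'
#' @param seed integer seed recorded in the config.
#' @return list of class `sim_config`; pass to [simulate_table()].
#' @export
default_paper_layout <- function(seed = 1) {
  sp <- sprintf("species_%02d", 1:8)
  out <- "outgroup"
  assign <- rbind(
    # core study: six species, one location, one year
    data.frame(species = c(sp[1:5], out), study = "study1",
               sample_type = "shark", year = 2017, location = "loc_A"),
    data.frame(species = c(sp[1], sp[6], sp[6]), study = "study2",
               sample_type = "shark", year = c(2018, 2018, 2019),
               location = "loc_B"),
    data.frame(species = c(sp[2], sp[7], sp[7]), study = "study3",
               sample_type = "shark", year = 2019, location = "loc_C"),
    data.frame(species = c(sp[8], sp[8]), study = "study4",
               sample_type = "shark", year = c(2016, 2017), location = "loc_D"),
    data.frame(species = sp[6], study = "study5",
               sample_type = "shark", year = 2020, location = "loc_E"),
    data.frame(species = c(sp[7], out), study = "study6",
               sample_type = "shark", year = 2021, location = "loc_F"),
    data.frame(species = "seawater", study = paste0("study", 1:5),
               sample_type = "seawater", year = 2017:2021,
               location = paste0("loc_", LETTERS[1:5]))
  )
  assign$sample_id <- sprintf("S%02d", seq_len(nrow(assign)))
  structure(list(n_species = 9,
                 n_studies = 6,
                 species_study_assignment = assign[c("sample_id", "species",
                                                     "study", "sample_type",
                                                     "year", "location")],
                 n_otus_phylo = 20,
                 n_otus_noise = 280,
                 sigma2_phylo = 4,
                 sigma2_study = 4,
                 sigma2_sample = 4,
                 sigma2_resid = 0.25,
                 baseline_sd = 1,
                 phylo_baseline_shift = 0.5,
                 depth_range = c(30185, 1677653),
                 singleton_rate = 0.05,
                 contaminant_rate = 0.03,
                 unassigned_rate = 0.1,
                 outgroup = "outgroup",
                 seed = as.integer(seed)),
            class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  with(cfg, {
    stopifnot(n_species >= 4,
              sigma2_phylo >= 0, sigma2_study >= 0, sigma2_resid >= 0,
              depth_range[1] >= 1, depth_range[2] >= depth_range[1],
              n_otus_phylo >= 0, n_otus_noise >= 0,
              n_otus_phylo + n_otus_noise > 0,
              singleton_rate >= 0, contaminant_rate >= 0,
              all(c("sample_id", "species", "study", "sample_type") %in%
                    names(species_study_assignment)))
  })
  invisible(cfg)
}

# Synthetic but structurally valid six-rank lineages.
synth_taxonomy <- function(otu_ids, contaminant, unassigned_genus, seed) {
  phyla <- c("Pseudomonadota", "Bacteroidota", "Cyanobacteriota", "Bacillota",
             "Planctomycetota", "Actinomycetota", "Verrucomicrobiota")
  n <- length(otu_ids)
  with_seed(seed, {
    ph <- sample(phyla, n, replace = TRUE,
                 prob = c(0.4, 0.2, 0.12, 0.12, 0.06, 0.06, 0.04))
    tax <- data.frame(otu_id = otu_ids,
                      domain = "Bacteria",
                      phylum = ph,
                      class = paste0(ph, "_class"),
                      order = paste0("order_", sample(40, n, replace = TRUE)),
                      family = paste0("family_", sample(120, n, replace = TRUE)),
                      genus = paste0("genus_", seq_len(n)))
    tax$genus[unassigned_genus] <- NA_character_
    tax$family[contaminant] <- "Mitochondria"
    tax$domain[contaminant] <- sample(c("Bacteria", "Archaea"),
                                      sum(contaminant), replace = TRUE)
    tax
  })
}

#' Simulate an OTU table with a planted phylosymbiotic fraction
#'
#' Log-linear abundance model with multinomial read sampling. For a
#' phylosymbiotic OTU j, species trait values z_j evolve by Brownian motion
#' (rate `sigma2_phylo` per unit branch length) on the host tree, and
#' log-abundance in host sample i is a_j + z_j(species(i)) + e; for a noise
#' OTU, log-abundance is a_j + b_(j, study(i)) + e with study effects b ~
#' N(0, `sigma2_study`) and residual e ~ N(0, `sigma2_resid`). Baselines
#' a_j ~ N(0, `baseline_sd`^2) create a log-normal rank-abundance curve.
#' Seawater samples receive baselines, study effects and residuals but no
#' species trait. Relative abundances are the softmax of the log-abundances
#' and counts are Multinomial(depth_i, p_i) with depth_i log-uniform in
#' `depth_range`, so sample totals equal the drawn depths exactly.
#' Singleton OTUs (one read, compensated from the sample's most abundant
#' OTU) and contaminant-lineage OTUs are injected at the configured rates.
#'
#' A species replicated across studies keeps the same z_j in both (its
#' trait is a host property) but draws different study effects — conspecific
#' replicates therefore cluster by study unless phylosymbiotic OTUs
#' dominate.
#'
#' @param cfg a `sim_config`, e.g. from [default_paper_layout()].
#' @return list with `table` (an [otu_table()]) and `truth` (list:
#'   `host_tree`, `host_dist`, `otu_role` factor
#'   phylo/noise/contaminant/singleton, `z` species x phylo-OTU trait
#'   matrix, `lambda` latent log-abundance matrix, `depths`, `seed`).
#' @export
simulate_table <- function(cfg) {
  validate_sim_config(cfg)
  seeds <- split_seed(cfg$seed, 9)
  meta <- cfg$species_study_assignment
  n_samp <- nrow(meta)
  host <- simulate_host_tree(cfg$n_species, seeds[1],
                             outgroup_label = cfg$outgroup %||% "outgroup")
  species <- host$tree$tip.label
  is_host <- meta$sample_type != "seawater"
  miss <- setdiff(unique(meta$species[is_host]), species)
  if (length(miss) > 0)
    stop("species in layout but not in host tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n_phylo <- cfg$n_otus_phylo
  n_noise <- cfg$n_otus_noise
  n_otu <- n_phylo + n_noise
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otu))
  role <- rep(c("phylo", "noise"), c(n_phylo, n_noise))

  # Brownian species traits for the phylosymbiotic fraction:
  # cov(z(sp1), z(sp2)) = sigma2_phylo * shared root-to-tip path length.
  V <- ape::vcv(host$tree)[species, species]
  z <- matrix(0, length(species), n_phylo,
              dimnames = list(species, otu_ids[role == "phylo"]))
  if (n_phylo > 0) {
    L <- t(chol(cfg$sigma2_phylo * V + diag(1e-10, nrow(V))))
    z <- with_seed(seeds[2],
                   L %*% matrix(stats::rnorm(nrow(V) * n_phylo), nrow(V)))
    dimnames(z) <- list(species, otu_ids[role == "phylo"])
  }
  studies <- unique(meta$study)
  b <- with_seed(seeds[3],
                 matrix(stats::rnorm(length(studies) * n_otu, 0,
                                     sqrt(cfg$sigma2_study)),
                        length(studies), n_otu,
                        dimnames = list(studies, otu_ids)))
  b[, role == "phylo"] <- 0
  a <- with_seed(seeds[4], stats::rnorm(n_otu, 0, cfg$baseline_sd))
  # host-associated symbionts sit above the bulk environmental taxa in
  # abundance; the shift puts planted OTUs at the top of the rank-abundance
  # curve so they can dominate the composition of small OTU subsets
  a[role == "phylo"] <- a[role == "phylo"] + (cfg$phylo_baseline_shift %||% 0)

  lambda <- matrix(rep(a, each = n_samp), n_samp, n_otu,
                   dimnames = list(meta$sample_id, otu_ids))
  lambda <- lambda + b[meta$study, , drop = FALSE]
  hosts <- which(is_host)
  if (n_phylo > 0)
    lambda[hosts, role == "phylo"] <-
      lambda[hosts, role == "phylo", drop = FALSE] +
      z[meta$species[hosts], , drop = FALSE]
  eps <- with_seed(seeds[5],
                   matrix(stats::rnorm(n_samp * n_otu, 0, sqrt(cfg$sigma2_resid)),
                          n_samp, n_otu))
  # shared environmental gradient: a latent per-sample score with per-OTU
  # loadings on the noise fraction. Real surveys carry such dominant
  # non-phylogenetic gradients; they give dendrograms coherent (bootstrap-
  # supported) but host-incongruent structure even within one study.
  s2samp <- cfg$sigma2_sample %||% 0
  if (s2samp > 0) {
    grad <- with_seed(seeds[5] + 1L, {
      f <- stats::rnorm(n_samp, 0, sqrt(s2samp))
      u <- stats::rnorm(n_otu)
      u[role == "phylo"] <- 0
      outer(f, u)
    })
    lambda <- lambda + grad
  }
  lambda <- lambda + eps

  depths <- with_seed(seeds[6], round(exp(stats::runif(
    n_samp, log(cfg$depth_range[1]), log(cfg$depth_range[2])))))
  counts <- with_seed(seeds[7], {
    cts <- matrix(0, n_samp, n_otu, dimnames = dimnames(lambda))
    for (i in seq_len(n_samp)) {
      p <- exp(lambda[i, ] - max(lambda[i, ]))
      cts[i, ] <- stats::rmultinom(1, depths[i], p / sum(p))
    }
    cts
  })

  # inject singletons and flag contaminant lineages
  n_single <- round(cfg$singleton_rate * n_otu)
  n_contam <- round(cfg$contaminant_rate * n_otu)
  extra <- with_seed(seeds[8], {
    res <- list()
    if (n_single > 0) {
      sm <- matrix(0, n_samp, n_single,
                   dimnames = list(meta$sample_id,
                                   sprintf("OTU_S%03d", seq_len(n_single))))
      donor <- sample.int(n_samp, n_single, replace = TRUE)
      for (j in seq_len(n_single)) {
        sm[donor[j], j] <- 1
        top <- which.max(counts[donor[j], ])
        counts[donor[j], top] <- counts[donor[j], top] - 1
      }
      res$singles <- sm
      res$counts <- counts
    } else res$counts <- counts
    res$contam <- sample(which(role == "noise"), n_contam)
    res$unassigned <- sample(which(role == "noise"),
                             round((cfg$unassigned_rate %||% 0) * n_noise))
    res
  })
  counts <- extra$counts
  if (n_single > 0) {
    counts <- cbind(counts, extra$singles)
    role <- c(role, rep("singleton", n_single))
    otu_ids <- colnames(counts)
  }
  role[extra$contam] <- "contaminant"
  contam_flag <- seq_along(otu_ids) %in% extra$contam
  unassigned_flag <- seq_along(otu_ids) %in% extra$unassigned
  tax <- synth_taxonomy(otu_ids, contam_flag, unassigned_flag, seeds[9])

  table <- otu_table(counts, tax, meta)
  truth <- list(host_tree = host$tree, host_dist = host$dist,
                otu_role = stats::setNames(factor(role), otu_ids),
                z = z, lambda = lambda, depths = stats::setNames(depths, meta$sample_id),
                seed = cfg$seed)
  list(table = table, truth = truth)
}
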