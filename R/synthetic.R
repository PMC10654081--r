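#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the study design at desk scale: 1,000 taxa on a
#' high-turnover birth-death phylogeny (extinction near speciation, giving
#' the tight clade structure of real 16S trees), 4 cellar-age groups
#' (Aa-Ad) crossed with 4 longitude groups (La-Ld), 6 samples per cell,
#' 10,000 reads per sample, Dirichlet-multinomial overdispersion at
#' roughly twice multinomial variance, a per-sample colonization lottery
#' whose dispersion declines along the age gradient, and a logistic
#' early-to-late dominant-clade succession.
#'
#' @param n_taxa number of tips / OTUs.
#' @param n_samples_per_group samples per age x region cell.
#' @param age_groups,region_groups factor level sets.
#' @param birth_rate,death_rate birth-death tree rates (birth > death >= 0).
#' @param brownian_sigma2 Brownian trait variance rate.
#' @param meta_sdlog log-normal spread of metacommunity (regional pool)
#'   relative abundances; larger values give more uneven pools.
#' @param assembly_regime `"neutral_drift"`, `"homogeneous_selection"` or
#'   `"heterogeneous_selection"`; a single value or one per age group.
#' @param selection_strength selection strength (>= 0; ignored for neutral).
#' @param succession list with `replacement_rate` (logistic rate on
#'   log10-age; 0 disables succession) and `dominance_boost` (fold weight
#'   given to the fully dominant clade); clades are chosen on the tree.
#' @param depth reads per sample.
#' @param dispersion Dirichlet-multinomial precision; the default
#'   `depth - 2` gives ~2x multinomial variance.
#' @param drift ecological-drift lottery creating taxonomic turnover
#'   between replicate communities: a list with `presence` (per-sample
#'   colonization probability of each taxon from the regional pool), `sd`
#'   (log-normal abundance noise among colonizers) and `age_factors`
#'   (per-age-group dispersion multipliers; the default declines along the
#'   age gradient, so young communities are the most dispersed — a factor
#'   `f` scales the noise to `sd * f` and the colonization probability to
#'   `1 - (1 - presence) * f`).
#' @param planted_biomarkers optional data.frame `taxon`, `group`, `fold`.
#' @param correlation_blocks optional list `sizes` (block sizes) and `rho`
#'   (within-block latent correlation) for [simulate_correlated_table()].
#' @param seed integer seed; the seed fully determines all output.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 1000, n_samples_per_group = 6,
                            age_groups = c("Aa", "Ab", "Ac", "Ad"),
                            region_groups = c("La", "Lb", "Lc", "Ld"),
                            birth_rate = 1, death_rate = 0.999,
                            brownian_sigma2 = 1, meta_sdlog = 1,
                            assembly_regime = "neutral_drift",
                            selection_strength = 0,
                            succession = list(replacement_rate = 3,
                                              dominance_boost = 15),
                            depth = 10000, dispersion = NULL,
                            drift = list(presence = 0.35, sd = 0.5,
                                         age_factors = c(1, 0.75, 0.5, 0.25)),
                            planted_biomarkers = NULL,
                            correlation_blocks = NULL, seed = 1L) {
  if (birth_rate <= death_rate || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  regimes <- c("neutral_drift", "homogeneous_selection",
               "heterogeneous_selection")
  if (!all(assembly_regime %in% regimes))
    stop("unknown assembly_regime")
  if (!length(assembly_regime) %in% c(1, length(age_groups)))
    stop("assembly_regime must be length 1 or one per age group")
  if (is.null(dispersion)) dispersion <- depth - 2
  structure(list(n_taxa = n_taxa, n_samples_per_group = n_samples_per_group,
                 age_groups = age_groups, region_groups = region_groups,
                 birth_rate = birth_rate, death_rate = death_rate,
                 brownian_sigma2 = brownian_sigma2, meta_sdlog = meta_sdlog,
                 assembly_regime = assembly_regime,
                 selection_strength = selection_strength,
                 succession = succession, depth = depth,
                 dispersion = dispersion, drift = drift,
                 planted_biomarkers = planted_biomarkers,
                 correlation_blocks = correlation_blocks, seed = seed),
            class = "scenario_config")
}

#' Simulate a birth-death phylogeny over OTU tips
#'
#' Ultrametric tree conditioned on the configured tip count, tips labelled
#' `OTU_0001` onward; identical seeds give identical Newick strings.
#'
#' @param config `scenario_config`.
#' @return `ape::phylo`.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_taxa, birth = config$birth_rate,
                      death = config$death_rate)
  tree$tip.label <- sprintf("OTU_%04d", seq_len(config$n_taxa))
  tree
}

# pick two disjoint clades of moderate size for the succession crossover;
# deterministic given the tree
.pick_clades <- function(tree, lo = 0.08, hi = 0.3) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(nd)
    length(.clade_tips(tree, nd)), integer(1))
  ok <- internal[sizes >= lo * ntip & sizes <= hi * ntip]
  if (length(ok) < 2) ok <- internal[order(abs(sizes - 0.15 * ntip))][1:4]
  first <- ok[1]
  t1 <- .clade_tips(tree, first)
  second <- NULL
  for (nd in ok[-1]) {
    t2 <- .clade_tips(tree, nd)
    if (!length(intersect(t1, t2))) { second <- nd; break }
  }
  if (is.null(second)) stop("could not find two disjoint clades")
  list(early = tree$tip.label[t1],
       late = tree$tip.label[.clade_tips(tree, second)])
}

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Simulate communities under a configured assembly regime
#'
#' A trait evolves on the tree under Brownian motion; each sample has an
#' environmental optimum (one shared value per group under homogeneous
#' selection, spread across samples under heterogeneous selection, unused
#' under neutral drift) and taxon fitness
#' \eqn{\exp(-s (trait - E)^2)} with normalized strength `s`. Log-normal
#' metacommunity abundances times fitness, the logistic succession
#' crossover of the two dominant clades, and any planted biomarker
#' fold-changes give expected proportions; counts are drawn
#' Dirichlet-multinomial at the configured depth and dispersion.
#'
#' @param tree phylogeny from [simulate_tree()].
#' @param config `scenario_config`.
#' @return list with `table` (`community_table` of counts), `frame`
#'   (metadata) and `truth` (regimes, traits, clades, expected dominance
#'   trajectory, planted biomarkers).
#' @export
simulate_communities <- function(tree, config) {
  set.seed(config$seed + 1L)
  nt <- config$n_taxa
  trait <- ape::rTraitCont(tree, model = "BM",
                           sigma = sqrt(config$brownian_sigma2))
  trait <- trait[tree$tip.label]
  meta <- rlnorm(nt, meanlog = 0, sdlog = config$meta_sdlog)
  names(meta) <- tree$tip.label
  clades <- .pick_clades(tree)
  ages <- c(Aa = 5, Ab = 30, Ac = 100, Ad = 350)
  regimes <- config$assembly_regime
  if (length(regimes) == 1) regimes <- rep(regimes, length(config$age_groups))
  names(regimes) <- config$age_groups
  s_norm <- config$selection_strength / (2 * max(var(trait), 1e-12))
  rate <- config$succession$replacement_rate
  boost <- config$succession$dominance_boost
  la <- log10(ages[config$age_groups])
  mid <- mean(range(la))
  fac <- setNames(rep_len(config$drift$age_factors,
                          length(config$age_groups)), config$age_groups)
  drift_sd <- config$drift$sd * fac
  drift_pi <- 1 - (1 - config$drift$presence) * fac
  counts <- NULL; rows <- list(); truth_E <- list()
  dom_expect <- matrix(NA_real_, length(config$age_groups), 2,
                       dimnames = list(config$age_groups, c("early", "late")))
  for (ag in config$age_groups) {
    f_late <- 1 / (1 + exp(-rate * (log10(ages[ag]) - mid)))
    w_succ <- rep(1, nt); names(w_succ) <- tree$tip.label
    if (rate > 0) {
      w_succ[clades$early] <- 1 + boost * (1 - f_late)
      w_succ[clades$late] <- 1 + boost * f_late
    }
    # optimum anchored at an existing tip's trait so the fitness window
    # sits on a realized trait clump rather than between clades
    E_group <- trait[sample.int(nt, 1)]
    for (rg in config$region_groups) {
      for (i in seq_len(config$n_samples_per_group)) {
        sid <- sprintf("%s_%s_%02d", ag, rg, i)
        regime <- regimes[ag]
        # one per-sample optimum is always drawn so all regimes consume the
        # same RNG stream and selection_strength = 0 reduces every regime
        # to the identical neutral draw
        E_i <- trait[sample.int(nt, 1)]
        w_fit <- switch(regime,
                        neutral_drift = rep(1, nt),
                        homogeneous_selection =
                          exp(-s_norm * (trait - E_group)^2),
                        heterogeneous_selection =
                          exp(-s_norm * (trait - E_i)^2))
        if (regime == "heterogeneous_selection") truth_E[[sid]] <- E_i
        # ecological drift: per-sample colonization lottery plus abundance
        # noise among the colonizers
        arrived <- runif(nt) < drift_pi[ag]
        w_drift <- arrived * exp(rnorm(nt, 0, drift_sd[ag]))
        p <- meta * w_fit * w_succ * w_drift
        if (sum(p) == 0) p <- meta * w_fit * w_succ   # empty lottery guard
        if (!is.null(config$planted_biomarkers)) {
          pb <- config$planted_biomarkers
          hit <- pb$group == ag & pb$taxon %in% names(p)
          if (any(hit)) p[pb$taxon[hit]] <- p[pb$taxon[hit]] * pb$fold[hit]
        }
        p <- p / sum(p)
        gam <- rgamma(nt, shape = config$dispersion * p)
        if (sum(gam) == 0) gam <- p
        cnt <- rmultinom(1, config$depth, gam / sum(gam))[, 1]
        counts <- cbind(counts, cnt)
        rows[[sid]] <- data.frame(
          sample_id = sid, age_group = ag, age_years = unname(ages[ag]),
          longitude_group = rg,
          longitude_deg = c(La = 105, Lb = 113, Lc = 115.5, Ld = 118.5)[rg],
          stringsAsFactors = FALSE)
        colnames(counts)[ncol(counts)] <- sid
      }
    }
    dom_expect[ag, ] <- c(sum((meta * w_succ)[clades$early]),
                          sum((meta * w_succ)[clades$late])) /
      sum(meta * w_succ)
  }
  rownames(counts) <- tree$tip.label
  frame <- sample_frame(do.call(rbind, rows))
  truth <- list(regimes = regimes, trait = trait, clades = clades,
                dominance_trajectory = dom_expect,
                planted_biomarkers = config$planted_biomarkers,
                env_optima = truth_E, metacommunity = meta)
  list(table = community_table(counts), frame = frame, truth = truth)
}

#' Simulate a count table with planted correlation blocks
#'
#' Latent Gaussian copula with block-diagonal correlation (within-block
#' `rho`, zero across blocks), rank-preserving transform to log-normal
#' abundances, then Dirichlet-multinomial counts — a fixture with known
#' co-occurrence structure for the network stage.
#'
#' @param config `scenario_config` with `correlation_blocks` set; taxa not
#'   covered by the blocks are independent noise.
#' @param n_samples number of samples (default 200).
#' @return list with `table` (`community_table` of counts) and `truth`
#'   (block membership vector).
#' @export
simulate_correlated_table <- function(config, n_samples = 200) {
  cb <- config$correlation_blocks
  if (is.null(cb)) stop("config$correlation_blocks is not set")
  if (sum(cb$sizes) > config$n_taxa) stop("block sizes exceed n_taxa")
  if (any(cb$rho <= -1 | cb$rho >= 1)) stop("rho must lie in (-1, 1)")
  if (any(cb$rho < 0))
    stop("equicorrelated blocks need rho >= 0 to stay positive definite")
  set.seed(config$seed + 2L)
  nt <- config$n_taxa
  block <- rep(0L, nt)
  block[seq_len(sum(cb$sizes))] <- rep(seq_along(cb$sizes), cb$sizes)
  rho <- rep(cb$rho, length.out = length(cb$sizes))
  z <- matrix(rnorm(n_samples * nt), n_samples, nt)
  for (b in seq_along(cb$sizes)) {
    idx <- which(block == b)
    common <- rnorm(n_samples)
    z[, idx] <- sqrt(rho[b]) * common +
      sqrt(1 - rho[b]) * z[, idx, drop = FALSE]
  }
  meanlog <- rnorm(nt, 0, 1)
  abun <- t(qlnorm(pnorm(t(z)), meanlog = meanlog, sdlog = 1))
  counts <- apply(abun, 1, function(a) {
    p <- a / sum(a)
    gam <- rgamma(nt, shape = config$dispersion * p)
    rmultinom(1, config$depth, gam / sum(gam))[, 1]
  })
  rownames(counts) <- sprintf("OTU_%04d", seq_len(nt))
  colnames(counts) <- sprintf("S_%03d", seq_len(n_samples))
  names(block) <- rownames(counts)
  list(table = community_table(counts), truth = list(block = block))
}

#' Derive a taxonomy table for a simulated tree
#'
#' Assigns lineage labels by cutting the tree at successive depths so that
#' related tips share higher ranks — enough taxonomic structure for
#' aggregation, overlap and network-annotation stages.
#'
#' @param tree `ape::phylo` from [simulate_tree()].
#' @param n_per_rank approximate number of distinct labels per rank
#'   (phylum, class, order, family, genus).
#' @return taxonomy data.frame as from [read_taxonomy()].
#' @export
simulate_taxonomy <- function(tree, n_per_rank = c(4, 8, 15, 25, 40)) {
  h <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(h), method = "average")
  ranks <- .rank_ladder
  out <- data.frame(taxon_id = tree$tip.label, stringsAsFactors = FALSE)
  for (i in seq_along(ranks)) {
    k <- min(n_per_rank[i], length(tree$tip.label))
    grp <- stats::cutree(hc, k = k)
    out[[ranks[i]]] <- sprintf("%s_%02d", ranks[i], grp[out$taxon_id])
  }
  out
}
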