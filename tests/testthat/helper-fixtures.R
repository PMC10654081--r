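# fixture builders and independent reference implementations used as
# oracles across the suite; everything is generated in code

# small random count table with guaranteed nonempty samples
random_table <- function(n_taxa, n_samples, seed = 1, lambda = 5) {
  set.seed(seed)
  x <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  empty <- colSums(x) == 0
  x[1, empty] <- 1
  community_table(x)
}

# brute-force betaMNTD by full cophenetic enumeration (independent of the
# compiled kernel): for each taxon present in one sample, scan all taxa
# present in the other
ref_beta_mntd <- function(rel, tree, k, m) {
  D <- ape::cophenetic.phylo(tree)
  x <- rel$counts
  pk <- rownames(x)[x[, k] > 0]
  pm <- rownames(x)[x[, m] > 0]
  fk <- x[pk, k] / sum(x[pk, k])
  fm <- x[pm, m] / sum(x[pm, m])
  mins_k <- vapply(pk, function(i) min(D[i, pm]), numeric(1))
  mins_m <- vapply(pm, function(i) min(D[i, pk]), numeric(1))
  0.5 * (sum(fk * mins_k) + sum(fm * mins_m))
}

# independent Spearman screen: per-pair cor.test double loop
ref_correlation_screen <- function(rel, rho_threshold = 0.7, alpha = 0.01) {
  x <- rel$counts
  out <- list()
  for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    if (length(unique(x[i, ])) == 1 || length(unique(x[j, ])) == 1) next
    ct <- suppressWarnings(cor.test(x[i, ], x[j, ], method = "spearman",
                                    exact = FALSE))
    if (abs(ct$estimate) > rho_threshold && ct$p.value < alpha)
      out[[length(out) + 1]] <- data.frame(
        taxon_u = rownames(x)[i], taxon_v = rownames(x)[j],
        rho = unname(ct$estimate), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(taxon_u = character(0),
                                      taxon_v = character(0),
                                      rho = numeric(0)))
  do.call(rbind, out)
}

# 4-tip balanced tree used in hand-enumerated UniFrac / betaMNTD checks
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# metadata frame for ad-hoc tables: one age group per block of samples
block_frame <- function(sids, groups_per_block) {
  data.frame(sample_id = sids,
             age_group = rep(groups_per_block,
                             length.out = length(sids)),
             longitude_group = "La",
             stringsAsFactors = FALSE)
}

# shared fixture: neutral communities with 12 planted OTUs whose abundance
# rises monotonically with age (fold 1, 4, 16, 64 across Aa..Ad); the other
# 288 taxa carry no age signal
planted_scenario <- function(seed = 11, n_taxa = 300, n_per = 4,
                             depth = 2000) {
  taxa <- sprintf("OTU_%04d", 1:12)
  pb <- expand.grid(taxon = taxa, group = c("Aa", "Ab", "Ac", "Ad"),
                    stringsAsFactors = FALSE)
  pb$fold <- c(Aa = 1, Ab = 4, Ac = 16, Ad = 64)[pb$group]
  cfg <- scenario_config(n_taxa = n_taxa, n_samples_per_group = n_per,
                         depth = depth,
                         succession = list(replacement_rate = 0,
                                           dominance_boost = 0),
                         drift = list(presence = 1, sd = 1.5,
                                      age_factors = 1),
                         planted_biomarkers = pb, seed = seed)
  tree <- simulate_tree(cfg)
  sim <- simulate_communities(tree, cfg)
  list(sim = sim, tree = tree, planted = taxa)
}

# adjusted Rand index between two label vectors (closed-form contingency
# computation; independent of any clustering package)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / (0.5 * (sum_a + sum_b) - exp_idx)
}
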