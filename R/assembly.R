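#' Between-community mean nearest taxon distance
#'
#' Abundance-weighted betaMNTD for one sample pair:
#' \deqn{0.5 \left[ \sum_{i_k} f_{i_k} \min_{j_m}(\Delta_{i_k j_m}) +
#'       \sum_{i_m} f_{i_m} \min_{j_k}(\Delta_{i_m j_k}) \right]}
#' where \eqn{f} are within-sample relative abundances over the taxa
#' present in that sample, \eqn{\Delta} are cophenetic tree distances, and
#' the minimum runs over taxa present in the other sample (shared taxa
#' contribute distance 0 to themselves).
#'
#' @param table `community_table` (counts or relative); abundances are
#'   renormalized within each sample over tree-resident taxa.
#' @param tree rooted `ape::phylo`; tips must cover the table's taxa (use
#'   [match_tree()] first if not).
#' @param pair length-2 vector of sample ids or indices.
#' @param weighted if `FALSE`, presence/absence weights (1/richness) are
#'   used instead of relative abundances.
#' @return betaMNTD value in tree branch-length units.
#' @export
beta_mntd <- function(table, tree, pair, weighted = TRUE) {
  prep <- .assembly_prep(table, tree, weighted)
  idx <- pair
  if (is.character(pair)) idx <- match(pair, colnames(prep$X))
  if (anyNA(idx) || length(idx) != 2) stop("`pair` must name two samples")
  pairs <- matrix(as.integer(idx - 1L), 1, 2)
  as.numeric(mntd_pairs(prep$D, prep$X, prep$pres, pairs,
                        seq_len(nrow(prep$D)) - 1L))
}

# Align table with tree, renormalize per-sample weights, precompute the
# cophenetic matrix and presence index lists (0-based for the C++ kernel).
.assembly_prep <- function(table, tree, weighted = TRUE) {
  stopifnot(inherits(table, "community_table"), inherits(tree, "phylo"))
  missing <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "),
         "; run match_tree() first")
  extra <- setdiff(tree$tip.label, taxon_ids(table))
  if (length(extra)) tree <- ape::keep.tip(tree, intersect(tree$tip.label,
                                                           taxon_ids(table)))
  D <- ape::cophenetic.phylo(tree)
  # rows of X aligned with D so the kernel shares one indexing
  x <- table$counts[rownames(D), , drop = FALSE]
  if (!weighted) x <- (x > 0) * 1
  cs <- colSums(x)
  if (any(cs == 0)) stop("sample(s) with no tree-resident taxa: ",
                         paste(colnames(x)[cs == 0], collapse = ", "))
  X <- sweep(x, 2, cs, "/")
  pres <- lapply(seq_len(ncol(X)), function(j) which(X[, j] > 0) - 1L)
  list(D = D, X = X, pres = pres)
}

#' betaNTI null-model z-scores for sample pairs
#'
#' For every requested sample pair, the observed betaMNTD is compared with
#' a null distribution obtained by shuffling taxon identities across the
#' tips of the phylogeny (`taxa.labels`-style randomization, preserving
#' each sample's abundance vector and richness) `n_null` times:
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}}) /
#'       sd(\beta MNTD_{null})}
#' Identical seeds give identical output regardless of pair order. Pairs
#' whose null distribution is degenerate (sd = 0) are flagged with
#' `degenerate = TRUE` and carry `NA` betaNTI.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffle randomizations (>= 99; default 999).
#' @param seed integer seed.
#' @param pairs optional 2-column matrix of sample ids (or indices); default
#'   all unordered pairs.
#' @param frame,group_col if given, restricts `pairs` to within-group pairs
#'   and records the group label.
#' @return data.frame with `sample_k`, `sample_m`, `group` (NA when not
#'   restricted), `beta_mntd_obs`, `null_mean`, `null_sd`, `n_null`,
#'   `beta_nti`, `class`, `degenerate`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = 1L, pairs = NULL,
                     frame = NULL, group_col = "age_group", weighted = TRUE) {
  if (n_null < 99) stop("n_null must be >= 99")
  prep <- .assembly_prep(table, tree, weighted)
  sids <- colnames(prep$X)
  n <- length(sids)
  grp_of <- rep(NA_character_, n)
  if (!is.null(frame)) {
    grp_of <- as.character(frame[[group_col]][match(sids, frame$sample_id)])
  }
  if (is.null(pairs)) {
    pr <- t(combn(n, 2))
    if (!is.null(frame)) {
      same <- grp_of[pr[, 1]] == grp_of[pr[, 2]] &
        !is.na(grp_of[pr[, 1]]) & !is.na(grp_of[pr[, 2]])
      pr <- pr[same, , drop = FALSE]
    }
  } else {
    pr <- pairs
    if (is.character(pr)) pr <- matrix(match(pr, sids), ncol = 2)
    pr <- as.matrix(pr)
    if (anyNA(pr)) stop("unknown sample id in `pairs`")
  }
  if (!nrow(pr)) stop("no sample pairs to evaluate")
  pr0 <- matrix(as.integer(pr - 1L), ncol = 2)
  ident <- seq_len(nrow(prep$D)) - 1L
  obs <- as.numeric(mntd_pairs(prep$D, prep$X, prep$pres, pr0, ident))
  set.seed(seed)
  s1 <- 0; s2 <- 0
  nt <- nrow(prep$D)
  for (r in seq_len(n_null)) {
    perm <- sample.int(nt) - 1L
    v <- as.numeric(mntd_pairs(prep$D, prep$X, prep$pres, pr0, perm))
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  null_mean <- s1 / n_null
  null_sd <- sqrt(pmax(0, (s2 - n_null * null_mean^2) / (n_null - 1)))
  degenerate <- null_sd <= .Machine$double.eps^0.5
  if (any(degenerate))
    warning(sum(degenerate), " pair(s) with degenerate null (sd = 0) flagged")
  bnti <- ifelse(degenerate, NA_real_, (obs - null_mean) / null_sd)
  res <- data.frame(
    sample_k = sids[pr[, 1]], sample_m = sids[pr[, 2]],
    group = ifelse(!is.na(grp_of[pr[, 1]]) & grp_of[pr[, 1]] == grp_of[pr[, 2]],
                   grp_of[pr[, 1]], NA_character_),
    beta_mntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
    n_null = n_null, beta_nti = bnti, stringsAsFactors = FALSE)
  res$class <- NA_character_
  res$class[!degenerate] <- classify_assembly(res$beta_nti[!degenerate])
  res$degenerate <- degenerate
  res
}

#' Classify betaNTI values into assembly processes
#'
#' betaNTI > 2 is heterogeneous selection, betaNTI < -2 homogeneous
#' selection, |betaNTI| <= 2 stochastic (the boundary value 2 is
#' stochastic; the selection rules use strict inequalities).
#'
#' @param beta_nti numeric vector of finite betaNTI values.
#' @return character vector in
#'   `{"stochastic", "homogeneous_selection", "heterogeneous_selection"}`.
#' @export
classify_assembly <- function(beta_nti) {
  if (any(!is.finite(beta_nti))) stop("betaNTI values must be finite")
  ifelse(beta_nti > 2, "heterogeneous_selection",
         ifelse(beta_nti < -2, "homogeneous_selection", "stochastic"))
}

#' Per-group assembly-process fractions
#'
#' Tabulates the fraction of within-group sample pairs assigned to each
#' assembly class; the three fractions sum to 1 per group. Degenerate
#' pairs are excluded.
#'
#' @param results data.frame from [beta_nti()].
#' @param frame metadata frame (used when `results$group` is absent).
#' @param group_col grouping column.
#' @return data.frame with `group`, `frac_stochastic`, `frac_homogeneous`,
#'   `frac_heterogeneous`, `n_pairs`.
#' @export
assembly_fractions <- function(results, frame = NULL, group_col = "age_group") {
  res <- results[!results$degenerate, , drop = FALSE]
  if (all(is.na(res$group))) {
    if (is.null(frame)) stop("no group labels: supply `frame`")
    gk <- frame[[group_col]][match(res$sample_k, frame$sample_id)]
    gm <- frame[[group_col]][match(res$sample_m, frame$sample_id)]
    res$group <- ifelse(as.character(gk) == as.character(gm),
                        as.character(gk), NA_character_)
  }
  res <- res[!is.na(res$group), , drop = FALSE]
  if (!nrow(res)) stop("no within-group pairs")
  out <- lapply(split(res, res$group), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1],
               frac_stochastic = mean(d$class == "stochastic"),
               frac_homogeneous = mean(d$class == "homogeneous_selection"),
               frac_heterogeneous = mean(d$class == "heterogeneous_selection"),
               n_pairs = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Within-sample standardized nearest taxon index (ses.MNTD)
#'
#' Secondary statistic using the same tip-shuffle null machinery: for each
#' sample, the abundance-weighted mean distance from each taxon to its
#' nearest co-occurring taxon, standardized against `n_null` tip shuffles.
#' Reported as the negative z-score (NTI convention).
#'
#' @inheritParams beta_nti
#' @return data.frame with `sample_id`, `mntd_obs`, `null_mean`, `null_sd`,
#'   `nti`.
#' @export
ses_mntd <- function(table, tree, n_null = 999, seed = 1L, weighted = TRUE) {
  if (n_null < 99) stop("n_null must be >= 99")
  prep <- .assembly_prep(table, tree, weighted)
  D <- prep$D; X <- prep$X
  one <- function(perm) {
    vapply(seq_len(ncol(X)), function(j) {
      p <- prep$pres[[j]] + 1L
      if (length(p) < 2) return(0)
      tips <- perm[p]
      Ds <- D[tips, tips, drop = FALSE]
      diag(Ds) <- Inf
      nearest <- apply(Ds, 1, min)
      f <- X[p, j] / sum(X[p, j])
      sum(f * nearest)
    }, numeric(1))
  }
  ident <- seq_len(nrow(D))
  obs <- one(ident)
  set.seed(seed)
  s1 <- 0; s2 <- 0
  for (r in seq_len(n_null)) {
    v <- one(sample.int(nrow(D)))
    s1 <- s1 + v; s2 <- s2 + v * v
  }
  nm <- s1 / n_null
  nsd <- sqrt(pmax(0, (s2 - n_null * nm^2) / (n_null - 1)))
  data.frame(sample_id = colnames(X), mntd_obs = obs, null_mean = nm,
             null_sd = nsd, nti = -(obs - nm) / nsd,
             stringsAsFactors = FALSE)
}
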