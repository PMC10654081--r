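#' Alpha-diversity indices per sample
#'
#' Chao1 (bias-corrected), Shannon (natural log) and Pielou evenness from a
#' rarefied count table. The bias-corrected Chao1 is
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))} with \eqn{F_1, F_2} the singleton
#' and doubleton counts, so it is defined even when no doubletons exist and
#' reduces to \eqn{S_{obs}} when \eqn{F_1 = 0}. Pielou is
#' \eqn{H / \ln S_{obs}} (NA for single-taxon samples).
#'
#' @param table `community_table` of counts (typically rarefied).
#' @return data.frame with columns `sample_id`, `observed_richness`,
#'   `chao1`, `shannon`, `pielou`.
#' @export
alpha_indices <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (table$is_relative) stop("alpha indices require counts")
  x <- table$counts
  if (any(colSums(x) == 0))
    stop("empty sample(s): ", paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    v <- v[v > 0]
    s_obs <- length(v)
    f1 <- sum(v == 1)
    f2 <- sum(v == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- v / sum(v)
    shannon <- -sum(p * log(p))
    pielou <- if (s_obs > 1) shannon / log(s_obs) else NA_real_
    data.frame(sample_id = colnames(x)[j], observed_richness = s_obs,
               chao1 = chao1, shannon = shannon, pielou = pielou,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Ordinary least-squares trend fit
#'
#' Linear regression of an index or relative abundance on numeric cellar
#' age, reporting slope, intercept, R-squared and the two-sided t-test
#' p-value on the slope.
#'
#' @param x numeric predictor (e.g. age in years).
#' @param y numeric response.
#' @return data.frame with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
trend_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("trend regression needs n >= 3")
  if (length(unique(x)) < 2) stop("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r_squared = sm$r.squared,
             p_value = unname(sm$coefficients[2, 4]), n = length(x))
}

#' Pairwise dissimilarity matrices
#'
#' [bray_curtis()] computes Bray-Curtis dissimilarity on relative
#' abundances; [weighted_unifrac()] computes the normalized weighted
#' UniFrac distance
#' \eqn{\sum_b l_b |A_b - B_b| / \sum_b l_b (A_b + B_b)} over branches
#' \eqn{b} with length \eqn{l_b} and descendant-tip abundance fractions
#' \eqn{A_b, B_b}; both are bounded in \[0, 1\].
#'
#' @param table relative-abundance `community_table`.
#' @return a `pairwise_matrix`: list with `values` (symmetric matrix, zero
#'   diagonal) and `metric_name`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (!table$is_relative) table <- to_relative(table)
  d <- as.matrix(vegan::vegdist(t(table$counts), method = "bray"))
  pairwise_matrix(d, "bray_curtis")
}

#' @rdname bray_curtis
#' @param tree rooted `ape::phylo` whose tips cover every taxon in `table`.
#' @export
weighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "community_table"), inherits(tree, "phylo"))
  if (!table$is_relative) table <- to_relative(table)
  missing <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "))
  ntip <- length(tree$tip.label)
  x <- table$counts
  # per-branch descendant-tip abundance fraction, accumulated bottom-up
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nnode, ncol(x))
  acc[match(taxon_ids(table), tree$tip.label), ] <- x
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    acc[par, ] <- acc[par, ] + acc[child, ]
  }
  b_frac <- acc[tree$edge[, 2], , drop = FALSE]  # one row per branch
  len <- tree$edge.length
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    num <- sum(len * abs(b_frac[, j] - b_frac[, k]))
    den <- sum(len * (b_frac[, j] + b_frac[, k]))
    d[j, k] <- d[k, j] <- if (den > 0) num / den else 0
  }
  pairwise_matrix(d, "weighted_unifrac")
}

#' Construct a labelled pairwise sample matrix
#'
#' @param values symmetric numeric matrix with zero diagonal and matching
#'   dimnames.
#' @param metric_name label of the metric.
#' @return object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, metric_name) {
  if (!isSymmetric(unname(values), tol = 1e-8))
    stop("pairwise matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("pairwise matrix must have zero diagonal")
  if (is.null(rownames(values)))
    stop("pairwise matrix needs sample-id dimnames")
  structure(list(values = values, sample_ids = rownames(values),
                 metric_name = metric_name),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix '%s': %d samples\n", x$metric_name,
              nrow(x$values)))
  invisible(x)
}

#' Write a pairwise matrix as square TSV
#' @param pm `pairwise_matrix`.
#' @param path output path.
#' @export
write_pairwise <- function(pm, path) {
  df <- data.frame(sample_id = pm$sample_ids, pm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Rank-based stress minimization with multiple seeded random restarts
#' (vegan's monoMDS engine); coordinates are centered at the origin and the
#' final stress is reported.
#'
#' @param dist `pairwise_matrix`.
#' @param k target dimension (default 2).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param trymax number of random restarts.
#' @return list with `coordinates` (samples x k matrix) and `stress`.
#' @export
nmds <- function(dist, k = 2, seed = 1L, trymax = 20) {
  stopifnot(inherits(dist, "pairwise_matrix"))
  if (nrow(dist$values) < 4) stop("NMDS needs at least 4 samples")
  set.seed(seed)
  fit <- vegan::metaMDS(as.dist(dist$values), k = k, trymax = trymax,
                        trace = 0, autotransform = FALSE, wascores = FALSE,
                        maxit = 500)
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- dist$sample_ids
  colnames(coords) <- paste0("axis", seq_len(k))
  list(coordinates = coords, stress = fit$stress)
}

#' PERMANOVA variance partitioning
#'
#' Sequential (Type-I) sums of squares on the Gower-centered distance
#' matrix via `vegan::adonis2`, with p-values by free permutation of sample
#' labels. Term R-squared fractions plus the residual sum to 1.
#'
#' @param dist `pairwise_matrix`.
#' @param frame sample metadata frame.
#' @param terms ordered character vector of metadata columns
#'   (default `c("age_group", "longitude_group")`).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame with per-term `sum_of_squares`, `df`, `pseudo_F`,
#'   `r2_fraction`, `p_value`, plus Residual and Total rows.
#' @export
permanova <- function(dist, frame, terms = c("age_group", "longitude_group"),
                      n_perm = 999, seed = 1L) {
  stopifnot(inherits(dist, "pairwise_matrix"))
  if (n_perm < 99) stop("n_perm must be >= 99")
  miss <- setdiff(terms, names(frame))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
  frame <- frame[match(dist$sample_ids, frame$sample_id), , drop = FALSE]
  for (tm in terms) {
    if (length(unique(na.omit(frame[[tm]][frame$sample_id %in% dist$sample_ids]))) < 2)
      stop("term '", tm, "' has a single level")
  }
  dat <- droplevels(as.data.frame(frame[, terms, drop = FALSE]))
  fml <- as.formula(paste("as.dist(dist$values) ~", paste(terms, collapse = " + ")))
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = dat, permutations = n_perm, by = "terms")
  data.frame(term = rownames(fit),
             sum_of_squares = fit$SumOfSqs, df = fit$Df,
             pseudo_F = fit$F, r2_fraction = fit$R2,
             p_value = fit$`Pr(>F)`, row.names = NULL)
}

#' Within-group dissimilarity distributions and trend
#'
#' Collects all within-group pairwise distances per group, tests for
#' between-group differences (Kruskal-Wallis plus pairwise Wilcoxon with
#' Holm adjustment) and assesses the monotone temporal trend by regressing
#' group medians on the group age rank.
#'
#' @param dist `pairwise_matrix`.
#' @param frame metadata frame.
#' @param group_col metadata column defining groups.
#' @return list with `distributions` (long data.frame group/value),
#'   `medians`, `kruskal_p`, `pairwise_p` (matrix) and `trend`
#'   (a [trend_regression()] row on medians vs. group rank).
#' @export
group_dissimilarity <- function(dist, frame, group_col = "age_group") {
  stopifnot(inherits(dist, "pairwise_matrix"))
  frame <- frame[match(dist$sample_ids, frame$sample_id), , drop = FALSE]
  grp <- frame[[group_col]]
  tab <- table(grp)
  small <- names(tab)[tab < 2 & tab > 0]
  if (length(small)) stop("group(s) with < 2 samples: ", paste(small, collapse = ", "))
  long <- do.call(rbind, lapply(names(tab)[tab >= 2], function(g) {
    idx <- which(grp == g)
    v <- dist$values[idx, idx][upper.tri(diag(length(idx)))]
    data.frame(group = g, value = v, stringsAsFactors = FALSE)
  }))
  long$group <- factor(long$group, levels = levels(factor(grp)))
  med <- tapply(long$value, long$group, median)
  kw <- kruskal.test(value ~ group, data = long)
  pw <- if (nlevels(long$group) > 2)
    pairwise.wilcox.test(long$value, long$group, p.adjust.method = "holm")$p.value
  else NULL
  trend <- if (length(med) >= 3)
    trend_regression(seq_along(med), as.numeric(med)) else NULL
  list(distributions = long, medians = med, kruskal_p = kw$p.value,
       pairwise_p = pw, trend = trend)
}

#' Per-group unique and shared taxa at a rank
#'
#' Aggregates the table at the given rank, defines group-level presence as
#' nonzero abundance in at least one sample of the group, and returns the
#' full inclusion-exclusion partition over groups (Venn-style).
#'
#' @param table `community_table`.
#' @param taxonomy taxonomy data.frame.
#' @param rank taxonomic rank.
#' @param frame metadata frame.
#' @param group_col grouping column.
#' @return list with `membership` (taxon -> "+"-separated group pattern),
#'   `partition` (named list of taxon sets per pattern), and `unique`
#'   (named list of taxa exclusive to each group).
#' @export
taxon_overlap <- function(table, taxonomy, rank, frame, group_col = "longitude_group") {
  agg <- aggregate_taxa(table, taxonomy, rank)
  frame <- frame[match(sample_ids(agg), frame$sample_id), , drop = FALSE]
  grp <- droplevels(factor(frame[[group_col]]))
  present <- sapply(levels(grp), function(g)
    rowSums(agg$counts[, grp == g, drop = FALSE] > 0) > 0)
  present <- present[rowSums(present) > 0, , drop = FALSE]
  pattern <- apply(present, 1, function(r) paste(colnames(present)[r], collapse = "+"))
  partition <- split(names(pattern), pattern)
  uniq <- setNames(lapply(levels(grp), function(g)
    partition[[g]] %||% character(0)), levels(grp))
  list(membership = pattern, partition = partition, unique = uniq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tukey HSD comparison of alpha diversity between groups
#'
#' One-way ANOVA per index followed by Tukey honestly-significant-difference
#' adjusted pairwise comparisons.
#'
#' @param alpha data.frame from [alpha_indices()].
#' @param frame metadata frame.
#' @param group_col grouping column.
#' @param index which index column to test.
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
group_alpha_test <- function(alpha, frame, group_col = "age_group",
                             index = "shannon") {
  if (!index %in% names(alpha)) stop("unknown index: ", index)
  frame <- frame[match(alpha$sample_id, frame$sample_id), , drop = FALSE]
  g <- droplevels(factor(frame[[group_col]]))
  if (nlevels(g) < 2) stop("need at least two groups")
  dat <- data.frame(y = alpha[[index]], g = g)
  fit <- aov(y ~ g, data = dat)
  tk <- TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}
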