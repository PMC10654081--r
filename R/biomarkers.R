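#' Random-forest cross-validated age-biomarker selection
#'
#' Regresses community composition against cellar age with a random forest
#' and selects the taxon subset minimizing repeated k-fold
#' cross-validation error. Within each fold, taxa are ranked by permutation
#' importance from a forest fit on the training samples; for each candidate
#' feature count on a Fibonacci-like grid of ranked prefixes, a forest is
#' refit on the top-n taxa and the held-out mean-squared error recorded.
#' The selected size is the curve's minimum (ties broken toward fewer
#' taxa); the reported taxa are the top-n by importance of a final
#' all-sample forest.
#'
#' @param table relative-abundance `community_table` at OTU level.
#' @param frame metadata frame.
#' @param response `"age_group_ordinal"` (1-4 over Aa-Ad, default) or
#'   `"age_years"`.
#' @param n_trees trees per forest (default 500).
#' @param folds cross-validation folds (default 10).
#' @param repeats fold repetitions (default 5).
#' @param seed integer seed; identical seeds give identical selections.
#' @return list of class `rf_selection` with `cv_error_curve` (data.frame
#'   `n_features`, `cv_mse`), `selected_n`, `selected_taxa`, `importances`.
#' @export
rf_select <- function(table, frame, response = c("age_group_ordinal", "age_years"),
                      n_trees = 500, folds = 10, repeats = 5, seed = 1L) {
  stopifnot(inherits(table, "community_table"))
  response <- match.arg(response)
  frame <- frame[match(sample_ids(table), frame$sample_id), , drop = FALSE]
  y <- if (response == "age_group_ordinal")
    as.numeric(frame$age_group) else frame$age_years
  if (anyNA(y)) stop("missing response values")
  if (length(unique(y)) < 2) stop("response is constant")
  X <- t(table$counts)
  # canonical feature order so results are invariant to the input table's
  # taxon ordering (forest fits consume RNG in column order)
  X <- X[, order(colnames(X)), drop = FALSE]
  n <- nrow(X)
  if (folds > n) stop("more folds than samples")
  # Fibonacci-like prefix grid keeps the search tractable
  grid <- c(1, 2, 3)
  while (tail(grid, 1) < ncol(X))
    grid <- c(grid, tail(grid, 1) + tail(grid, 2)[1])
  grid <- unique(pmin(grid, ncol(X)))
  set.seed(seed)
  err <- matrix(0, folds * repeats, length(grid))
  row <- 0
  for (rep_i in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      row <- row + 1
      tr <- fold_id != f
      # randomForest warns when the ordinal response has < 5 distinct
      # values; regression on the 1-4 age code is intended
      rf_full <- suppressWarnings(
        randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                   ntree = n_trees, importance = TRUE))
      imp <- randomForest::importance(rf_full, type = 1)[, 1]
      ord <- order(imp, decreasing = TRUE)
      for (gi in seq_along(grid)) {
        top <- ord[seq_len(grid[gi])]
        rf <- suppressWarnings(
          randomForest::randomForest(X[tr, top, drop = FALSE], y[tr],
                                     ntree = n_trees))
        pred <- predict(rf, X[!tr, top, drop = FALSE])
        err[row, gi] <- mean((pred - y[!tr])^2)
      }
    }
  }
  curve <- data.frame(n_features = grid, cv_mse = colMeans(err))
  selected_n <- grid[which.min(curve$cv_mse)]   # which.min takes first tie
  rf_final <- suppressWarnings(
    randomForest::randomForest(X, y, ntree = n_trees, importance = TRUE))
  imp_final <- sort(randomForest::importance(rf_final, type = 1)[, 1],
                    decreasing = TRUE)
  structure(list(cv_error_curve = curve, selected_n = selected_n,
                 selected_taxa = names(imp_final)[seq_len(selected_n)],
                 importances = imp_final),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat(sprintf("rf_selection: %d taxa selected (CV MSE %.4f)\n",
              x$selected_n, min(x$cv_error_curve$cv_mse)))
  invisible(x)
}

#' LDA effect-size (LEfSe-style) biomarker discovery
#'
#' Two-stage procedure on relative abundances scaled to parts-per-million:
#' (1) a Kruskal-Wallis test across groups per feature retains features
#' with `p < alpha`; (2) for the survivors, `n_boot` bootstrap rounds each
#' draw two-thirds of every group's samples, fit a one-dimensional linear
#' discriminant on the surviving feature set (pooled within-group
#' covariance shrunk by `lambda` toward the identity), and measure each
#' feature's effect as the average of the between-extreme-group mean
#' difference of its discriminant component and of the raw feature — the
#' raw term keeps large fold-changes visible even when the
#' variance-normalized discriminant loads elsewhere. The LDA score is
#' `log10(1 + mean effect)`; biomarkers satisfy `lda_score > lda_threshold`
#' and the enriched group is the group with the highest mean abundance.
#'
#' @param table relative-abundance `community_table` (any rank).
#' @param frame metadata frame.
#' @param group_col grouping column (>= 2 groups, each >= 3 samples).
#' @param alpha Kruskal-Wallis cutoff (default 0.05).
#' @param lda_threshold log10 effect-size cutoff (default 4).
#' @param n_boot bootstrap rounds (default 30).
#' @param lambda covariance shrinkage (default 1e-6).
#' @param seed integer seed.
#' @return data.frame with per-feature `feature`, `kw_p_value`,
#'   `enriched_group`, `lda_score`, `is_biomarker`.
#' @export
lefse <- function(table, frame, group_col = "age_group", alpha = 0.05,
                  lda_threshold = 4, n_boot = 30, lambda = 1e-6, seed = 1L) {
  stopifnot(inherits(table, "community_table"))
  if (!table$is_relative) table <- to_relative(table)
  frame <- frame[match(sample_ids(table), frame$sample_id), , drop = FALSE]
  g <- droplevels(factor(frame[[group_col]]))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 3)) stop("every group needs >= 3 samples")
  X <- t(table$counts) * 1e6              # per-million scaling
  kw_p <- apply(X, 2, function(v) {
    if (length(unique(v)) == 1) return(1)
    suppressWarnings(kruskal.test(v, g)$p.value)
  })
  feat <- colnames(X)
  surv <- which(kw_p < alpha)
  res <- data.frame(feature = feat, kw_p_value = kw_p,
                    enriched_group = NA_character_, lda_score = NA_real_,
                    is_biomarker = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!length(surv)) return(res)
  Xs <- X[, surv, drop = FALSE]
  set.seed(seed)
  eff_sum <- numeric(length(surv))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      sample(idx, max(3, ceiling(2 * length(idx) / 3)))
    }))
    xb <- Xs[take, , drop = FALSE]
    gb <- g[take]
    w <- .lda_axis(xb, gb, lambda)
    proj <- sweep(xb, 2, w, "*")          # per-feature LDA component
    gm_proj <- apply(proj, 2, function(v) tapply(v, gb, mean))
    gm_raw <- apply(xb, 2, function(v) tapply(v, gb, mean))
    eff_sum <- eff_sum +
      0.5 * (apply(gm_proj, 2, function(v) max(v) - min(v)) +
               apply(gm_raw, 2, function(v) max(v) - min(v)))
  }
  lda_score <- log10(1 + eff_sum / n_boot)
  means <- apply(X[, surv, drop = FALSE], 2,
                 function(v) levels(g)[which.max(tapply(v, g, mean))])
  res$lda_score[surv] <- lda_score
  res$enriched_group[surv] <- means
  res$is_biomarker <- !is.na(res$lda_score) & res$kw_p_value < alpha &
    res$lda_score > lda_threshold
  res
}

# first discriminant axis, unit norm, with ridge shrinkage of the pooled
# within-class scatter (keeps degenerate bootstraps well-posed)
.lda_axis <- function(x, g, lambda) {
  p <- ncol(x)
  mu <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lv in levels(g)) {
    xg <- x[g == lv, , drop = FALSE]
    mg <- colMeans(xg)
    if (nrow(xg) > 1) W <- W + cov(xg) * (nrow(xg) - 1)
    B <- B + nrow(xg) * tcrossprod(mg - mu)
  }
  W <- W / max(1, nrow(x) - nlevels(g))
  scale_w <- mean(diag(W))
  if (!is.finite(scale_w) || scale_w <= 0) scale_w <- 1
  W <- W + lambda * scale_w * diag(p)
  e <- eigen(solve(W, B), symmetric = FALSE)
  w <- Re(e$vectors[, which.max(Re(e$values))])
  w / sqrt(sum(w^2))
}
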