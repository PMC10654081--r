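test_that("alpha indices follow their closed forms", {
  # sample built to have S_obs = 10, F1 = 5, F2 = 2
  v <- c(rep(1, 5), rep(2, 2), 5, 7, 9)
  x <- matrix(v, ncol = 1, dimnames = list(sprintf("t%02d", 1:10), "s1"))
  a <- alpha_indices(community_table(rbind(x, t11 = 0)))
  expect_equal(a$observed_richness, 10)
  expect_equal(a$chao1, 10 + 5 * 4 / (2 * 3))
  # uniform over 8 taxa: maximal evenness
  u <- community_table(matrix(rep(10, 8), 8, 1,
                              dimnames = list(letters[1:8], "s")))
  au <- alpha_indices(u)
  expect_equal(au$shannon, log(8))
  expect_equal(au$pielou, 1)
  # single taxon
  m <- community_table(matrix(9, 1, 1, dimnames = list("a", "s")))
  expect_equal(alpha_indices(m)$shannon, 0)
  # Chao1 reduces to S_obs when no singletons
  nosing <- community_table(matrix(c(5, 3, 2), 3, 1,
                                   dimnames = list(letters[1:3], "s")))
  expect_equal(alpha_indices(nosing)$chao1, 3)
  # pielou identity
  tab <- random_table(40, 6, seed = 6)
  aa <- alpha_indices(tab)
  expect_equal(aa$pielou, aa$shannon / log(aa$observed_richness))
})

test_that("trend regression recovers exact fits and rejects degenerate x", {
  x <- 1:10
  fit <- trend_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(trend_regression(rep(5, 10), rnorm(10)), "variance")
  expect_error(trend_regression(1:2, 1:2), "n >= 3")
  # null calibration: slope test is ~5% size under independence
  set.seed(99)
  rej <- mean(vapply(1:400, function(i)
    trend_regression(rnorm(50), rnorm(50))$p_value < 0.05, logical(1)))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("Bray-Curtis matches the hand formula and its bounds", {
  x <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  bc <- bray_curtis(community_table(x, is_relative = TRUE))
  expect_equal(bc$values["s1", "s2"], 0.5)
  same <- matrix(rep(c(0.3, 0.7), 2), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(community_table(same, is_relative = TRUE))
               $values["s1", "s2"], 0)
  disj <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(community_table(disj, is_relative = TRUE))
               $values["s1", "s2"], 1)
})

test_that("weighted UniFrac reduces to Bray-Curtis on star trees and matches hand enumeration", {
  set.seed(21)
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(star$tip.label, paste0("s", 1:4)))
  rel <- to_relative(community_table(x))
  wu <- weighted_unifrac(rel, star)
  bc <- bray_curtis(rel)
  expect_equal(wu$values, bc$values, tolerance = 1e-9)

  # 4-tip balanced tree, samples on two tips each: enumerate all 6 branches.
  # sample 1 = {A: .5, B: .5}, sample 2 = {C: .5, D: .5}:
  # tip branches contribute 4 * 1 * 0.5; the two depth-1 branches |1-0| = 2.
  # numerator 4, denominator = total branch mass 2 + 4*0.5 = 4, wu = 1? no:
  # denominator sums A_b + B_b over branches: tips 4 * 0.5, internals 2 * 1,
  # so wu = (4*0.5 + 2*1) / (4*0.5 + 2*1) = 1 (fully disjoint clades).
  t4 <- balanced4()
  x2 <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 0.5, 0.5), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  wu2 <- weighted_unifrac(community_table(x2, is_relative = TRUE), t4)
  expect_equal(wu2$values["s1", "s2"], 1)
  # mixed case, hand-enumerated: s1 = {A: .75, B: .25}, s2 = {A: .25, C: .75}
  # branch masses (s1, s2): A (.75, .25), B (.25, 0), C (0, .75), D (0, 0),
  # AB (1, .25), CD (0, .75); all lengths 1.
  # num = .5 + .25 + .75 + 0 + .75 + .75 = 3; den = 1 + .25 + .75 + 1.25 + .75 = 4
  x3 <- matrix(c(0.75, 0.25, 0, 0, 0.25, 0, 0.75, 0), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  wu3 <- weighted_unifrac(community_table(x3, is_relative = TRUE), t4)
  expect_equal(wu3$values["s1", "s2"], 3 / 4)
  # identical samples at distance zero, symmetry and range on random data
  tab <- to_relative(random_table(12, 6, seed = 31))
  tr <- ape::rtree(12, tip.label = taxon_ids(tab))
  w <- weighted_unifrac(tab, tr)$values
  expect_equal(w, t(w))
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_error(weighted_unifrac(tab, ape::drop.tip(tr, "t01")), "absent")
})

test_that("weighted UniFrac agrees with an independent implementation", {
  set.seed(31)
  tab <- to_relative(random_table(12, 6, seed = 31))
  tr <- ape::rtree(12, tip.label = taxon_ids(tab))
  mine <- weighted_unifrac(tab, tr)$values
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(tab$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})

test_that("NMDS embeds metric configurations and is seed-deterministic", {
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(pts))
  pm <- pairwise_matrix(d, "euclidean")
  fit <- nmds(pm, seed = 5)
  expect_lte(fit$stress, 0.01)
  expect_equal(unname(colMeans(fit$coordinates)), c(0, 0), tolerance = 1e-8)
  fit2 <- nmds(pm, seed = 5)
  expect_identical(fit$coordinates, fit2$coordinates)
  # well-separated clusters stay separated in the ordination
  grp <- rep(1:2, each = 5)
  pts2 <- matrix(rnorm(20, sd = 0.1), 10, 2) + 5 * cbind(grp, grp)
  rownames(pts2) <- paste0("s", 1:10)
  f3 <- nmds(pairwise_matrix(as.matrix(dist(pts2)), "euclidean"), seed = 1)
  dd <- as.matrix(dist(f3$coordinates))
  between <- mean(dd[grp == 1, grp == 2])
  within <- mean(dd[grp == 1, grp == 1][upper.tri(diag(5))])
  expect_gt(between, within)
})

test_that("PERMANOVA partitions variance and detects perfect separation", {
  # two groups of identical points, distinct between groups
  x <- cbind(matrix(0, 2, 4), matrix(10, 2, 4))
  colnames(x) <- paste0("s", 1:8); rownames(x) <- c("d1", "d2")
  d <- as.matrix(dist(t(x + matrix(rnorm(16, sd = 1e-3), 2))))
  pm <- pairwise_matrix(d, "euclidean")
  fr <- block_frame(colnames(x), rep(c("Aa", "Ad"), each = 4))
  fr <- sample_frame(fr)
  res <- permanova(pm, fr, terms = "age_group", n_perm = 199, seed = 1)
  expect_gt(res$r2_fraction[res$term == "age_group"], 0.99)
  expect_lte(res$p_value[1], 1 / 100)
  expect_equal(sum(res$r2_fraction[res$term != "Total"]), 1, tolerance = 1e-9)
  expect_error(permanova(pm, transform(fr, age_group = "Aa"),
                         terms = "age_group", n_perm = 199), "single level")
})

test_that("group dissimilarity summarises within-group structure", {
  # identical samples: all distances zero
  n <- 8
  z <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  pm <- pairwise_matrix(z, "bray_curtis")
  fr <- sample_frame(block_frame(paste0("s", 1:n), rep(c("Aa", "Ab"), each = 4)))
  gd <- suppressWarnings(group_dissimilarity(pm, fr))
  expect_true(all(gd$distributions$value == 0))
  # a single-sample group errors with its name
  fr2 <- sample_frame(block_frame(paste0("s", 1:n),
                                  c(rep("Aa", 7), "Ad")))
  expect_error(group_dissimilarity(pm, fr2), "Ad")
  # planted decreasing dispersion is recovered in the medians
  set.seed(12)
  sds <- c(Aa = 2, Ab = 1.2, Ac = 0.6, Ad = 0.2)
  pts <- do.call(rbind, lapply(names(sds), function(g)
    matrix(rnorm(12 * 3, sd = sds[g]), 12, 3)))
  rownames(pts) <- paste0("s", seq_len(nrow(pts)))
  pmx <- pairwise_matrix(as.matrix(dist(pts)), "euclidean")
  frx <- sample_frame(block_frame(rownames(pts), rep(names(sds), each = 12)))
  gdx <- group_dissimilarity(pmx, frx)
  expect_true(all(diff(as.numeric(gdx$medians)) < 0))
  expect_lt(gdx$trend$slope, 0)
})

test_that("taxon overlap partitions groups by presence", {
  tab <- random_table(30, 12, seed = 14)
  tax <- data.frame(taxon_id = taxon_ids(tab), phylum = "P1", class = "C1",
                    order = "O1",
                    family = paste0("F", rep(1:15, 2)),
                    genus = paste0("G", 1:30), stringsAsFactors = FALSE)
  fr <- sample_frame(data.frame(sample_id = sample_ids(tab),
                                age_group = "Aa",
                                longitude_group = rep(c("La", "Lb", "Lc"),
                                                      each = 4)))
  ov <- taxon_overlap(tab, tax, "family", fr)
  total <- length(unique(ov$membership))
  expect_equal(sum(lengths(ov$partition)), length(ov$membership))
  # brute-force set algebra agrees per group
  agg <- aggregate_taxa(tab, tax, "family")
  for (g in c("La", "Lb", "Lc")) {
    sids <- fr$sample_id[fr$longitude_group == g]
    pres_g <- rownames(agg$counts)[rowSums(agg$counts[, sids] > 0) > 0]
    others <- setdiff(fr$sample_id, sids)
    pres_o <- rownames(agg$counts)[rowSums(agg$counts[, others] > 0) > 0]
    expect_setequal(ov$unique[[g]], setdiff(pres_g, pres_o))
  }
  # two identical groups share everything; disjoint groups share nothing
  x <- tab$counts[, rep(1, 4)]
  colnames(x) <- paste0("r", 1:4)
  dup <- community_table(x)
  frd <- sample_frame(data.frame(sample_id = colnames(x), age_group = "Aa",
                                 longitude_group = rep(c("La", "Lb"), 2)))
  ovd <- taxon_overlap(dup, tax, "genus", frd)
  expect_equal(lengths(ovd$unique[c("La", "Lb")]),
               c(La = 0L, Lb = 0L))
})

test_that("Tukey HSD group tests behave like t-tests for two groups", {
  set.seed(33)
  tab <- random_table(40, 12, seed = 33)
  alpha <- alpha_indices(tab)
  fr <- sample_frame(block_frame(alpha$sample_id, rep(c("Aa", "Ab"), each = 6)))
  tk <- group_alpha_test(alpha, fr, index = "shannon")
  tt <- t.test(alpha$shannon[fr$age_group == "Ab"],
               alpha$shannon[fr$age_group == "Aa"], var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  # a strongly shifted group is flagged in all of its comparisons
  alpha4 <- alpha
  fr4 <- sample_frame(block_frame(alpha$sample_id,
                                  rep(c("Aa", "Ab", "Ac", "Ad"), each = 3)))
  alpha4$shannon[fr4$age_group == "Ad"] <-
    alpha4$shannon[fr4$age_group == "Ad"] + 10 * sd(alpha4$shannon)
  tk4 <- group_alpha_test(alpha4, fr4, index = "shannon")
  hit <- grepl("Ad", tk4$comparison)
  expect_true(all(tk4$p_adj[hit] < 0.01))
})
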