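test_that("correlation screen equals brute-force double-loop screening", {
  rel <- to_relative(random_table(20, 15, seed = 41, lambda = 6))
  edges <- correlation_screen(rel, 0.5, 0.05)
  ref <- ref_correlation_screen(rel, 0.5, 0.05)
  key <- function(d) sort(paste(pmin(d$taxon_u, d$taxon_v),
                                pmax(d$taxon_u, d$taxon_v)))
  expect_identical(key(edges), key(ref))
  if (nrow(edges)) {
    m <- match(paste(edges$taxon_u, edges$taxon_v),
               paste(ref$taxon_u, ref$taxon_v))
    expect_equal(edges$rho, ref$rho[m], tolerance = 1e-10)
  }
  # screen is invariant to taxon and sample ordering
  perm_t <- sample(20); perm_s <- sample(15)
  rel2 <- community_table(rel$counts[perm_t, perm_s], is_relative = TRUE)
  expect_identical(key(correlation_screen(rel2, 0.5, 0.05)), key(edges))
})

test_that("threshold edges behave as strict cutoffs", {
  # rho = 1 exactly: retained (p = 0 < alpha, |rho| > 0.7)
  x <- rbind(a = 1:8, b = (1:8) * 2, c = c(2, 1, 4, 3, 6, 5, 8, 7))
  colnames(x) <- paste0("s", 1:8)
  rel <- to_relative(community_table(x))
  e <- correlation_screen(rel, 0.7, 0.01)
  expect_true(any(e$taxon_u == "a" & e$taxon_v == "b"))
  expect_true(all(abs(e$rho) > 0.7 & e$p_value < 0.01))
  expect_true(all(e$sign == ifelse(e$rho > 0, "positive", "negative")))
  # constant taxon is skipped with a warning, not an error (raw counts so
  # the row stays constant; normalization would break ties)
  x2 <- rbind(x, d = rep(3, 8))
  expect_warning(correlation_screen(community_table(x2), 0.7, 0.01),
                 "constant")
})

test_that("topology metrics match closed forms on canonical graphs", {
  # two disjoint triangles: partition into the triangles has Q = 0.5
  ed <- data.frame(taxon_u = c("a", "b", "c", "d", "e", "f"),
                   taxon_v = c("b", "c", "a", "e", "f", "d"),
                   rho = 0.8, p_value = 1e-4, sign = "positive")
  net <- build_network(ed)
  topo <- topology(net, seed = 2)
  expect_equal(topo$modularity, 0.5)
  expect_true(modular_structure_flag(topo$modularity))
  expect_equal(topo$n_connected_components, 2)
  # hand check of Q = sum(e_ii/m - (d_i/2m)^2) for the triangle partition
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(igraph::modularity(net, memb[igraph::V(net)$name]), 0.5)

  # K5: density 1, average degree 4
  k5 <- t(combn(letters[1:5], 2))
  edk <- data.frame(taxon_u = k5[, 1], taxon_v = k5[, 2], rho = 0.9,
                    p_value = 1e-5, sign = "positive")
  tk <- topology(build_network(edk), seed = 1)
  expect_equal(tk$density, 1)
  expect_equal(tk$average_degree, 4)
  expect_equal(tk$average_path_length, 1)

  # 10 positive + 5 negative edges: ratio 50%
  edr <- data.frame(taxon_u = paste0("u", 1:15), taxon_v = paste0("v", 1:15),
                    rho = c(rep(0.8, 10), rep(-0.8, 5)), p_value = 1e-5,
                    sign = c(rep("positive", 10), rep("negative", 5)))
  expect_equal(topology(build_network(edr), seed = 1)$neg_pos_ratio, 50)

  expect_false(modular_structure_flag(0.4))   # strict inequality
  expect_false(modular_structure_flag(0.265))
  expect_true(modular_structure_flag(0.515))
})

test_that("focal-class edge decomposition matches direct enumeration", {
  # star: focal hub with 4 non-focal leaves, all positive
  ed <- data.frame(taxon_u = "hub", taxon_v = paste0("leaf", 1:4),
                   rho = 0.9, p_value = 1e-5, sign = "positive")
  tax <- data.frame(taxon_id = c("hub", paste0("leaf", 1:4)),
                    phylum = "P", class = c("Clostridia", rep("Other", 4)),
                    order = NA, family = NA, genus = NA,
                    stringsAsFactors = FALSE)
  net <- build_network(ed, taxonomy = tax)
  fc <- focal_class_edges(net, "Clostridia")
  expect_equal(fc, list(intra_positive = 0L, intra_negative = 0L,
                        inter_positive = 4L, inter_negative = 0L))
  # all-focal graph has no inter edges
  tax2 <- transform(tax, class = "Clostridia")
  fc2 <- focal_class_edges(build_network(ed, taxonomy = tax2), "Clostridia")
  expect_equal(fc2$inter_positive + fc2$inter_negative, 0)
  expect_error(focal_class_edges(net, "NoSuchClass"), "unknown class")

  # random annotated graph vs brute-force loop over edges
  set.seed(9)
  pairs <- t(combn(paste0("n", 1:12), 2))
  pick <- sample(nrow(pairs), 30)
  edr <- data.frame(taxon_u = pairs[pick, 1], taxon_v = pairs[pick, 2],
                    rho = runif(30, -1, 1), p_value = 1e-5,
                    sign = NA, stringsAsFactors = FALSE)
  edr$sign <- ifelse(edr$rho > 0, "positive", "negative")
  taxr <- data.frame(taxon_id = paste0("n", 1:12), phylum = "P",
                     class = sample(c("Clostridia", "Bacilli"), 12, TRUE),
                     order = NA, family = NA, genus = NA,
                     stringsAsFactors = FALSE)
  netr <- build_network(edr, taxonomy = taxr)
  fcr <- focal_class_edges(netr, "Clostridia")
  isfocal <- setNames(taxr$class == "Clostridia", taxr$taxon_id)
  cnt <- c(ip = 0, inn = 0, ep = 0, en = 0)
  for (r in seq_len(nrow(edr))) {
    fu <- isfocal[edr$taxon_u[r]]; fv <- isfocal[edr$taxon_v[r]]
    if (!fu && !fv) next
    pos <- edr$sign[r] == "positive"
    if (fu && fv) cnt[if (pos) "ip" else "inn"] <-
        cnt[if (pos) "ip" else "inn"] + 1
    else cnt[if (pos) "ep" else "en"] <- cnt[if (pos) "ep" else "en"] + 1
  }
  expect_equal(unlist(fcr, use.names = FALSE), unname(cnt))
})

test_that("robustness matches the complete-graph closed form and ranks the star below it", {
  k20 <- t(combn(paste0("n", 1:20), 2))
  edk <- data.frame(taxon_u = k20[, 1], taxon_v = k20[, 2], rho = 0.8,
                    p_value = 1e-5, sign = "positive")
  net <- build_network(edk)
  rb <- robustness(net, step = 0.05, n_reps = 30, seed = 8)
  expect_equal(rb$mean[1], 1)
  # closed form: no secondary extinctions until <= 1 node survives
  closed <- vapply(rb$removal_fractions, function(q) {
    left <- 20 - round(q * 20)
    if (left <= 1) 0 else left / 20
  }, numeric(1))
  expect_equal(rb$mean, closed, tolerance = 1e-12)
  expect_lt(abs(rb$robustness_score -
                  sum(diff(rb$removal_fractions) *
                        (head(closed, -1) + closed[-1]) / 2)), 1e-12)
  expect_true(all(rb$mean >= 0 & rb$mean <= 1))

  # star: losing the hub collapses everything, curve sits below K20's
  eds <- data.frame(taxon_u = "hub", taxon_v = paste0("l", 1:19), rho = 0.8,
                    p_value = 1e-5, sign = "positive")
  rs <- robustness(build_network(eds), step = 0.05, n_reps = 60, seed = 8)
  interior <- rb$removal_fractions > 0 & rb$removal_fractions < 1
  expect_true(all(rs$mean[interior] <= closed[interior] + 1e-9))
  expect_lt(rs$robustness_score, rb$robustness_score)
  expect_error(robustness(net, step = 0.3), "divide")
})

test_that("vulnerability equals hand-computed efficiency drops", {
  # path a-b-c-d: E = (3*1 + 2*0.5 + 1/3)/6 = 13/18;
  # removing an interior node leaves one edge: E_i = 1/3;
  # vulnerability = (13/18 - 1/3)/(13/18) = 7/13
  ed <- data.frame(taxon_u = c("a", "b", "c"), taxon_v = c("b", "c", "d"),
                   rho = 0.8, p_value = 1e-5, sign = "positive")
  expect_equal(vulnerability(build_network(ed)), 7 / 13, tolerance = 1e-12)
  # complete graph: removal is symmetric and barely hurts
  k4 <- t(combn(letters[1:4], 2))
  edk <- data.frame(taxon_u = k4[, 1], taxon_v = k4[, 2], rho = 0.8,
                    p_value = 1e-5, sign = "positive")
  netk <- build_network(edk)
  eff <- igraph::global_efficiency(netk, weights = NA)
  drops <- vapply(1:4, function(i)
    (eff - igraph::global_efficiency(igraph::delete_vertices(netk, i),
                                     weights = NA)) / eff, numeric(1))
  expect_equal(vulnerability(netk), max(drops))
  expect_lt(diff(range(drops)), 1e-12)
  expect_error(vulnerability(build_network(ed[1, ])), ">= 3 nodes")
})

test_that("natural connectivity increases with added edges", {
  ed <- data.frame(taxon_u = c("a", "b", "c"), taxon_v = c("b", "c", "d"),
                   rho = 0.8, p_value = 1e-5, sign = "positive")
  g1 <- build_network(ed)
  ed2 <- rbind(ed, data.frame(taxon_u = "a", taxon_v = "d", rho = 0.8,
                              p_value = 1e-5, sign = "positive"))
  expect_gt(natural_connectivity(build_network(ed2)),
            natural_connectivity(g1))
})
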