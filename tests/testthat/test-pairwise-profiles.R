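test_that("hamming distance counts differing presence states", {
  p <- c(s1 = 1L, s2 = 0L, s3 = 2L, s4 = 0L)
  expect_identical(hamming_distance(p, p), 0L)
  expect_identical(hamming_distance(p, c(s1 = 0L, s2 = 1L, s3 = 0L, s4 = 3L)),
                   4L)
  expect_error(hamming_distance(p, p[1:3]), "panel")
  fx <- triplet_examples()
  # MTOR absent in 3 species, all of them also lacking RICTOR; RICTOR
  # absent in 18, so the profiles differ in 15 species
  expect_identical(hamming_distance(fx$profiles["MTOR", ],
                                    fx$profiles["RICTOR", ]), 15L)
})

test_that("Dollo reconstruction places forced gains and losses", {
  tr <- tiny_tree()
  root <- 5L  # ape numbering: leaves 1..4, root 5
  ev <- dollo_gain_loss(c(s1 = 1, s2 = 1, s3 = 1, s4 = 1), tr)
  expect_identical(ev[root], 1L)
  expect_identical(sum(ev == -1L), 0L)

  ev <- dollo_gain_loss(c(s1 = 1, s2 = 0, s3 = 0, s4 = 0), tr)
  expect_identical(ev[match("s1", tr$tip.label)], 1L)
  expect_identical(sum(ev != 0L), 1L)

  ev <- dollo_gain_loss(c(s1 = 1, s2 = 0, s3 = 1, s4 = 0), tr)
  expect_identical(ev[root], 1L)
  expect_identical(which(ev == -1L),
                   sort(match(c("s2", "s4"), tr$tip.label)))
  expect_error(dollo_gain_loss(c(s1 = 0, s2 = 0, s3 = 0, s4 = 0), tr),
               "all-absent")
})

test_that("Dollo loss counts are minimal on random small trees", {
  for (s in 1:10) {
    n <- sample(4:6, 1L)
    tr <- simulate_tree(n, seed = 100 + s)
    ti <- cooccur3:::tree_index(tr)
    set.seed(200 + s)
    pres <- stats::runif(n) < 0.5
    if (!any(pres)) pres[1L] <- TRUE
    names(pres) <- tr$tip.label
    ev <- dollo_gain_loss(pres, tr)
    expect_identical(sum(ev == 1L), 1L)
    expect_identical(sum(ev == -1L),
                     as.integer(oracle_min_losses(ti, unname(pres[ti$labels]))))
  }
})

test_that("global trend sums per-OG events", {
  tr <- tiny_tree()
  pm <- make_pm(list(OG1 = rep(1L, 4), OG2 = rep(1L, 4)), panel4)
  g <- global_trend(pm, tr)
  expect_identical(g[5L], 2)
  expect_identical(sum(g != 0), 1L)
  pm1 <- make_pm(list(OG1 = c(1L, 0L, 1L, 0L)), panel4)
  expect_identical(global_trend(pm1, tr),
                   as.numeric(dollo_gain_loss(pm1["OG1", ], tr)))
  # 20 simulated OGs: trend equals the sum of single reconstructions
  sim <- simulate_gene_content(sim_config(n_species = 10, n_ogs = 20,
                                          n_arch = 0, n_indep = 0),
                               seed = 31)
  manual <- Reduce(`+`, lapply(rownames(sim$profiles), function(og)
    dollo_gain_loss(sim$profiles[og, ], sim$tree)))
  expect_identical(global_trend(sim$profiles, sim$tree), as.numeric(manual))
})

test_that("partial correlation follows the corrected-correlation formula", {
  g <- c(1, -1, -1, 1, 0, 1)
  ga <- c(1, -1, 1, -1, 0, 0)
  expect_equal(partial_correlation(ga, ga, g), 1)
  expect_equal(partial_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1),
                                   c(1, -1, -1, 1)), 0)
  # oracle: correlation of residuals after regressing each vector on G
  set.seed(41)
  for (rep in 1:20) {
    ga <- sample(c(-1L, 0L, 1L), 10, replace = TRUE)
    gb <- sample(c(-1L, 0L, 1L), 10, replace = TRUE)
    g <- sample(c(-1L, 0L, 1L), 10, replace = TRUE)
    if (sd(ga) == 0 || sd(gb) == 0) next
    if (sd(g) == 0 || abs(cor(ga, g)) == 1 || abs(cor(gb, g)) == 1) next
    res <- cor(resid(lm(ga ~ g)), resid(lm(gb ~ g)))
    expect_equal(partial_correlation(ga, gb, g), res, tolerance = 1e-12)
  }
  expect_error(partial_correlation(rep(1, 4), c(1, -1, 1, -1), g[1:4]),
               "zero-variance")
})

test_that("partial correlation is symmetric and relabeling-invariant", {
  set.seed(42)
  for (rep in 1:10) {
    ga <- sample(c(-1L, 0L, 1L), 12, replace = TRUE)
    gb <- sample(c(-1L, 0L, 1L), 12, replace = TRUE)
    g <- sample(c(-1L, 0L, 1L), 12, replace = TRUE)
    if (sd(ga) == 0 || sd(gb) == 0) next
    expect_equal(partial_correlation(ga, gb, g),
                 partial_correlation(gb, ga, g))
    perm <- sample(12)
    expect_equal(partial_correlation(ga, gb, g),
                 partial_correlation(ga[perm], gb[perm], g[perm]))
  }
})

test_that("subset score counts asymmetric presence", {
  a <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 1)
  b <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 0)
  expect_identical(as.integer(subset_score(a, b, "A", "B")), 2L)
  expect_identical(as.integer(subset_score(b, a, "B", "A")), 2L)  # A chosen by width
  expect_identical(as.integer(subset_score(a, a, "A", "B")), 0L)
  fx <- triplet_examples()
  sc <- subset_score(fx$profiles["HNRNPK", ], fx$profiles["PDCD4", ],
                     "HNRNPK", "PDCD4")
  expect_identical(as.integer(sc), 16L)
  expect_identical(attr(sc, "n_a_not_b"), 16L)
  expect_identical(attr(sc, "n_b_not_a"), 0L)
  expect_identical(attr(sc, "wide"), "HNRNPK")
})

test_that("subset score of a true subset equals the cardinality difference", {
  set.seed(43)
  for (rep in 1:10) {
    a <- stats::runif(20) < 0.7
    b <- a & stats::runif(20) < 0.6
    expect_identical(as.integer(subset_score(a, b, "a", "b")),
                     as.integer(sum(a) - sum(b)))
  }
})

test_that("taxonomic subset is decided by strict LCA descendance", {
  tr <- tiny_tree()
  all4 <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 1)
  expect_true(taxonomic_subset(all4, c(s1 = 1, s2 = 1, s3 = 0, s4 = 0), tr))
  expect_false(taxonomic_subset(c(s1 = 1, s2 = 0, s3 = 0, s4 = 1),
                                c(s1 = 0, s2 = 1, s3 = 1, s4 = 0), tr))
  # disjoint sets: no overlap, never a taxonomic subset
  expect_false(taxonomic_subset(c(s1 = 1, s2 = 1, s3 = 0, s4 = 0),
                                c(s1 = 0, s2 = 0, s3 = 1, s4 = 1), tr))
  # A = {s1,s2,s3} spans the root, B = {s1,s2} is a cherry below it
  expect_true(taxonomic_subset(c(s1 = 1, s2 = 1, s3 = 1, s4 = 0),
                               c(s1 = 1, s2 = 1, s3 = 0, s4 = 0), tr))
})

test_that("background thresholds use nearest-rank percentiles", {
  th <- background_thresholds(1:100, 1:100, 90)
  expect_identical(th$matching_cutoff, 90L)
  expect_true(91 > th$matching_cutoff)
  expect_false(90 > th$matching_cutoff)
  th <- background_thresholds(rep(0.5, 30), rep(3L, 30), 90)
  expect_false(0.5 > th$matching_cutoff)  # nothing passes an all-equal bg
  expect_error(background_thresholds(1:10, 1:10, 90), "at least 20")
  set.seed(44)
  bg <- stats::rnorm(1000)
  th <- background_thresholds(bg, 1:1000, 95)
  expect_identical(th$matching_cutoff, sort(bg)[ceiling(0.95 * 1000)])
  expect_identical(th$subset_cutoff, 950L)
})

test_that("classification precedence is matching, taxonomic, subset, other", {
  th <- background_thresholds(seq(0, 1, length.out = 100), 1:100, 90)
  expect_identical(classify_pair(0.99, 0, FALSE, th), "matching")
  # taxonomic wins over subset even when the subset score qualifies
  expect_identical(classify_pair(0.1, 99, TRUE, th), "taxonomic")
  expect_identical(classify_pair(0.1, 99, FALSE, th), "subset")
  expect_identical(classify_pair(0.1, 5, FALSE, th), "other")
})

test_that("classify_pairs recovers planted matching pairs and partitions", {
  for (s in 1:3) {
    tree <- simulate_tree(51, seed = 300 + s)
    coh <- plant_pair_cohort(tree, n_per_category = 30, seed = 300 + s)
    rec <- classify_pairs(coh$profiles, tree, coh$network, percentile = 90,
                          seed = s)
    truth_key <- paste(coh$truth$og_a, coh$truth$og_b)
    m <- match(paste(rec$og_a, rec$og_b), truth_key)
    expect_false(anyNA(m))
    is_match <- coh$truth$category[m] == "matching" & rec$eligible
    expect_gte(mean(rec$category[is_match] == "matching"), 0.9)
    # categories partition the eligible pairs exactly
    expect_false(anyNA(rec$category[rec$eligible]))
    expect_true(all(is.na(rec$category[!rec$eligible])))
    expect_identical(sum(table(rec$category)), sum(rec$eligible))
  }
})

test_that("ineligible pairs are excluded, not classified", {
  tr <- tiny_tree()
  # both OGs present in fewer than half (ceiling(4/2) = 2) species
  pm <- make_pm(list(A = c(1L, 0L, 0L, 0L), B = c(0L, 1L, 0L, 0L),
                     C = rep(1L, 4), D = rep(1L, 4), E = c(1L, 1L, 0L, 0L),
                     F = c(1L, 1L, 1L, 0L), G = c(0L, 1L, 1L, 1L),
                     H = c(1L, 0L, 1L, 1L)), panel4)
  net <- make_net("A", "B", "C", "D", "E", "F", "G", "H")
  rec <- classify_pairs(pm, tr, net, percentile = 90)
  ab <- rec[rec$og_a == "A" & rec$og_b == "B", ]
  expect_false(ab$eligible)
  expect_true(is.na(ab$category))
  cd <- rec[rec$og_a == "C" & rec$og_b == "D", ]
  expect_true(cd$eligible)
})
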