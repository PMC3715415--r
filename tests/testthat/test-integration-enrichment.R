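fake_pairs <- function(og_a, og_b, category) {
  data.frame(og_a = og_a, og_b = og_b, hamming = 0L, pcorr = 0,
             subset_score = 0L, eligible = TRUE, category = category,
             stringsAsFactors = FALSE)
}

fake_triplet <- function(a, b, cc, score, type = "open") {
  data.frame(og_a = a, og_b = b, og_c = cc, type = type, tax_subset = FALSE,
             n_good_b = 0L, n_good_c = 0L, n_bad = 0L,
             score = as.integer(score), stringsAsFactors = FALSE)
}

test_that("positive open triangles mark their A-side pairs", {
  tri <- fake_triplet("A", "B", "C", 8L)
  pairs <- fake_pairs(c("A", "A", "B"), c("B", "C", "C"),
                      c("other", "other", "matching"))
  ct <- positive_triplet_pairs(tri, pairs)
  expect_identical(ct$in_triplet[ct$category == "other"], 2L)
  expect_identical(ct$in_triplet[ct$category == "matching"], 0L)
  # score 0 is not positive
  ct0 <- positive_triplet_pairs(fake_triplet("A", "B", "C", 0L), pairs)
  expect_identical(sum(ct0$in_triplet), 0L)
  # closed triangles never qualify
  ctc <- positive_triplet_pairs(fake_triplet("A", "B", "C", 9L, "closed"),
                                pairs)
  expect_identical(sum(ctc$in_triplet), 0L)
})

test_that("crosstab counts equal a brute-force membership scan", {
  set.seed(71)
  ogs <- sprintf("G%02d", 1:30)
  tri <- do.call(rbind, lapply(1:50, function(i) {
    trio <- sample(ogs, 3L)
    fake_triplet(trio[1L], min(trio[2:3]), max(trio[2:3]),
                 sample(-5:10, 1L),
                 sample(c("open", "open2A", "closed"), 1L))
  }))
  e <- t(replicate(60, sample(ogs, 2L)))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  pairs <- fake_pairs(e[, 1L], e[, 2L],
                      sample(c("matching", "taxonomic", "subset", "other"),
                             nrow(e), replace = TRUE))
  ct <- positive_triplet_pairs(tri, pairs)
  for (cc in ct$category) {
    manual <- 0L
    for (i in which(pairs$category == cc)) {
      hit <- FALSE
      k <- paste(sort(c(pairs$og_a[i], pairs$og_b[i])), collapse = "|")
      for (j in seq_len(nrow(tri))) {
        if (tri$type[j] == "closed" || tri$score[j] <= 0L) next
        sides <- c(paste(sort(c(tri$og_a[j], tri$og_b[j])), collapse = "|"),
                   paste(sort(c(tri$og_a[j], tri$og_c[j])), collapse = "|"))
        if (k %in% sides) hit <- TRUE
      }
      manual <- manual + hit
    }
    expect_identical(ct$in_triplet[ct$category == cc], manual)
    expect_lte(ct$in_triplet[ct$category == cc],
               ct$total[ct$category == cc])
  }
})

test_that("raising the positivity threshold never adds pairs", {
  set.seed(72)
  ogs <- sprintf("H%02d", 1:20)
  tri <- do.call(rbind, lapply(1:40, function(i) {
    trio <- sample(ogs, 3L)
    fake_triplet(trio[1L], trio[2L], trio[3L], sample(-3:12, 1L))
  }))
  e <- t(replicate(40, sample(ogs, 2L)))
  pairs <- fake_pairs(e[, 1L], e[, 2L], "other")
  pairs <- pairs[!duplicated(paste(pmin(pairs$og_a, pairs$og_b),
                                   pmax(pairs$og_a, pairs$og_b))), ]
  prev <- Inf
  for (thr in c(0L, 2L, 5L, 8L)) {
    now <- sum(positive_triplet_pairs(tri, pairs, min_score = thr)$in_triplet)
    expect_lte(now, prev)
    prev <- now
  }
})

test_that("over-representation matches the hand chi-square", {
  ct <- data.frame(category = c("other", "matching"),
                   total = c(100L, 100L), in_triplet = c(30L, 10L))
  class(ct) <- c("crosstab", class(ct))
  ov <- overrepresentation(ct, "other")
  expect_equal(ov$observed_fraction, 0.30)
  expect_equal(ov$expected_fraction, 0.20)
  expect_equal(ov$fold_excess_percent, 50)
  # chi-square statistic from the standard formula on the 2x2 table
  tab <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  expect_equal(ov$p, stats::pchisq(stat, 1, lower.tail = FALSE))

  flat <- data.frame(category = c("a", "b"), total = c(50L, 50L),
                     in_triplet = c(10L, 10L))
  ov0 <- overrepresentation(flat, "a")
  expect_equal(ov0$fold_excess_percent, 0)
  expect_gt(ov0$p, 0.9)
})

test_that("planted category enrichment is detected in simulation", {
  set.seed(73)
  n <- 1500L
  category <- sample(c("matching", "taxonomic", "subset", "other"), n,
                     replace = TRUE, prob = c(0.2, 0.2, 0.1, 0.5))
  p_in <- ifelse(category == "other", 0.3, 0.15)
  in_tri <- stats::runif(n) < p_in
  ct <- data.frame(category = c("matching", "taxonomic", "subset", "other"))
  ct$total <- as.integer(table(category)[ct$category])
  ct$in_triplet <- as.integer(tapply(in_tri, category, sum)[ct$category])
  ov <- overrepresentation(ct, "other")
  expect_gt(ov$fold_excess_percent, 0)
  expect_lt(ov$p, 0.01)
})

test_that("enrichment grid normalizes and handles corner cases", {
  set.seed(74)
  n <- 2000L
  pcorr <- stats::runif(n)
  tscore <- sample(-10:10, n, replace = TRUE)
  inter <- stats::runif(n) < 0.2
  g <- enrichment_grid(pcorr, tscore, inter, 5L, 5L)
  cnt <- attr(g, "n_pairs")
  # weighted mean of 2^cell equals 1 (enrichment normalization)
  nz <- !is.na(g)
  expect_equal(sum(2^g[nz] * cnt[nz]) / sum(cnt), 1, tolerance = 1e-12)
  # independent groupby recomputation of one cell
  pb <- cooccur3:::equal_count_bin(pcorr, 5L)
  tb <- cooccur3:::equal_count_bin(tscore, 5L)
  sel <- pb == 3L & tb == 4L
  expect_equal(g[3, 4], log2(mean(inter[sel]) / mean(inter)))
  # uniform interaction probability gives cells near 0
  expect_lt(max(abs(g[nz])), 1)

  # all interacting pairs in one cell
  inter1 <- pb == 1L & tb == 1L
  g1 <- enrichment_grid(pcorr, tscore, inter1, 5L, 5L)
  expect_equal(g1[1, 1], log2(1 / mean(inter1)))
  # pairs in no triplet fall into the sentinel lowest triplet bin
  t2 <- tscore; t2[1:100] <- -Inf
  g2 <- enrichment_grid(pcorr, t2, inter, 5L, 5L)
  expect_true(all(attr(g2, "n_pairs") >= 0))
})

test_that("pair triplet scores take the maximum over containing triplets", {
  tri <- rbind(fake_triplet("A", "B", "C", 3L),
               fake_triplet("A", "B", "D", 7L),
               fake_triplet("E", "B", "A", -2L))
  expect_equal(pair_triplet_score(tri, c("A", "A", "C", "X"),
                                  c("B", "D", "B", "Y")),
               c(7, 7, 3, -Inf))
  # central-only containment ignores the B-C side
  expect_equal(pair_triplet_score(tri, "C", "A", sides = "central"), 3)
  expect_equal(pair_triplet_score(tri, "C", "B", sides = "central"), -Inf)
})
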