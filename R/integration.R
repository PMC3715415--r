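# Feeding triplet results back into the pairwise picture: which classified
# interacting pairs sit inside positive-scoring open triangles, whether any
# category is over-represented among them, and the 2-D enrichment of
# interacting pairs over pair-similarity x triplet-score bins.

#' Cross-tabulate classified pairs against positive-scoring open triangles
#'
#' A pair is "in" when it appears as an A-B or A-C side of at least one
#' open triangle (including `open2A`) with complementarity score strictly
#' greater than zero.
#'
#' @param triplets scored triplet data.frame ([score_triplets]).
#' @param pairs classified `pair_records` ([classify_pairs]).
#' @param min_score positivity threshold: triangles with
#'   `score > min_score` qualify (default 0, i.e. strictly positive).
#' @return data.frame of class `crosstab`: per category the total number of
#'   eligible pairs and the number inside positive open triangles.
#' @export
positive_triplet_pairs <- function(triplets, pairs, min_score = 0L) {
  open <- triplets[triplets$type %in% c("open", "open2A") &
                     triplets$score > min_score, , drop = FALSE]
  in_keys <- unique(c(pair_key(open$og_a, open$og_b),
                      pair_key(open$og_a, open$og_c)))
  elig <- pairs[pairs$eligible, , drop = FALSE]
  keys <- pair_key(elig$og_a, elig$og_b)
  cats <- c("matching", "taxonomic", "subset", "other")
  fac <- factor(elig$category, levels = cats)
  out <- data.frame(category = cats,
                    total = as.integer(table(fac)),
                    in_triplet = as.integer(table(fac[keys %in% in_keys])),
                    stringsAsFactors = FALSE)
  class(out) <- c("crosstab", class(out))
  out
}

pair_key <- function(a, b) {
  if (length(a) == 0L) return(character(0L))
  paste0(pmin(a, b), "|", pmax(a, b))
}

#' Over-representation of a category among positive-triplet pairs
#'
#' Compares the observed fraction of in-triplet pairs within a category to
#' the category-blind expectation (the overall in-triplet fraction), as a
#' percent excess, with a chi-square test on the 2x2 table (in-triplet x
#' in-category).
#'
#' @param ct a `crosstab` from [positive_triplet_pairs].
#' @param category the category to test.
#' @param correct apply Yates continuity correction (default FALSE; the
#'   large-count regime does not need it).
#' @return list `fold_excess_percent`, `p`, `observed_fraction`,
#'   `expected_fraction`.
#' @export
overrepresentation <- function(ct, category, correct = FALSE) {
  row <- ct[ct$category == category, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown category: ", category)
  if (row$total == 0L) stop("empty category: ", category)
  tot_all <- sum(ct$total)
  in_all <- sum(ct$in_triplet)
  obs <- row$in_triplet / row$total
  expd <- in_all / tot_all
  tab <- matrix(c(row$in_triplet, row$total - row$in_triplet,
                  in_all - row$in_triplet,
                  (tot_all - row$total) - (in_all - row$in_triplet)),
                nrow = 2L, byrow = TRUE)
  p <- if (expd == 0 || expd == 1) 1
  else suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  list(fold_excess_percent = (obs / expd - 1) * 100,
       p = p, observed_fraction = obs, expected_fraction = expd)
}

#' Log2 enrichment grid of interacting pairs over pair and triplet scores
#'
#' Bins all background pairs by pairwise similarity (partial correlation)
#' and by their triplet score (the maximum complementarity score over
#' triplets containing the pair; pairs in no scored triplet fall in a
#' sentinel lowest bin). Each cell holds
#' `log2(interacting fraction in cell / overall interacting fraction)`;
#' cells without pairs are `NA`, not 0.
#'
#' @param pcorr numeric pair similarities.
#' @param tscore numeric triplet scores (use `-Inf` for pairs in no
#'   triplet).
#' @param interacting logical, whether each pair interacts / co-occurs in a
#'   complex.
#' @param n_pair_bins,n_triplet_bins grid resolution (equal-count bins per
#'   axis; the `-Inf` sentinel forms its own lowest triplet bin).
#' @return numeric matrix (pair bins x triplet bins) of class
#'   `enrichment_grid`, with attributes `n_pairs` (cell counts) and
#'   `overall_fraction`.
#' @export
enrichment_grid <- function(pcorr, tscore, interacting,
                            n_pair_bins = 10L, n_triplet_bins = 10L) {
  n <- length(pcorr)
  if (length(tscore) != n || length(interacting) != n)
    stop("inputs must have equal length")
  if (n < n_pair_bins * 2L) stop("degenerate binning: too few pairs")
  overall <- mean(interacting)
  pb <- equal_count_bin(pcorr, n_pair_bins)
  has_t <- is.finite(tscore)
  tb <- integer(n)
  if (any(!has_t)) {
    tb[!has_t] <- 1L
    tb[has_t] <- 1L + equal_count_bin(tscore[has_t], n_triplet_bins - 1L)
  } else {
    tb <- equal_count_bin(tscore, n_triplet_bins)
  }
  cnt <- table(factor(pb, levels = seq_len(n_pair_bins)),
               factor(tb, levels = seq_len(n_triplet_bins)))
  hit <- table(factor(pb[interacting], levels = seq_len(n_pair_bins)),
               factor(tb[interacting], levels = seq_len(n_triplet_bins)))
  cnt <- matrix(as.numeric(cnt), n_pair_bins)
  hit <- matrix(as.numeric(hit), n_pair_bins)
  grid <- matrix(NA_real_, n_pair_bins, n_triplet_bins)
  nz <- cnt > 0
  grid[nz] <- log2((hit[nz] / cnt[nz]) / overall)
  dimnames(grid) <- list(pair_bin = seq_len(n_pair_bins),
                         triplet_bin = seq_len(n_triplet_bins))
  structure(grid, n_pairs = cnt, overall_fraction = overall,
            class = c("enrichment_grid", "matrix", "array"))
}

# equal-count bin index (1 = lowest) with stable ordering
equal_count_bin <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(k, n))
  ord <- order(x, method = "radix")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(k), times = sizes)
  bin
}

#' Triplet score per pair (max over containing triplets)
#'
#' @param triplets scored triplet data.frame.
#' @param og_a,og_b pair endpoints.
#' @param sides which triplet sides count as containing the pair:
#'   `"all"` (any two members) or `"central"` (A-B / A-C sides only).
#' @return numeric vector; `-Inf` for pairs in no triplet.
#' @export
pair_triplet_score <- function(triplets, og_a, og_b, sides = c("all", "central")) {
  sides <- match.arg(sides)
  keys <- c(pair_key(triplets$og_a, triplets$og_b),
            pair_key(triplets$og_a, triplets$og_c))
  scores <- c(triplets$score, triplets$score)
  if (sides == "all") {
    keys <- c(keys, pair_key(triplets$og_b, triplets$og_c))
    scores <- c(scores, triplets$score)
  }
  best <- tapply(scores, keys, max)
  out <- best[pair_key(og_a, og_b)]
  out <- as.numeric(out)
  out[is.na(out)] <- -Inf
  out
}
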