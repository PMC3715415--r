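# Equal-count binning of the scored triplet universe (open + closed
# triangles plus a random sample of mutually non-interacting triplets) and
# the rank trend of triangle-type frequency across bins.

#' Sample mutually non-interacting triplets from a network
#'
#' Draws `n` distinct unordered node triples with no internal edge; each
#' node has at least one interaction elsewhere (they are network nodes),
#' matching a triplet universe of interacting proteins that do not interact
#' with each other. Deterministic given the seed. When fewer such triples
#' exist than requested (small graphs) all of them are returned with a
#' warning.
#'
#' @param net an [interaction_network].
#' @param n number of triples to draw.
#' @param seed RNG seed (mandatory).
#' @return data.frame `og_a`, `og_b`, `og_c` (canonically ordered within
#'   each triple; `og_a` here is just the first id, centering is done by the
#'   scorer).
#' @export
sample_noninteracting <- function(net, n, seed) {
  nodes <- net$nodes
  if (length(nodes) < 3L) stop("network needs >= 3 nodes")
  edge_keys <- paste0(net$edges$a, "|", net$edges$b)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n_total <- choose(length(nodes), 3)
  if (n_total <= 5 * n || length(nodes) <= 60L) {
    # enumerate exhaustively for small graphs
    idx <- utils::combn(length(nodes), 3L)
    a <- nodes[idx[1L, ]]; b <- nodes[idx[2L, ]]; cc <- nodes[idx[3L, ]]
    ok <- !(paste0(a, "|", b) %in% edge_keys) &
      !(paste0(a, "|", cc) %in% edge_keys) &
      !(paste0(b, "|", cc) %in% edge_keys)
    a <- a[ok]; b <- b[ok]; cc <- cc[ok]
    if (length(a) == 0L) stop("no non-interacting triples in this network")
    if (length(a) > n) {
      keep <- sample.int(length(a), n)
      a <- a[keep]; b <- b[keep]; cc <- cc[keep]
    } else if (length(a) < n) {
      warning("only ", length(a), " non-interacting triples available")
    }
    return(data.frame(og_a = a, og_b = b, og_c = cc, stringsAsFactors = FALSE))
  }
  got <- character(0L)
  res_a <- res_b <- res_c <- character(0L)
  tries <- 0L
  while (length(res_a) < n && tries < 200L) {
    tries <- tries + 1L
    m <- ceiling((n - length(res_a)) * 1.3)
    i1 <- sample.int(length(nodes), m, replace = TRUE)
    i2 <- sample.int(length(nodes), m, replace = TRUE)
    i3 <- sample.int(length(nodes), m, replace = TRUE)
    ok <- i1 != i2 & i1 != i3 & i2 != i3
    s <- cbind(i1, i2, i3)[ok, , drop = FALSE]
    s <- t(apply(s, 1L, sort))
    a <- nodes[s[, 1L]]; b <- nodes[s[, 2L]]; cc <- nodes[s[, 3L]]
    key <- paste0(a, "|", b, "|", cc)
    new <- !duplicated(key) & !(key %in% got)
    a <- a[new]; b <- b[new]; cc <- cc[new]; key <- key[new]
    free <- !(paste0(a, "|", b) %in% edge_keys) &
      !(paste0(a, "|", cc) %in% edge_keys) &
      !(paste0(b, "|", cc) %in% edge_keys)
    res_a <- c(res_a, a[free]); res_b <- c(res_b, b[free])
    res_c <- c(res_c, cc[free]); got <- c(got, key[free])
  }
  if (length(res_a) < n)
    warning("only ", length(res_a), " non-interacting triples sampled")
  k <- min(n, length(res_a))
  data.frame(og_a = res_a[seq_len(k)], og_b = res_b[seq_len(k)],
             og_c = res_c[seq_len(k)], stringsAsFactors = FALSE)
}

#' Score non-interacting triplets
#'
#' The complementarity score needs a designated central profile; for
#' unconnected triples the most widespread member (ties broken
#' lexicographically) is taken as A, the most favorable centering under the
#' central-protein filter. Triples whose designated A fails that filter are
#' dropped when `central = TRUE`.
#'
#' @param pm [profile_matrix].
#' @param triples data.frame from [sample_noninteracting].
#' @param central apply the central filter.
#' @return triplet data.frame in the [score_triplets] layout, `type =
#'   "none"`.
#' @export
score_noninteracting <- function(pm, triples, central = TRUE) {
  if (nrow(triples) == 0L) return(empty_triplet_df())
  P <- presence(pm)
  npres <- rowSums(P)
  idx <- cbind(match(triples$og_a, rownames(pm)),
               match(triples$og_b, rownames(pm)),
               match(triples$og_c, rownames(pm)))
  if (any(is.na(idx))) stop("triple OG without profile")
  # designate A = most widespread member, ties by lexicographic OG id;
  # the composite key makes every OG's rank unique
  idrank <- match(rownames(pm), sort(rownames(pm)))
  key <- npres * (nrow(pm) + 1) - idrank
  kmat <- matrix(key[idx], ncol = 3L)
  acol <- max.col(kmat, ties.method = "first")
  m <- nrow(idx)
  ia <- idx[cbind(seq_len(m), acol)]
  rest1 <- idx[cbind(seq_len(m), ifelse(acol == 1L, 2L, 1L))]
  rest2 <- idx[cbind(seq_len(m), ifelse(acol == 3L, 2L, 3L))]
  swap <- idrank[rest1] > idrank[rest2]
  ib <- ifelse(swap, rest2, rest1)
  ic <- ifelse(swap, rest1, rest2)
  keep <- if (central) npres[ia] >= ceiling(ncol(P) / 2) else rep(TRUE, length(ia))
  ia <- ia[keep]; ib <- ib[keep]; ic <- ic[keep]
  if (length(ia) == 0L) return(empty_triplet_df())
  sc <- comp_scores_bulk(P, ia, ib, ic)
  ids <- rownames(pm)
  bfirst <- pmin(ids[ib], ids[ic]); csecond <- pmax(ids[ib], ids[ic])
  data.frame(og_a = ids[ia], og_b = bfirst, og_c = csecond,
             type = "none", tax_subset = FALSE, sc,
             stringsAsFactors = FALSE)
}

#' Bin scored triplets into equal-count score bins
#'
#' Records are sorted by score with a stable tie-break on the canonical
#' triplet id, then split into `n_bins` contiguous bins whose sizes differ
#' by at most one; bin 1 holds the lowest scores. Open triangles where B or
#' C is a taxonomic subset of A are counted as the separate display type
#' `open_taxsubset`.
#'
#' @param records triplet data.frame ([score_triplets] /
#'   [score_noninteracting] rows combined).
#' @param n_bins number of bins (default 20).
#' @return data.frame of class `bin_summary`: per bin the score range,
#'   size, counts and fractions per type; the per-record bin assignment is
#'   attached as attribute `"assignment"`.
#' @export
bin_triplets <- function(records, n_bins = 20L) {
  if (nrow(records) < n_bins)
    stop("fewer records (", nrow(records), ") than bins (", n_bins, ")")
  key <- paste0(records$og_a, "|", records$og_b, "|", records$og_c)
  ord <- order(records$score, key, method = "radix")
  n <- nrow(records)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  dtype <- display_type(records)
  types <- c("open", "open2A", "open_taxsubset", "closed", "none")
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(dtype, levels = types))
  counts <- matrix(as.integer(tab), nrow = n_bins,
                   dimnames = list(NULL, types))
  out <- data.frame(bin = seq_len(n_bins),
                    score_min = tapply(records$score, bin, min),
                    score_max = tapply(records$score, bin, max),
                    n = as.integer(sizes))
  out <- cbind(out, counts)
  frac <- counts / out$n
  colnames(frac) <- paste0("frac_", types)
  out <- cbind(out, frac)
  rownames(out) <- NULL
  class(out) <- c("bin_summary", class(out))
  attr(out, "assignment") <- bin
  out
}

# display type: open triangles with a taxonomic-subset partner get their
# own class; open2A keeps precedence over the taxonomic flag
display_type <- function(records) {
  dt <- records$type
  dt[dt == "open" & records$tax_subset] <- "open_taxsubset"
  dt
}

#' Rank trend of a triangle-type fraction across score bins
#'
#' Spearman rank correlation between bin index (1 = lowest score) and the
#' fraction of the given type per bin, with two-sided p value. A constant
#' fraction makes the correlation undefined; that is reported explicitly
#' rather than as an arbitrary number.
#'
#' @param bins a `bin_summary` from [bin_triplets].
#' @param type one of `"open"`, `"open2A"`, `"open_taxsubset"`, `"closed"`,
#'   `"none"` (`"open"` may be combined, see `combine_open`).
#' @param combine_open when TRUE and `type = "open"`, pool plain open,
#'   `open2A` and `open_taxsubset` fractions.
#' @return list `rho`, `p`, `constant`.
#' @export
fraction_trend <- function(bins, type = "open", combine_open = FALSE) {
  if (nrow(bins) < 5L) stop("need >= 5 bins for a trend")
  frac <- if (combine_open && type == "open")
    bins$frac_open + bins$frac_open2A + bins$frac_open_taxsubset
  else bins[[paste0("frac_", type)]]
  if (is.null(frac)) stop("unknown type: ", type)
  if (stats::sd(frac) == 0)
    return(list(rho = NA_real_, p = NA_real_, constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(bins$bin, frac, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}
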