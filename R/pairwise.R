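# Pair-level profile similarity. The similarity measure of record is the
# partial correlation of reconstructed gain/loss events on the branches of
# the species tree, corrected for the global (all-OG) trend of events per
# branch; raw Hamming distance is kept for reference. Pairs are classified
# matching / taxonomic / subset / other against empirical background
# percentiles.

#' Hamming distance between two phyletic profiles
#' @param p,q copy-number (or logical presence) vectors over the same panel.
#' @return integer: number of species whose presence state differs.
#' @export
hamming_distance <- function(p, q) {
  if (length(p) != length(q)) stop("panel mismatch between profiles")
  if (!is.null(names(p)) && !is.null(names(q)) &&
      !identical(names(p), names(q))) {
    if (!setequal(names(p), names(q))) stop("panel mismatch between profiles")
    q <- q[names(p)]
  }
  sum((p > 0) != (q > 0))
}

#' Dollo gain/loss reconstruction of one profile on the species tree
#'
#' Under Dollo parsimony a gene family is gained exactly once — on the
#' branch above the last common ancestor of all species carrying it — and
#' subsequently only lost. One loss (-1) is placed on every maximal branch
#' whose subtree contains no present species but which descends from the
#' gain; this loss count is the minimum achievable with a single gain.
#' Branches are indexed by the node below them (see [tree_index]); the
#' root's branch is its virtual stem.
#'
#' @param p copy-number or logical presence vector, names = species panel
#'   (must match the tree's leaves).
#' @param tree rooted [ape::phylo] species tree.
#' @return integer vector over branches: +1 gain, -1 loss, 0 otherwise.
#' @export
dollo_gain_loss <- function(p, tree) {
  ti <- tree_index(tree)
  pres <- align_presence(p, ti)
  if (!any(pres)) stop("all-absent profile cannot be reconstructed")
  drop(dollo_events(matrix(pres, nrow = 1L,
                           dimnames = list("og", ti$labels)), ti))
}

# map a named presence/count vector onto tree leaf order
align_presence <- function(p, ti) {
  if (is.null(names(p))) {
    if (length(p) != ti$ntip) stop("profile length does not match tree leaves")
    return(p > 0)
  }
  if (!setequal(names(p), ti$labels)) stop("profile species do not match tree leaves")
  unname(p[ti$labels] > 0)
}

# Vectorized Dollo reconstruction: P is a logical presence matrix
# (OG x species, columns ordered like ti$labels). Returns an integer
# branch x OG event matrix.
dollo_events <- function(P, ti) {
  n_og <- nrow(P)
  m <- ti$nbranch
  if (any(rowSums(P) == 0L)) stop("all-absent profile cannot be reconstructed")
  # present-leaf counts per subtree (node x OG)
  cnt <- matrix(0L, nrow = m, ncol = n_og)
  cnt[seq_len(ti$ntip), ] <- t(P) + 0L
  for (v in ti$postorder) {
    ch <- ti$children[[v]]
    if (length(ch) > 0L)
      cnt[v, ] <- colSums(cnt[ch, , drop = FALSE])
  }
  total <- cnt[ti$root, ]
  # gain node = deepest node whose subtree holds all present leaves
  gain <- integer(n_og)
  best_depth <- rep(-1L, n_og)
  for (v in seq_len(m)) {
    full <- cnt[v, ] == total
    take <- full & ti$depth[v] > best_depth
    gain[take] <- v
    best_depth[take] <- ti$depth[v]
  }
  # in-subtree indicator below each OG's gain node
  insub <- matrix(FALSE, nrow = m, ncol = n_og)
  for (v in ti$preorder) {
    par <- ti$parent[v]
    insub[v, ] <- (gain == v) | (if (par > 0L) insub[par, ] else FALSE)
  }
  ev <- matrix(0L, nrow = m, ncol = n_og,
               dimnames = list(NULL, rownames(P)))
  ev[cbind(gain, seq_len(n_og))] <- 1L
  for (v in seq_len(m)) {
    par <- ti$parent[v]
    if (par == 0L) next
    loss <- insub[v, ] & gain != v & cnt[v, ] == 0L & cnt[par, ] > 0L
    ev[v, loss] <- -1L
  }
  ev
}

#' Gain/loss event matrix for all OGs of a profile matrix
#' @param pm a [profile_matrix].
#' @param tree rooted species tree whose leaves are the panel.
#' @return integer matrix, branches x OGs, entries in `{-1, 0, +1}`.
#' @export
gain_loss_matrix <- function(pm, tree) {
  ti <- tree_index(tree)
  if (!setequal(colnames(pm), ti$labels))
    stop("profile species do not match tree leaves")
  P <- presence(pm)[, ti$labels, drop = FALSE]
  dollo_events(P, ti)
}

#' Global per-branch trend of gains and losses
#'
#' The per-branch sum of all OGs' gain/loss events; this captures
#' genome-wide episodes (streamlining, bursts of invention) that would
#' otherwise induce spurious pairwise correlation.
#'
#' @param pm a [profile_matrix] (>= 2 OGs) or an event matrix from
#'   [gain_loss_matrix].
#' @param tree species tree (required when `pm` is a profile matrix).
#' @return numeric vector over branches.
#' @export
global_trend <- function(pm, tree = NULL) {
  ev <- if (inherits(pm, "profile_matrix")) {
    if (is.null(tree)) stop("tree required to reconstruct events")
    gain_loss_matrix(pm, tree)
  } else pm
  rowSums(ev)
}

#' Partial correlation of two gain/loss vectors given the global trend
#'
#' `r_AB.G = (r_AB - r_AG * r_BG) / sqrt((1 - r_AG^2) (1 - r_BG^2))` with
#' Pearson correlations over branches. If either denominator factor is zero
#' (an event vector perfectly collinear with the trend) the plain `r_AB` is
#' returned with attribute `degenerate = TRUE`; a constant trend likewise
#' degrades to plain correlation.
#'
#' @param ga,gb gain/loss vectors over the same branch index.
#' @param g global trend vector.
#' @return numeric in `[-1, 1]`.
#' @export
partial_correlation <- function(ga, gb, g) {
  if (length(ga) != length(gb) || length(ga) != length(g))
    stop("vectors must share the branch index")
  if (stats::sd(ga) == 0 || stats::sd(gb) == 0)
    stop("zero-variance event vector")
  r_ab <- stats::cor(ga, gb)
  if (stats::sd(g) == 0)
    return(structure(r_ab, degenerate = TRUE))
  r_ag <- stats::cor(ga, g)
  r_bg <- stats::cor(gb, g)
  den <- (1 - r_ag^2) * (1 - r_bg^2)
  if (den <= .Machine$double.eps)
    return(structure(r_ab, degenerate = TRUE))
  max(-1, min(1, (r_ab - r_ag * r_bg) / sqrt(den)))
}

# Partial correlations for selected column pairs of an event matrix,
# sharing one pass over the (centred, scaled) columns.
pcorr_pairs <- function(ev, g, ia, ib) {
  Z <- scale(ev)                      # columns with sd 0 would be NaN
  sds <- attr(Z, "scaled:scale")
  if (any(sds == 0)) stop("zero-variance event vector")
  n <- nrow(ev)
  if (stats::sd(g) == 0) {
    r_ab <- colSums(Z[, ia, drop = FALSE] * Z[, ib, drop = FALSE]) / (n - 1)
    return(pmin(1, pmax(-1, r_ab)))
  }
  zg <- as.vector(scale(g))
  rg <- as.vector(crossprod(Z, zg)) / (n - 1)
  r_ab <- colSums(Z[, ia, drop = FALSE] * Z[, ib, drop = FALSE]) / (n - 1)
  den <- (1 - rg[ia]^2) * (1 - rg[ib]^2)
  out <- ifelse(den <= .Machine$double.eps, r_ab,
                (r_ab - rg[ia] * rg[ib]) / sqrt(pmax(den, .Machine$double.eps)))
  pmin(1, pmax(-1, out))
}

#' Subset score of two profiles
#'
#' With A the more widespread profile (ties broken lexicographically by OG
#' id), the score counts species where A is present without B (supporting a
#' subset relation) minus species where B is present without A (violating
#' it).
#'
#' @param p,q presence or copy-number vectors over the same panel.
#' @param id_p,id_q OG ids used only for the tie-break.
#' @return integer score with attributes `n_a_not_b`, `n_b_not_a`, `wide`
#'   (id of the profile taken as A).
#' @export
subset_score <- function(p, q, id_p = "p", id_q = "q") {
  if (length(p) != length(q)) stop("panel mismatch between profiles")
  pp <- p > 0; qq <- q > 0
  p_wider <- sum(pp) > sum(qq) || (sum(pp) == sum(qq) && id_p <= id_q)
  if (!p_wider) {
    tmp <- pp; pp <- qq; qq <- tmp
    wide <- id_q
  } else wide <- id_p
  a_not_b <- sum(pp & !qq)
  b_not_a <- sum(qq & !pp)
  structure(a_not_b - b_not_a,
            n_a_not_b = a_not_b, n_b_not_a = b_not_a, wide = wide)
}

#' Is one profile a taxonomic subset of the other?
#'
#' Operationalization of "overlapping species sets, one spanning a wider
#' taxonomic range": TRUE iff the two present-species sets overlap and the
#' LCA node of one is a strict descendant of the LCA node of the other.
#'
#' @param p,q presence or count vectors named by species.
#' @param tree rooted species tree.
#' @return logical.
#' @export
taxonomic_subset <- function(p, q, tree) {
  ti <- tree_index(tree)
  pp <- align_presence(p, ti); qq <- align_presence(q, ti)
  if (!any(pp & qq)) return(FALSE)
  lp <- lca_node(ti, which(pp))
  lq <- lca_node(ti, which(qq))
  is_strict_descendant(ti, lp, lq) || is_strict_descendant(ti, lq, lp)
}

#' Empirical background cutoffs for pair classification
#'
#' Nearest-rank percentiles of the background distributions of partial
#' correlations and subset scores; classification requires strictly
#' exceeding a cutoff.
#'
#' @param bg_pcorr numeric background partial correlations (>= 20 values).
#' @param bg_subset integer background subset scores (>= 20 values).
#' @param percentile background percentile (default 90; 85 and 95
#'   used for sensitivity).
#' @return list of class `pair_thresholds` with `matching_cutoff`,
#'   `subset_cutoff`, `percentile`.
#' @export
background_thresholds <- function(bg_pcorr, bg_subset, percentile = 90) {
  stopifnot(percentile > 0, percentile < 100)
  if (length(bg_pcorr) < 20L || length(bg_subset) < 20L)
    stop("need at least 20 background values")
  nearest_rank <- function(x, pct) {
    x <- sort(x)
    x[ceiling(pct / 100 * length(x))]
  }
  structure(list(matching_cutoff = nearest_rank(bg_pcorr, percentile),
                 subset_cutoff = nearest_rank(bg_subset, percentile),
                 percentile = percentile),
            class = "pair_thresholds")
}

#' Classify one eligible profile pair
#'
#' Precedence: matching (partial correlation above the background cutoff),
#' then taxonomic subset (tested before the generic subset even when the
#' subset score would qualify), then subset, else other.
#'
#' @param pcorr partial correlation of the pair.
#' @param subset subset score of the pair.
#' @param is_tax logical from [taxonomic_subset].
#' @param th a [background_thresholds] object.
#' @return one of `"matching"`, `"taxonomic"`, `"subset"`, `"other"`.
#' @export
classify_pair <- function(pcorr, subset, is_tax, th) {
  if (pcorr > th$matching_cutoff) return("matching")
  if (isTRUE(is_tax)) return("taxonomic")
  if (subset > th$subset_cutoff) return("subset")
  "other"
}

#' Classify all interacting pairs of a network against profile backgrounds
#'
#' Runs the full pairwise stage: Dollo reconstruction of every OG, global
#' trend, partial correlations and subset scores for (a) the background set
#' — all pairs among OGs with at least one interaction, optionally
#' subsampled — and (b) the network's edges; then the 4-way classification
#' of eligible edges. A pair is eligible when at least one member is
#' present in at least half of the species (`ceiling(N / 2)`); ineligible
#' pairs are reported with `eligible = FALSE` and no category.
#'
#' @param pm [profile_matrix] covering all network OGs.
#' @param tree rooted species tree.
#' @param net OG-level [interaction_network] (nodes must be rows of `pm`).
#' @param percentile background percentile for both cutoffs.
#' @param max_background optional cap on the number of background pairs
#'   (seeded subsample when exceeded); default uses all.
#' @param seed RNG seed for the optional subsample.
#' @return data.frame (class `pair_records`) with columns `og_a`, `og_b`,
#'   `hamming`, `pcorr`, `subset_score`, `eligible`, `category`; the
#'   thresholds and background values are attached as attributes.
#' @export
classify_pairs <- function(pm, tree, net, percentile = 90,
                           max_background = Inf, seed = 1L) {
  if (net$level != "og") stop("network must be OG-level (see project_to_ogs)")
  missing_ogs <- setdiff(net$nodes, rownames(pm))
  if (length(missing_ogs) > 0L)
    stop("network OGs without profiles: ",
         paste(utils::head(missing_ogs, 5L), collapse = ", "))
  ti <- tree_index(tree)
  P <- presence(pm)[, ti$labels, drop = FALSE]
  ev <- dollo_events(P, ti)
  g <- rowSums(ev)
  nodes <- intersect(rownames(pm), net$nodes)   # OGs with >= 1 interaction
  n_nodes <- length(nodes)
  if (n_nodes < 3L) stop("too few interacting OGs")

  # background pairs: all pairs among interacting OGs
  idx <- utils::combn(n_nodes, 2L)
  if (ncol(idx) > max_background) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    idx <- idx[, sample.int(ncol(idx), max_background), drop = FALSE]
  }
  bg_a <- nodes[idx[1L, ]]; bg_b <- nodes[idx[2L, ]]
  col_of <- match(nodes, rownames(pm))
  bg_pcorr <- pcorr_pairs(ev, g, col_of[idx[1L, ]], col_of[idx[2L, ]])
  bg_subset <- subset_scores_bulk(P, bg_a, bg_b)
  th <- background_thresholds(bg_pcorr, bg_subset, percentile)

  # network edges
  ea <- net$edges$a; eb <- net$edges$b
  ia <- match(ea, rownames(pm)); ib <- match(eb, rownames(pm))
  pc <- pcorr_pairs(ev, g, ia, ib)
  ss <- subset_scores_bulk(P, ea, eb)
  hm <- rowSums(P[ia, , drop = FALSE] != P[ib, , drop = FALSE])
  npres <- rowSums(P)
  elig <- npres[ia] >= ceiling(ncol(P) / 2) | npres[ib] >= ceiling(ncol(P) / 2)

  # taxonomic-subset calls need per-OG presence LCAs
  lca <- vapply(seq_len(nrow(P)), function(i) lca_node(ti, which(P[i, ])),
                integer(1L))
  anc <- ancestor_matrix(ti)
  is_tax <- mapply(function(i, j) {
    if (!any(P[i, ] & P[j, ])) return(FALSE)
    li <- lca[i]; lj <- lca[j]
    li != lj && (anc[lj, li] || anc[li, lj])
  }, ia, ib)

  category <- rep(NA_character_, length(ea))
  for (k in which(elig))
    category[k] <- classify_pair(pc[k], ss[k], is_tax[k], th)
  out <- data.frame(og_a = ea, og_b = eb, hamming = as.integer(hm),
                    pcorr = pc, subset_score = as.integer(ss),
                    eligible = elig, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_records", class(out))
  attr(out, "thresholds") <- th
  attr(out, "background") <- list(pcorr = bg_pcorr, subset = bg_subset,
                                  og_a = bg_a, og_b = bg_b)
  out
}

# subset scores for many pairs at once (ids used for the widespread
# tie-break); P is a logical OG x species matrix
subset_scores_bulk <- function(P, ids_a, ids_b) {
  ia <- match(ids_a, rownames(P)); ib <- match(ids_b, rownames(P))
  A <- P[ia, , drop = FALSE]; B <- P[ib, , drop = FALSE]
  na <- rowSums(A); nb <- rowSums(B)
  a_not_b <- rowSums(A & !B); b_not_a <- rowSums(B & !A)
  a_wider <- na > nb | (na == nb & ids_a <= ids_b)
  as.integer(ifelse(a_wider, a_not_b - b_not_a, b_not_a - a_not_b))
}

# ancestor matrix: anc[u, v] TRUE iff u is a strict descendant of v
ancestor_matrix <- function(ti) {
  m <- ti$nbranch
  anc <- matrix(FALSE, m, m)
  for (v in ti$preorder) {
    par <- ti$parent[v]
    if (par > 0L) {
      anc[v, ] <- anc[par, ]
      anc[v, par] <- TRUE
    }
  }
  anc
}

# seed helpers: run a block under a local RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Category fractions of classified pairs (pie-chart view)
#' @param records a `pair_records` data.frame from [classify_pairs].
#' @return named numeric vector over the four categories, summing to 1.
#' @export
category_fractions <- function(records) {
  cats <- c("matching", "taxonomic", "subset", "other")
  tab <- table(factor(records$category[records$eligible], levels = cats))
  as.vector(tab / sum(tab)) |> stats::setNames(cats)
}
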