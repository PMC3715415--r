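# The complementarity score on profile triplets. For a central protein A
# interacting with B and with C, the expected signature of a shared complex
# subunit is: wherever A is present, exactly one of B or C may be missing
# (the complex it belongs to was lost there), but not both; and neither B
# nor C should occur where A is absent. Species supporting the pattern with
# only B (or only C) next to A are "good"; species violating it are "bad".

#' Complementarity score of a profile triplet
#'
#' `n_good_b` counts species with A and B but not C, `n_good_c` species with
#' A and C but not B; `n_bad` counts species (once each) where A is present
#' with neither B nor C, or where A is absent but B or C present.
#' `score = min(n_good_b, n_good_c) - n_bad`. The score is symmetric in B
#' and C.
#'
#' @param pa,pb,pc copy-number or presence vectors over the same panel
#'   (A is the central profile).
#' @return list with `n_good_b`, `n_good_c`, `n_bad`, `score` (integers).
#' @export
complementarity_score <- function(pa, pb, pc) {
  if (length(pa) != length(pb) || length(pa) != length(pc))
    stop("panel mismatch between profiles")
  a <- pa > 0; b <- pb > 0; cc <- pc > 0
  n_good_b <- sum(a & b & !cc)
  n_good_c <- sum(a & !b & cc)
  n_bad <- sum((a & !b & !cc) | (!a & (b | cc)))
  list(n_good_b = n_good_b, n_good_c = n_good_c, n_bad = n_bad,
       score = min(n_good_b, n_good_c) - n_bad)
}

# vectorized scorer over index triples into a logical presence matrix
comp_scores_bulk <- function(P, ia, ib, ic) {
  A <- P[ia, , drop = FALSE]
  B <- P[ib, , drop = FALSE]
  C <- P[ic, , drop = FALSE]
  g_b <- rowSums(A & B & !C)
  g_c <- rowSums(A & !B & C)
  bad <- rowSums((A & !B & !C) | (!A & (B | C)))
  data.frame(n_good_b = as.integer(g_b), n_good_c = as.integer(g_c),
             n_bad = as.integer(bad),
             score = as.integer(pmin(g_b, g_c) - bad))
}

#' Central-protein filter
#'
#' The triplet analysis targets global trends, so the central protein A must
#' be present in at least half of all species (`ceiling(N / 2)`, i.e. 26 of
#' 51).
#'
#' @param pa copy-number or presence vector of the central profile.
#' @param n panel size (defaults to `length(pa)`).
#' @return logical.
#' @export
central_filter <- function(pa, n = length(pa)) {
  sum(pa > 0) >= ceiling(n / 2)
}

#' Triangle type of an OG triplet in an interaction network
#'
#' With A central: `closed` if all three OG edges exist; `open` if A-B and
#' A-C exist but B-C does not; `open2A` is the open case where the A-B and
#' A-C edges are realized exclusively by two disjoint sets of member
#' proteins of OG A (two in-paralogs taking the two roles); `none`
#' otherwise.
#'
#' @param og_a,og_b,og_c OG identifiers (A central).
#' @param net OG-level [interaction_network]; provenance is needed for the
#'   `open2A` call (without it, open triangles are never typed `open2A`).
#' @return one of `"open"`, `"open2A"`, `"closed"`, `"none"`.
#' @export
triangle_type <- function(og_a, og_b, og_c, net) {
  if (net$level != "og") stop("network must be OG-level")
  if (!all(c(og_a, og_b, og_c) %in% net$nodes))
    stop("OG not in network")
  key <- function(x, y) paste0(pmin(x, y), "|", pmax(x, y))
  edges <- paste0(net$edges$a, "|", net$edges$b)
  ab <- key(og_a, og_b) %in% edges
  ac <- key(og_a, og_c) %in% edges
  bc <- key(og_b, og_c) %in% edges
  if (ab && ac && bc) return("closed")
  if (ab && ac) {
    if (!is.null(net$provenance)) {
      pab <- net$provenance[[key(og_a, og_b)]]
      pac <- net$provenance[[key(og_a, og_c)]]
      # proteins of OG A realizing each edge
      a_ab <- a_proteins(pab, og_a, net)
      a_ac <- a_proteins(pac, og_a, net)
      if (length(a_ab) > 0L && length(a_ac) > 0L &&
          length(intersect(a_ab, a_ac)) == 0L)
        return("open2A")
    }
    return("open")
  }
  "none"
}

# proteins belonging to og among a provenance record's endpoints
a_proteins <- function(prov, og, net) {
  if (is.null(prov)) return(character(0L))
  om <- attr(net, "og_map")
  v <- unique(c(prov$protein_a, prov$protein_b))
  if (is.null(om)) return(v)   # cannot resolve; caller treats as shared
  v[om[v] == og & !is.na(om[v])]
}

#' Enumerate all centered triangles of an OG-level network
#'
#' A centered triplet is (A; B, C) with A adjacent to both B and C. Open
#' triangles are reported once (only the hub can be the center); closed
#' triangles appear three times, once per choice of center, matching a
#' score that depends on which protein is taken as A.
#'
#' @param net OG-level [interaction_network].
#' @return data.frame `og_a`, `og_b`, `og_c` (B, C in canonical order),
#'   `type` in `{open, open2A, closed}`.
#' @export
enumerate_triangles <- function(net) {
  if (net$level != "og") stop("network must be OG-level")
  edges <- net$edges
  if (nrow(edges) == 0L)
    return(data.frame(og_a = character(), og_b = character(),
                      og_c = character(), type = character(),
                      stringsAsFactors = FALSE))
  nbr <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  edge_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in paste0(edges$a, "|", edges$b)) assign(k, TRUE, envir = edge_set)
  has_edge <- function(x, y)
    exists(paste0(pmin(x, y), "|", pmax(x, y)), envir = edge_set)
  out <- vector("list", length(nbr))
  j <- 0L
  for (a in names(nbr)) {
    nb <- sort(nbr[[a]])
    if (length(nb) < 2L) next
    idx <- utils::combn(length(nb), 2L)
    b <- nb[idx[1L, ]]; cc <- nb[idx[2L, ]]
    closed <- mapply(has_edge, b, cc)
    j <- j + 1L
    out[[j]] <- data.frame(og_a = a, og_b = b, og_c = cc,
                           type = ifelse(closed, "closed", "open"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(j)])
  if (is.null(res))
    return(data.frame(og_a = character(), og_b = character(),
                      og_c = character(), type = character(),
                      stringsAsFactors = FALSE))
  # refine open -> open2A using provenance, when available
  if (!is.null(net$provenance)) {
    open_idx <- which(res$type == "open")
    if (length(open_idx) > 0L) {
      key <- function(x, y) paste0(pmin(x, y), "|", pmax(x, y))
      is2a <- vapply(open_idx, function(k) {
        pab <- net$provenance[[key(res$og_a[k], res$og_b[k])]]
        pac <- net$provenance[[key(res$og_a[k], res$og_c[k])]]
        a_ab <- a_proteins(pab, res$og_a[k], net)
        a_ac <- a_proteins(pac, res$og_a[k], net)
        length(a_ab) > 0L && length(a_ac) > 0L &&
          length(intersect(a_ab, a_ac)) == 0L
      }, logical(1L))
      res$type[open_idx[is2a]] <- "open2A"
    }
  }
  res
}

#' Score all centered triangles of a network
#'
#' Applies the central-protein filter to A, drops triplets with two
#' identical OGs, scores each remaining triplet, and (when a tree is given)
#' flags open triangles where B or C is a taxonomic subset of A — those are
#' reported as display type `open_taxsubset` by the binning stage, since a
#' later invention of B or C mimics the complementarity signature without a
#' shared-subunit cause.
#'
#' @param pm [profile_matrix] covering the network's OGs.
#' @param net OG-level [interaction_network].
#' @param tree optional rooted species tree (enables the taxonomic flag).
#' @param central apply the central filter (default TRUE).
#' @return data.frame `og_a`, `og_b`, `og_c`, `type`, `tax_subset`,
#'   `n_good_b`, `n_good_c`, `n_bad`, `score`.
#' @export
score_triplets <- function(pm, net, tree = NULL, central = TRUE) {
  tri <- enumerate_triangles(net)
  missing_ogs <- setdiff(unique(c(tri$og_a, tri$og_b, tri$og_c)), rownames(pm))
  if (length(missing_ogs) > 0L)
    stop("triangle OGs without profiles: ",
         paste(utils::head(missing_ogs, 5L), collapse = ", "))
  P <- presence(pm)
  if (nrow(tri) > 0L && central) {
    npres <- rowSums(P)
    tri <- tri[npres[match(tri$og_a, rownames(pm))] >= ceiling(ncol(P) / 2), ,
               drop = FALSE]
  }
  tri <- tri[tri$og_a != tri$og_b & tri$og_a != tri$og_c &
               tri$og_b != tri$og_c, , drop = FALSE]
  if (nrow(tri) == 0L)
    return(empty_triplet_df())
  sc <- comp_scores_bulk(P, match(tri$og_a, rownames(pm)),
                         match(tri$og_b, rownames(pm)),
                         match(tri$og_c, rownames(pm)))
  tri$tax_subset <- FALSE
  if (!is.null(tree)) {
    ti <- tree_index(tree)
    Pt <- P[, ti$labels, drop = FALSE]
    lca <- vapply(seq_len(nrow(Pt)), function(i) lca_node(ti, which(Pt[i, ])),
                  integer(1L))
    anc <- ancestor_matrix(ti)
    ia <- match(tri$og_a, rownames(pm))
    ib <- match(tri$og_b, rownames(pm))
    ic <- match(tri$og_c, rownames(pm))
    tax_of <- function(i, j)   # j taxonomic subset of central i
      any(Pt[i, ] & Pt[j, ]) && lca[i] != lca[j] && anc[lca[j], lca[i]]
    tri$tax_subset <- mapply(function(i, j, k)
      tax_of(i, j) || tax_of(i, k), ia, ib, ic)
  }
  out <- cbind(tri[, c("og_a", "og_b", "og_c", "type", "tax_subset")], sc)
  rownames(out) <- NULL
  out
}

empty_triplet_df <- function() {
  data.frame(og_a = character(), og_b = character(), og_c = character(),
             type = character(), tax_subset = logical(),
             n_good_b = integer(), n_good_c = integer(),
             n_bad = integer(), score = integer(),
             stringsAsFactors = FALSE)
}
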