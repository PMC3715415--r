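# Duplication-retention analysis: are shared subunits (role A of open
# triangles) kept in duplicate more often than their partner proteins?

#' Duplication status of one orthologous group
#'
#' An OG enters the analysis (is *eligible*) when at least 5 species carry
#' exactly one copy — a guard against clusters contaminated with
#' out-paralogs or annotation artifacts — and counts as *duplicated* when
#' at least 5 species carry in-paralogs (copy number >= 2).
#'
#' @param counts per-species copy-number vector.
#' @return list `n_species_multi`, `n_species_single`, `eligible`,
#'   `duplicated`.
#' @export
dup_status <- function(counts) {
  multi <- sum(counts >= 2L)
  single <- sum(counts == 1L)
  eligible <- single >= 5L
  list(n_species_multi = multi, n_species_single = single,
       eligible = eligible,
       duplicated = if (eligible) multi >= 5L else NA)
}

# vectorized over a profile matrix
dup_status_table <- function(pm) {
  m <- unclass(pm)
  multi <- rowSums(m >= 2L)
  single <- rowSums(m == 1L)
  data.frame(og_id = rownames(pm), n_species_multi = multi,
             n_species_single = single, eligible = single >= 5L,
             duplicated = ifelse(single >= 5L, multi >= 5L, NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Duplication rates per triplet category and role
#'
#' For open triangles (and `open2A`) the central OG (role A) is contrasted
#' with the two partners (roles B/C); for closed triangles and unconnected
#' triplets there is no central gene, so all three members are pooled into
#' one rate (reported in both columns). Only eligible OGs (see
#' [dup_status]) enter the denominators. The default counting is per
#' role-occurrence — an OG occurring in many triangles counts each time,
#' so `n_triplets` matches the number of triangles; `mode = "unique"`
#' counts each OG-role combination once.
#'
#' @param triplets scored triplet data.frame ([score_triplets] rows, plus
#'   optionally `type == "none"` rows for the background).
#' @param pm [profile_matrix] with copy numbers for all member OGs.
#' @param mode `"occurrence"` (default, matches triangle counts) or
#'   `"unique"`.
#' @return data.frame of class `dup_category_stats` with per-category
#'   `n_triplets`, eligible role counts, `pct_dup_A`, `pct_dup_BC`;
#'   attribute `"chisq"` holds the A-vs-B/C chi-square contrast over open
#'   triangles (open + open2A pooled).
#' @export
dup_rates_by_category <- function(triplets, pm,
                                  mode = c("occurrence", "unique")) {
  mode <- match.arg(mode)
  missing_ogs <- setdiff(unique(c(triplets$og_a, triplets$og_b,
                                  triplets$og_c)), rownames(pm))
  if (length(missing_ogs) > 0L)
    stop("triplet OGs without profiles: ",
         paste(utils::head(missing_ogs, 5L), collapse = ", "))
  ds <- dup_status_table(pm)
  elig <- stats::setNames(ds$eligible, ds$og_id)
  dup <- stats::setNames(ds$duplicated, ds$og_id)
  cat_of <- function(type) switch(type, open = "open", open2A = "open2A",
                                  closed = "closed", none = "other", type)
  cats <- c("open", "open2A", "closed", "other")
  tri_cat <- vapply(triplets$type, cat_of, character(1L))
  res <- lapply(cats, function(cc) {
    sel <- tri_cat == cc
    if (!any(sel))
      return(data.frame(category = cc, n_triplets = 0L, n_A = 0L,
                        n_BC = 0L, pct_dup_A = NA_real_,
                        pct_dup_BC = NA_real_, stringsAsFactors = FALSE))
    tt <- triplets[sel, , drop = FALSE]
    central <- cc %in% c("open", "open2A")
    if (central) {
      a_ogs <- tt$og_a
      bc_ogs <- c(tt$og_b, tt$og_c)
      bc_role <- rep(c("B", "C"), each = nrow(tt))
      if (mode == "unique") {
        a_ogs <- unique(a_ogs)
        keep <- !duplicated(paste0(bc_ogs, "|", bc_role))
        bc_ogs <- bc_ogs[keep]
      }
      a_ok <- elig[a_ogs]; bc_ok <- elig[bc_ogs]
      a_dup <- dup[a_ogs][a_ok]; bc_dup <- dup[bc_ogs][bc_ok]
      data.frame(category = cc, n_triplets = nrow(tt),
                 n_A = sum(a_ok), n_BC = sum(bc_ok),
                 pct_dup_A = 100 * mean(a_dup),
                 pct_dup_BC = 100 * mean(bc_dup),
                 stringsAsFactors = FALSE)
    } else {
      all_ogs <- c(tt$og_a, tt$og_b, tt$og_c)
      if (mode == "unique") all_ogs <- unique(all_ogs)
      ok <- elig[all_ogs]
      pooled <- 100 * mean(dup[all_ogs][ok])
      data.frame(category = cc, n_triplets = nrow(tt),
                 n_A = sum(ok), n_BC = sum(ok),
                 pct_dup_A = pooled, pct_dup_BC = pooled,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("dup_category_stats", class(out))
  # chi-square contrast: role A vs roles B/C over open (+ open2A) triangles
  sel <- tri_cat %in% c("open", "open2A")
  if (any(sel)) {
    tt <- triplets[sel, , drop = FALSE]
    a_ogs <- tt$og_a; bc_ogs <- c(tt$og_b, tt$og_c)
    if (mode == "unique") { a_ogs <- unique(a_ogs); bc_ogs <- unique(bc_ogs) }
    a_dup <- dup[a_ogs][elig[a_ogs]]
    bc_dup <- dup[bc_ogs][elig[bc_ogs]]
    if (length(a_dup) > 0L && length(bc_dup) > 0L &&
        !all(c(a_dup, bc_dup)) && any(c(a_dup, bc_dup))) {
      tab <- rbind(A = c(sum(a_dup), sum(!a_dup)),
                   BC = c(sum(bc_dup), sum(!bc_dup)))
      attr(out, "chisq") <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE))
    } else {
      attr(out, "chisq") <- list(p.value = 1, note = "no variation")
    }
  }
  out
}
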