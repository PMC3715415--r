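# End-to-end orchestration: ingest or simulate -> classify pairs -> score
# triplets -> bin -> integrate -> duplication, with a machine-readable
# report.

#' Run the full co-occurrence analysis
#'
#' @param profiles a [profile_matrix].
#' @param tree rooted species tree matching the profile panel.
#' @param complexes optional [complex_set] (covered complexes are removed,
#'   then expanded to pairs).
#' @param pairs optional protein- or OG-level [interaction_network]; merged
#'   with the complex-derived pairs when both are given.
#' @param og_map named character vector `protein -> og`; required when the
#'   interaction data is protein-level.
#' @param percentile background percentile for the pair classification.
#' @param n_bins number of complementarity-score bins.
#' @param n_none number of non-interacting triplets to sample.
#' @param seed RNG seed for all stochastic steps.
#' @param outdir optional directory; when given, stage TSVs and the JSON
#'   report are written there.
#' @return list of class `cooccur_report` with elements `pairs`,
#'   `pie_fractions`, `thresholds`, `triplets`, `bins`, `trend`,
#'   `crosstab`, `overrepresentation`, `grid`, `duplication`, `log`.
#' @export
run_cooccur <- function(profiles, tree, complexes = NULL, pairs = NULL,
                        og_map = NULL, percentile = 90, n_bins = 20L,
                        n_none = 1e5, seed = 1L, outdir = NULL) {
  if (is.null(complexes) && is.null(pairs))
    stop("need complexes and/or pairs")
  log <- list(seed = seed, percentile = percentile, n_bins = n_bins,
              n_none = n_none)
  nets <- list()
  cs <- NULL
  if (!is.null(complexes)) {
    cs <- remove_covered_complexes(complexes)
    log$removed_complexes <- attr(cs, "removed")
    nets$complex <- complexes_to_pairs(cs)
  }
  if (!is.null(pairs)) nets$pairs <- pairs
  levels <- vapply(nets, `[[`, character(1L), "level")
  if (length(unique(levels)) > 1L)
    stop("cannot merge protein- and OG-level interaction inputs")
  net <- if (length(nets) == 1L) nets[[1L]] else {
    interaction_network(rbind(nets[[1L]]$edges, nets[[2L]]$edges),
                        nodes = union(nets[[1L]]$nodes, nets[[2L]]$nodes),
                        level = levels[[1L]])
  }
  if (net$level == "protein") {
    if (is.null(og_map)) stop("protein-level interactions need og_map")
    net <- project_to_ogs(net, og_map)
    log$n_intra_og_edges <- net$n_intra
  }
  net <- interaction_network(net$edges,
                             nodes = intersect(net$nodes, rownames(profiles)),
                             level = "og", provenance = net$provenance,
                             n_intra = net$n_intra) |>
    (\(x) { attr(x, "og_map") <- attr(net, "og_map") %||% og_map; x })()

  n_nodes <- length(intersect(net$nodes, rownames(profiles)))
  prec <- NULL
  if (choose(n_nodes, 2) >= 20) {
    prec <- classify_pairs(profiles, tree, net, percentile = percentile,
                           seed = seed)
    log$thresholds <- attr(prec, "thresholds")
    log$n_eligible_pairs <- sum(prec$eligible)
    log$n_ineligible_pairs <- sum(!prec$eligible)
  } else {
    warning("too few interacting OGs for a background distribution; ",
            "pair classification skipped")
    log$pair_classification <- "skipped (background < 20 pairs)"
  }

  tri <- score_triplets(profiles, net, tree = tree)
  none <- sample_noninteracting(net, n_none, seed = seed)
  tri_none <- score_noninteracting(profiles, none)
  log$n_triangles <- nrow(tri)
  log$n_none <- nrow(tri_none)
  universe <- rbind(tri, tri_none)
  bins <- bin_triplets(universe, n_bins = n_bins)
  trend <- fraction_trend(bins, "open")

  ct <- NULL; over <- NULL; grid <- NULL
  if (!is.null(prec)) {
    ct <- positive_triplet_pairs(universe, prec)
    over <- lapply(stats::setNames(ct$category, ct$category), function(cc)
      if (ct$total[ct$category == cc] > 0L && sum(ct$in_triplet) > 0L)
        overrepresentation(ct, cc) else NULL)
    bg <- attr(prec, "background")
    bg_keys_int <- pair_key(prec$og_a, prec$og_b)
    interacting <- pair_key(bg$og_a, bg$og_b) %in% bg_keys_int
    tsc <- pair_triplet_score(universe, bg$og_a, bg$og_b)
    grid <- enrichment_grid(bg$pcorr, tsc, interacting)
  }

  dup <- dup_rates_by_category(universe, profiles)

  report <- list(pairs = prec,
                 pie_fractions = if (!is.null(prec))
                   category_fractions(prec),
                 thresholds = log$thresholds, triplets = universe,
                 bins = bins, trend = trend, crosstab = ct,
                 overrepresentation = over, grid = grid, duplication = dup,
                 log = log)
  class(report) <- "cooccur_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$pairs))
    utils::write.table(report$pairs, file.path(outdir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$triplets, file.path(outdir, "triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$bins),
                     file.path(outdir, "bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$duplication, file.path(outdir, "dup_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    pie_fractions = as.list(report$pie_fractions),
    thresholds = report$thresholds[c("matching_cutoff", "subset_cutoff",
                                     "percentile")],
    trend = report$trend,
    crosstab = report$crosstab,
    overrepresentation = lapply(report$overrepresentation, function(x)
      if (is.null(x)) NULL else x[c("fold_excess_percent", "p")]),
    log = report$log[setdiff(names(report$log), "thresholds")])
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.cooccur_report <- function(x, ...) {
  cat("co-occurrence analysis report\n")
  if (!is.null(x$pairs)) {
    cat(sprintf("  pairs: %d (%d eligible)\n", nrow(x$pairs),
                sum(x$pairs$eligible)))
    cat("  pie fractions:",
        paste(sprintf("%s %.1f%%", names(x$pie_fractions),
                      100 * x$pie_fractions), collapse = ", "), "\n")
  }
  cat(sprintf("  triplets: %d (open %d, open2A %d, closed %d, none %d)\n",
              nrow(x$triplets), sum(x$triplets$type == "open"),
              sum(x$triplets$type == "open2A"),
              sum(x$triplets$type == "closed"),
              sum(x$triplets$type == "none")))
  cat(sprintf("  open-fraction trend over %d bins: rho = %.3f (p = %.2g)\n",
              nrow(x$bins), x$trend$rho, x$trend$p))
  invisible(x)
}

#' The two worked triplet examples as packaged data
#'
#' Loads the presence/absence profiles of the six proteins of the two
#' published example triplets — the TOR complex triplet (MTOR central, with
#' RPTOR and RICTOR) and the emerin-related triplet (HNRNPK central, with
#' PDCD4 and CDC37) — over the 51-species eukaryote panel, together with
#' the triplet specifications. Species are keyed by synthetic 4-letter
#' codes; the code-to-species-name map ships alongside the profiles.
#'
#' @return list `profiles` ([profile_matrix] of 6 OGs x 51 species),
#'   `triplets` (data.frame `og_a`, `og_b`, `og_c`), `species` (data.frame
#'   `code`, `species`).
#' @export
triplet_examples <- function() {
  path <- system.file("extdata", "triplet_examples_profiles.tsv",
                      package = "cooccur3", mustWork = TRUE)
  spath <- system.file("extdata", "triplet_examples_species.tsv",
                       package = "cooccur3", mustWork = TRUE)
  species <- utils::read.table(spath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "#")
  pm <- read_profile_matrix(path, panel = species$code)
  triplets <- data.frame(og_a = c("MTOR", "HNRNPK"),
                         og_b = c("RPTOR", "PDCD4"),
                         og_c = c("RICTOR", "CDC37"),
                         stringsAsFactors = FALSE)
  list(profiles = pm, triplets = triplets, species = species)
}
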