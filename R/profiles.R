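# Phyletic profiles are held as an integer matrix of per-species copy
# numbers: one row per orthologous group (OG), one column per species of the
# panel. Presence is derived as count > 0; the copy numbers themselves only
# matter for the duplication-retention analysis.

#' Construct a profile matrix
#'
#' @param counts integer matrix (OG x species) of non-negative copy numbers;
#'   rownames are OG identifiers, colnames the species panel.
#' @param panel optional species panel; when given, columns are checked (and
#'   reordered) against it.
#' @return an integer matrix of class `profile_matrix`.
#' @export
profile_matrix <- function(counts, panel = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("profile matrix needs OG row names")
  if (is.null(colnames(counts))) stop("profile matrix needs species column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OG ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("duplicate species in panel")
  if (!is.null(panel)) {
    if (!setequal(colnames(counts), panel))
      stop("profile columns do not match the species panel")
    counts <- counts[, panel, drop = FALSE]
  }
  if (ncol(counts) < 4L) stop("species panel must have >= 4 species")
  if (any(is.na(counts))) stop("missing values in profile counts")
  if (any(counts < 0)) stop("negative copy numbers in profile matrix")
  if (any(counts != round(counts))) stop("non-integer copy numbers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("profile_matrix", class(counts))
  counts
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d orthologous groups x %d species\n",
              nrow(x), ncol(x)))
  cat(sprintf("  presence range per OG: %d..%d species\n",
              min(rowSums(x > 0)), max(rowSums(x > 0))))
  invisible(x)
}

#' Presence/absence view of a profile matrix
#' @param pm a `profile_matrix` (or any count matrix).
#' @return logical matrix, `TRUE` where the copy number is positive.
#' @export
presence <- function(pm) {
  unclass(pm) > 0L
}

#' Read a profile matrix from a TSV file
#'
#' Expected format: a header line `og_id<TAB>sp1<TAB>sp2...`, then one row
#' per OG with integer copy numbers. Lines starting with `#` are ignored.
#'
#' @param path TSV file path.
#' @param panel optional species panel the columns must match.
#' @return a [profile_matrix].
#' @export
read_profile_matrix <- function(path, panel = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (ncol(df) < 2L) stop("profile TSV needs an og_id column plus species columns")
  ogs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric profile counts in ", path)
  rownames(m) <- ogs
  profile_matrix(m, panel = panel)
}

#' Write a profile matrix to TSV
#' @param pm a [profile_matrix].
#' @param path output path.
#' @export
write_profile_matrix <- function(pm, path) {
  df <- data.frame(og_id = rownames(pm), unclass(pm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a profile matrix from an ortholog-cluster membership table
#'
#' Cluster definitions list species-tagged protein identifiers per cluster
#' (by convention a 4-letter uppercase species code followed by a gene
#' number, e.g. `HSAP00123`). The per-species copy number of a cluster is
#' the number of its member proteins carrying that species' code.
#'
#' @param clusters two-column data.frame (`cluster_id`, `protein_id`) or a
#'   path to such a TSV (no header required; `#` comments ignored).
#' @param panel character vector of species codes.
#' @param code_regex regex extracting the species code from a protein id
#'   (first capture group or whole match); default: leading 4 uppercase
#'   letters.
#' @return a [profile_matrix] over `panel`.
#' @export
profiles_from_clusters <- function(clusters, panel,
                                   code_regex = "^[A-Z]{4}") {
  if (is.character(clusters) && length(clusters) == 1L) {
    clusters <- utils::read.table(clusters, header = FALSE, sep = "\t",
                                  comment.char = "#",
                                  stringsAsFactors = FALSE, quote = "")
  }
  if (ncol(clusters) < 2L) stop("cluster table needs cluster_id and protein_id columns")
  cl <- as.character(clusters[[1L]])
  prot <- as.character(clusters[[2L]])
  if (any(!nzchar(prot))) stop("empty protein id in cluster table")
  hit <- regexpr(code_regex, prot)
  if (any(hit < 0L))
    stop("protein id without recognizable species code: ",
         paste(utils::head(prot[hit < 0L], 5L), collapse = ", "))
  code <- regmatches(prot, hit)
  bad <- !code %in% panel
  if (any(bad))
    stop("species code not in panel: ",
         paste(unique(code[bad]), collapse = ", "))
  cl_ids <- sort(unique(cl))
  counts <- table(factor(cl, levels = cl_ids), factor(code, levels = panel))
  m <- matrix(as.integer(counts), nrow = length(cl_ids),
              dimnames = list(cl_ids, panel))
  if (any(rowSums(m) == 0L)) stop("empty cluster in table")
  profile_matrix(m)
}

#' Extract the species code from species-tagged protein ids
#' @param protein_id character vector of protein ids.
#' @param code_regex regex for the species-code prefix.
#' @return character vector of species codes.
#' @export
species_code <- function(protein_id, code_regex = "^[A-Z]{4}") {
  hit <- regexpr(code_regex, protein_id)
  if (any(hit < 0L))
    stop("protein id without recognizable species code: ",
         paste(utils::head(protein_id[hit < 0L], 5L), collapse = ", "))
  regmatches(protein_id, hit)
}
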