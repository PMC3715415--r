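# Complex sets and interaction networks. A complex set is a named list of
# protein-id vectors; a network is a canonical undirected simple edge list
# plus its (possibly larger) node set. OG-level networks carry, per edge,
# the protein pairs that realized it ("provenance"), which the triangle
# typing needs to call open triangles realized by two in-paralogs of the
# central OG.

#' Construct a complex set
#' @param complexes named list, `complex_id -> character vector of members`.
#' @return a validated list of class `complex_set`.
#' @export
complex_set <- function(complexes) {
  if (length(complexes) == 0L) stop("empty complex set")
  if (is.null(names(complexes)) || any(!nzchar(names(complexes))))
    stop("complexes must be named")
  if (anyDuplicated(names(complexes))) stop("duplicate complex ids")
  for (id in names(complexes)) {
    mem <- complexes[[id]]
    if (length(mem) < 2L)
      stop("complex with fewer than 2 members: ", id)
    if (anyDuplicated(mem))
      stop("duplicate member within complex ", id)
  }
  structure(complexes, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("complex_set: %d complexes, %d distinct proteins\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read complex definitions from TSV (`complex_id TAB member TAB member...`)
#' @param path TSV path; `#` comment lines ignored.
#' @return a [complex_set].
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no complexes in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  members <- lapply(parts, function(p) p[-1L])
  names(members) <- ids
  complex_set(members)
}

#' Write complex definitions to TSV
#' @param cs a [complex_set].
#' @param path output path.
#' @export
write_complexes <- function(cs, path) {
  lines <- vapply(names(cs), function(id)
    paste(c(id, cs[[id]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

# canonical edge orientation: a < b lexicographically
canonical_edges <- function(a, b) {
  if (length(a) == 0L)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste0(a, "\r", b))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b, method = "radix")   # deterministic edge order
  data.frame(a = a[ord], b = b[ord], stringsAsFactors = FALSE)
}

# length-safe key: paste0 recycles zero-length inputs against literals
edge_key <- function(a, b) {
  if (length(a) == 0L) return(character(0L))
  paste0(a, "|", b)
}

#' Construct an interaction network
#' @param edges data.frame with columns `a`, `b` (unordered pairs; made
#'   canonical and unique; self-pairs are an error).
#' @param nodes node set (defaults to the nodes appearing in edges).
#' @param level `"protein"` or `"og"`.
#' @param provenance optional list, one entry per edge (keyed `a|b`), each a
#'   data.frame of realizing protein pairs (OG-level networks only).
#' @param n_intra count of intra-OG protein edges dropped during projection.
#' @return a list of class `interaction_network`.
#' @export
interaction_network <- function(edges, nodes = NULL,
                                level = c("protein", "og"),
                                provenance = NULL, n_intra = 0L) {
  level <- match.arg(level)
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  if (any(edges$a == edges$b))
    stop("self-interaction: ",
         paste(utils::head(edges$a[edges$a == edges$b], 5L), collapse = ", "))
  edges <- canonical_edges(edges$a, edges$b)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  else nodes <- sort(unique(as.character(nodes)))
  if (!all(c(edges$a, edges$b) %in% nodes)) stop("edge endpoint not in node set")
  structure(list(edges = edges, nodes = nodes, level = level,
                 provenance = provenance, n_intra = as.integer(n_intra)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network (%s level): %d nodes, %d edges\n",
              x$level, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a pair list (two-column TSV) into a network
#' @param path TSV path with two columns (interactor a, interactor b).
#' @param level node level of the input ids.
#' @return an [interaction_network].
#' @export
read_pairs <- function(path, level = "protein") {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("pair TSV needs two columns")
  interaction_network(data.frame(a = df[[1L]], b = df[[2L]],
                                 stringsAsFactors = FALSE), level = level)
}

#' Write a network's edge list to TSV
#' @param net an [interaction_network].
#' @param path output path.
#' @export
write_pairs <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove complexes completely covered by other complexes
#'
#' A complex is retained iff at least one of its members appears in no other
#' complex of the original set. Coverage is evaluated in a single pass
#' against the original set, not iteratively, so the result does not depend
#' on processing order. Removed ids are recorded in the `"removed"`
#' attribute.
#'
#' @param cs a [complex_set].
#' @return the filtered [complex_set] (may be empty-able to an error if all
#'   complexes are covered).
#' @export
remove_covered_complexes <- function(cs) {
  membership <- table(unlist(lapply(unname(cs), unique)))
  has_unique <- vapply(cs, function(mem) any(membership[mem] == 1L),
                       logical(1L))
  removed <- names(cs)[!has_unique]
  out <- if (any(has_unique)) complex_set(cs[has_unique])
  else structure(stats::setNames(list(), character(0L)),
                 class = "complex_set")   # mutual coverage empties the set
  attr(out, "removed") <- removed
  out
}

#' Expand complexes to the co-complex pair network
#'
#' Every unordered pair of proteins sharing at least one complex becomes one
#' edge; internal complex structure is flattened.
#'
#' @param cs a [complex_set] (typically after [remove_covered_complexes]).
#' @return a protein-level [interaction_network].
#' @export
complexes_to_pairs <- function(cs) {
  pair_list <- lapply(unname(cs), function(mem) {
    mem <- sort(mem)
    if (length(mem) < 2L) return(NULL)
    idx <- utils::combn(length(mem), 2L)
    data.frame(a = mem[idx[1L, ]], b = mem[idx[2L, ]],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, pair_list)
  interaction_network(edges, level = "protein")
}

#' Project a protein-level network to the OG level
#'
#' Edges between proteins of the same OG (in-paralog pairs) are dropped but
#' counted; every OG edge keeps the list of protein pairs that realized it.
#'
#' @param net a protein-level [interaction_network].
#' @param og_map named character vector `protein_id -> og_id`, covering all
#'   network nodes (an unmapped node is an error, not a silent drop).
#' @return an OG-level [interaction_network] with provenance.
#' @export
project_to_ogs <- function(net, og_map) {
  if (net$level != "protein") stop("network is not protein-level")
  unmapped <- setdiff(net$nodes, names(og_map))
  if (length(unmapped) > 0L)
    stop("unmapped proteins: ", paste(utils::head(unmapped, 5L), collapse = ", "),
         if (length(unmapped) > 5L) " ...")
  oa <- unname(og_map[net$edges$a])
  ob <- unname(og_map[net$edges$b])
  intra <- oa == ob
  n_intra <- sum(intra)
  pa <- net$edges$a[!intra]; pb <- net$edges$b[!intra]
  oa <- oa[!intra]; ob <- ob[!intra]
  swap <- oa > ob
  tmp <- oa[swap]; oa[swap] <- ob[swap]; ob[swap] <- tmp
  tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  key <- edge_key(oa, ob)
  prov <- split(data.frame(protein_a = pa, protein_b = pb,
                           stringsAsFactors = FALSE), key)
  uniq <- !duplicated(key)
  out <- interaction_network(data.frame(a = oa[uniq], b = ob[uniq],
                                        stringsAsFactors = FALSE),
                             nodes = sort(unique(unname(og_map[net$nodes]))),
                             level = "og", provenance = prov,
                             n_intra = n_intra)
  attr(out, "og_map") <- og_map
  out
}

#' Basic statistics of an interaction network
#'
#' Average degree is `2 * n_pairs / n_proteins`; components are standard
#' undirected connected components (isolated nodes count as size-1
#' components); average component size is `n_proteins / n_components`.
#'
#' @param net an [interaction_network].
#' @param cs optional [complex_set] the network was derived from (adds
#'   `n_complexes`).
#' @return a list of class `network_stats`.
#' @export
network_stats <- function(net, cs = NULL) {
  if (length(net$nodes) == 0L) stop("empty network")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  comp <- igraph::components(g)
  structure(list(
    n_complexes = if (is.null(cs)) NA_integer_ else length(cs),
    n_proteins = length(net$nodes),
    n_pairs = nrow(net$edges),
    average_degree = 2 * nrow(net$edges) / length(net$nodes),
    n_components = as.integer(comp$no),
    average_component_size = length(net$nodes) / comp$no
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("network statistics\n")
  for (f in names(x))
    cat(sprintf("  %-24s %s\n", f,
                format(x[[f]], digits = 4)))
  invisible(x)
}
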