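# Shared fixture builders; everything is generated in code.

tiny_tree <- function() read_newick_text("((s1,s2),(s3,s4));")

# profile matrix from a named list of count vectors over a panel
make_pm <- function(rows, panel) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), panel)
  profile_matrix(m)
}

panel4 <- paste0("s", 1:4)

# an OG-level network from an edge list given as a two-column matrix
make_net <- function(..., nodes = NULL, level = "og") {
  e <- matrix(c(...), ncol = 2L, byrow = TRUE)
  interaction_network(data.frame(a = e[, 1L], b = e[, 2L],
                                 stringsAsFactors = FALSE),
                      nodes = nodes, level = level)
}

# independent per-species truth-table scorer used as the oracle for the
# complementarity score (explicit case analysis, scalar accumulation)
oracle_comp_score <- function(pa, pb, pc) {
  gb <- 0L; gc <- 0L; bad <- 0L
  for (s in seq_along(pa)) {
    a <- pa[s] > 0; b <- pb[s] > 0; cc <- pc[s] > 0
    if (a) {
      if (b && !cc) gb <- gb + 1L
      else if (!b && cc) gc <- gc + 1L
      else if (!b && !cc) bad <- bad + 1L
      # a && b && cc: neutral
    } else {
      if (b || cc) bad <- bad + 1L
    }
  }
  c(gb, gc, bad, min(gb, gc) - bad)
}

# exhaustive minimum loss count for a single-gain reconstruction
oracle_min_losses <- function(ti, pres) {
  leaves_below <- lapply(seq_len(ti$nbranch),
                         function(v) cooccur3:::which_leaves(ti, v))
  present <- which(pres)
  best <- Inf
  for (g in seq_len(ti$nbranch)) {
    if (!all(present %in% leaves_below[[g]])) next
    cnt <- 0L
    stack <- g
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!any(pres[leaves_below[[v]]])) { cnt <- cnt + 1L; next }
      if (v > ti$ntip) stack <- c(stack, ti$children[[v]])
    }
    best <- min(best, cnt)
  }
  best
}
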