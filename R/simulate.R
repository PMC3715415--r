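# Gene-content simulator. The generator states a world with the structure
# the analysis assumes: families gained once (mostly at the root, with a
# tail of later inventions), lost and duplicated along the branches of a
# Yule species tree, plus planted complex architectures in which a broadly
# retained shared subunit A belongs to two complexes whose partner modules
# are lost in complementary lineage sets.

#' Simulation configuration
#'
#' Defaults describe the analysis regime of the study: a 51-species
#' eukaryote-like panel, 2000 orthologous groups, 50 shared-subunit
#' architectures, and duplication pressure doubled on shared subunits.
#' Probabilities are per branch; see the methods vignette for the
#' rationale behind each value.
#'
#' @param n_species panel size.
#' @param n_ogs number of orthologous groups.
#' @param p_origin_root probability an OG originates on the root stem
#'   (otherwise a uniformly drawn internal node: a later invention).
#' @param p_loss per-branch loss probability below the origin.
#' @param p_dup per-branch duplication-retention probability.
#' @param dup_mult_A multiplier on `p_dup` for shared-subunit (role A) OGs.
#' @param n_arch number of planted shared-subunit architectures
#'   (each yields two complexes sharing A).
#' @param p_complementary complementary-loss strength: probability that an
#'   architecture's B- and C-module losses are confined to disjoint lineage
#'   sets (the shared-subunit signature); otherwise the two lineage sets
#'   are drawn independently and may overlap, yielding open triangles
#'   without the complementarity pattern.
#' @param frac_open2A fraction of architectures where two in-paralogs of A
#'   take the two complex memberships.
#' @param module_size partner proteins per complex module (excluding A).
#' @param n_indep independent (non-shared) complexes added.
#' @param indep_size members per independent complex.
#' @param comp_strength range of the per-architecture complementary-loss
#'   probability (chance that a module is lost in one of its assigned
#'   lineages).
#' @param lineage_frac range of the fraction of species assigned to each
#'   side's loss lineages.
#' @param noise per-species presence flip probability applied to planted
#'   module profiles (annotation/clustering error analogue).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 51L, n_ogs = 2000L,
                       p_origin_root = 0.7, p_loss = 0.05,
                       p_dup = 0.0125, dup_mult_A = 2,
                       n_arch = 50L, p_complementary = 0.5,
                       frac_open2A = 0.1,
                       module_size = 3L, n_indep = 25L, indep_size = 4L,
                       comp_strength = c(0.3, 0.95),
                       lineage_frac = c(0.15, 0.35),
                       noise = 0.01) {
  cfg <- list(n_species = as.integer(n_species), n_ogs = as.integer(n_ogs),
              p_origin_root = p_origin_root, p_loss = p_loss,
              p_dup = p_dup, dup_mult_A = dup_mult_A,
              n_arch = as.integer(n_arch),
              p_complementary = p_complementary,
              frac_open2A = frac_open2A,
              module_size = as.integer(module_size),
              n_indep = as.integer(n_indep),
              indep_size = as.integer(indep_size),
              comp_strength = comp_strength, lineage_frac = lineage_frac,
              noise = noise)
  probs <- c(cfg$p_origin_root, cfg$p_loss, cfg$p_dup, cfg$frac_open2A,
             cfg$p_complementary, cfg$comp_strength, cfg$lineage_frac,
             cfg$noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_species < 4L) stop("need >= 4 species")
  if (cfg$n_ogs < cfg$n_arch * (2L * cfg$module_size + 1L))
    stop("too few OGs for the requested architectures")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate 4-letter species codes
#' @param n number of codes.
#' @return character vector like `"SAAA"`, `"SAAB"`, ...
#' @export
species_codes <- function(n) {
  if (n > 26^3) stop("too many species codes requested")
  i <- seq_len(n) - 1L
  paste0("S", LETTERS[i %/% 676L + 1L],
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

#' Simulate a rooted species tree (Yule process)
#' @param n number of leaves (>= 4).
#' @param seed RNG seed; the tree is deterministic given the seed.
#' @return rooted [ape::phylo] with generated 4-letter leaf codes.
#' @export
simulate_tree <- function(n, seed) {
  if (n < 4L) stop("need >= 4 species")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- species_codes(n)
  tree
}

#' Simulate gene content on a species tree
#'
#' Each OG draws an origin node (root stem with probability
#' `p_origin_root`, otherwise a uniform internal node), presence is
#' propagated tip-ward with independent per-branch losses, and copy numbers
#' accumulate independent per-branch duplication events. OGs that lose all
#' species are regenerated (counted in the `"regenerated"` attribute),
#' since the analysis requires at least one present species.
#'
#' @param cfg a [sim_config].
#' @param tree optional rooted tree (simulated from `cfg$n_species` when
#'   absent).
#' @param seed RNG seed.
#' @param dup_mult per-OG duplication multiplier (default 1 for all).
#' @return list `profiles` ([profile_matrix]), `tree`, `truth`
#'   (per-OG origin node and loss branches).
#' @export
simulate_gene_content <- function(cfg, tree = NULL, seed = 1L,
                                  dup_mult = NULL) {
  if (is.null(tree)) tree <- simulate_tree(cfg$n_species, seed)
  ti <- tree_index(tree)
  old <- set_local_seed(seed + 1L)
  on.exit(restore_seed(old), add = TRUE)
  n_og <- cfg$n_ogs
  if (is.null(dup_mult)) dup_mult <- rep(1, n_og)
  internal <- setdiff((ti$ntip + 1L):ti$nbranch, ti$root)
  draw_origin <- function(k) {
    ifelse(stats::runif(k) < cfg$p_origin_root, ti$root,
           internal[sample.int(length(internal), k, replace = TRUE)])
  }
  origin <- draw_origin(n_og)
  pres <- simulate_presence(ti, origin, cfg$p_loss)
  regen <- 0L
  repeat {
    dead <- which(colSums(pres) == 0L)
    if (length(dead) == 0L) break
    regen <- regen + length(dead)
    origin[dead] <- draw_origin(length(dead))
    pres[, dead] <- simulate_presence(ti, origin[dead], cfg$p_loss)
  }
  counts <- simulate_copy_counts(ti, pres, origin, cfg$p_dup * dup_mult)
  og_ids <- sprintf("OG%05d", seq_len(n_og))
  m <- t(counts)
  dimnames(m) <- list(og_ids, ti$labels)
  pm <- profile_matrix(m)
  truth <- list(origin = stats::setNames(origin, og_ids),
                regenerated = regen)
  list(profiles = pm, tree = tree, truth = truth)
}

# presence matrix (leaves x OGs) from origins and per-branch loss prob
simulate_presence <- function(ti, origin, p_loss) {
  n_og <- length(origin)
  alive <- matrix(FALSE, nrow = ti$nbranch, ncol = n_og)
  loss <- matrix(stats::runif(ti$nbranch * n_og) < p_loss,
                 nrow = ti$nbranch)
  for (v in ti$preorder) {
    par <- ti$parent[v]
    from_parent <- if (par > 0L) alive[par, ] & !loss[v, ] else FALSE
    alive[v, ] <- from_parent | (origin == v)
  }
  alive[seq_len(ti$ntip), , drop = FALSE]
}

# copy counts (leaves x OGs): 1 + accumulated duplication events along the
# origin-to-leaf path, zero where absent
simulate_copy_counts <- function(ti, pres, origin, p_dup_og) {
  n_og <- length(origin)
  dup <- matrix(stats::runif(ti$nbranch * n_og) <
                  rep(p_dup_og, each = ti$nbranch), nrow = ti$nbranch)
  # events only accumulate on branches at or below each OG's origin
  insub <- matrix(FALSE, nrow = ti$nbranch, ncol = n_og)
  acc <- matrix(0L, nrow = ti$nbranch, ncol = n_og)
  for (v in ti$preorder) {
    par <- ti$parent[v]
    insub[v, ] <- (origin == v) | (if (par > 0L) insub[par, ] else FALSE)
    below <- if (par > 0L) acc[par, ] else 0L
    acc[v, ] <- (below + dup[v, ]) * insub[v, ]
  }
  cnt <- (1L + acc[seq_len(ti$ntip), , drop = FALSE]) * pres
  storage.mode(cnt) <- "integer"
  cnt
}

#' Plant shared-subunit complex architectures into simulated gene content
#'
#' For each architecture a broadly present OG is chosen as the shared
#' subunit A; two complexes `K_B = {A, B...}` and `K_C = {A, C...}` are
#' built, and the module members' profiles are resampled as copies of A's
#' presence with losses confined to two disjoint lineage sets (clade-level
#' complementary losses of strength drawn from `cfg$comp_strength`), plus
#' per-species noise flips. A fraction of architectures place two
#' in-paralogs of A in the two complexes (`open2A` ground truth).
#' Independent complexes are added from untouched OGs.
#'
#' @param cfg a [sim_config].
#' @param sim result of [simulate_gene_content].
#' @param seed RNG seed.
#' @return list `profiles` (updated), `complexes` ([complex_set]),
#'   `network` (protein-level), `og_network` (OG-level, with provenance),
#'   `og_map`, `truth` (architecture table, per-OG role, planted triplet
#'   labels).
#' @export
plant_complexes <- function(cfg, sim, seed = 1L) {
  tree <- sim$tree
  ti <- tree_index(tree)
  pm <- sim$profiles
  P <- presence(pm)[, ti$labels, drop = FALSE]
  n <- ti$ntip
  old <- set_local_seed(seed + 2L)
  on.exit(restore_seed(old), add = TRUE)

  npres <- rowSums(P)
  broad <- which(npres >= ceiling(0.75 * n))
  need_a <- cfg$n_arch
  if (length(broad) < need_a)
    stop("insufficient broadly-present OGs for architectures")
  a_idx <- sample(broad, need_a)
  pool <- setdiff(seq_len(nrow(pm)), a_idx)
  need_mod <- cfg$n_arch * 2L * cfg$module_size
  mod_idx <- sample(pool, need_mod)
  pool <- setdiff(pool, mod_idx)

  # candidate lineages: clades of 2..round(0.12 n) leaves, plus single leaves
  clades <- lapply(seq_len(ti$nbranch), function(v) which_leaves(ti, v))
  sizes <- lengths(clades)
  cand <- which(sizes >= 1L & sizes <= max(2L, round(0.12 * n)))

  ids <- rownames(pm)
  counts <- unclass(pm)[, ti$labels, drop = FALSE]
  complexes <- list()
  og_map <- character(0L)
  arch_rows <- list()
  trip_rows <- list()
  role <- stats::setNames(rep("background", nrow(pm)), ids)
  open2a <- stats::runif(cfg$n_arch) < cfg$frac_open2A
  complementary <- stats::runif(cfg$n_arch) < cfg$p_complementary
  mod_ptr <- 0L

  for (k in seq_len(cfg$n_arch)) {
    ai <- a_idx[k]
    a_pres <- P[ai, ]
    q <- stats::runif(1L, cfg$comp_strength[1L], cfg$comp_strength[2L])
    fb <- stats::runif(1L, cfg$lineage_frac[1L], cfg$lineage_frac[2L])
    fc <- stats::runif(1L, cfg$lineage_frac[1L], cfg$lineage_frac[2L])
    sets <- if (complementary[k])
      pick_disjoint_lineages(ti, clades, cand, round(fb * n), round(fc * n))
    else
      pick_free_lineages(ti, clades, cand, round(fb * n), round(fc * n))
    b_mem <- mod_idx[mod_ptr + seq_len(cfg$module_size)]
    mod_ptr <- mod_ptr + cfg$module_size
    c_mem <- mod_idx[mod_ptr + seq_len(cfg$module_size)]
    mod_ptr <- mod_ptr + cfg$module_size
    for (bi in b_mem) {
      P[bi, ] <- module_profile(a_pres, sets$B, q, cfg$noise)
    }
    for (ci in c_mem) {
      P[ci, ] <- module_profile(a_pres, sets$C, q, cfg$noise)
    }
    role[ai] <- "A"
    role[b_mem] <- "B"; role[c_mem] <- "C"
    a_prot <- if (open2a[k]) paste0(ids[ai], c(".1", ".2"))
    else rep(paste0(ids[ai], ".1"), 2L)
    b_prot <- paste0(ids[b_mem], ".1")
    c_prot <- paste0(ids[c_mem], ".1")
    complexes[[paste0("KB", k)]] <- c(a_prot[1L], b_prot)
    complexes[[paste0("KC", k)]] <- c(a_prot[2L], c_prot)
    og_map[a_prot] <- ids[ai]
    og_map[b_prot] <- ids[b_mem]
    og_map[c_prot] <- ids[c_mem]
    arch_rows[[k]] <- data.frame(arch = k, og_a = ids[ai],
                                 open2A = open2a[k],
                                 complementary = complementary[k],
                                 q = q, stringsAsFactors = FALSE)
    trip_rows[[k]] <- expand.grid(og_b = ids[b_mem], og_c = ids[c_mem],
                                  stringsAsFactors = FALSE)
    trip_rows[[k]]$og_a <- ids[ai]
    trip_rows[[k]]$arch <- k
    trip_rows[[k]]$architecture <-
      if (complementary[k]) "shared-subunit" else "shared-topology"
  }

  # independent complexes from untouched OGs
  if (cfg$n_indep > 0L) {
    need <- cfg$n_indep * cfg$indep_size
    if (length(pool) < need) stop("too few OGs left for independent complexes")
    ind_idx <- sample(pool, need)
    for (k in seq_len(cfg$n_indep)) {
      mem <- ind_idx[(k - 1L) * cfg$indep_size + seq_len(cfg$indep_size)]
      prot <- paste0(ids[mem], ".1")
      complexes[[paste0("KI", k)]] <- prot
      og_map[prot] <- ids[mem]
      role[mem] <- "indep"
    }
  }

  # refresh copy numbers: planted profiles changed presence, and role-A OGs
  # receive the duplication multiplier
  mult <- rep(1, nrow(pm))
  mult[role == "A"] <- cfg$dup_mult_A
  origin <- rep(ti$root, nrow(pm))   # counts conditioned on final presence
  dup_cnt <- simulate_copy_counts(ti, t(P), origin, cfg$p_dup * mult)
  counts_new <- t(dup_cnt)
  dimnames(counts_new) <- list(ids, ti$labels)
  pm2 <- profile_matrix(counts_new[, colnames(pm), drop = FALSE])

  cs <- complex_set(complexes)
  net <- complexes_to_pairs(cs)
  og_net <- project_to_ogs(net, og_map)
  truth <- list(arch = do.call(rbind, arch_rows),
                triplets = do.call(rbind, trip_rows),
                role = role, open2A = open2a)
  list(profiles = pm2, complexes = cs, network = net, og_network = og_net,
       og_map = og_map, truth = truth, tree = tree)
}

# leaves under node v
which_leaves <- function(ti, v) {
  if (v <= ti$ntip) return(v)
  out <- integer(0L)
  stack <- v
  while (length(stack) > 0L) {
    x <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (x <= ti$ntip) out <- c(out, x)
    else stack <- c(stack, ti$children[[x]])
  }
  out
}

# two lineage sets drawn independently (overlap allowed): open triangles
# without the complementary signature
pick_free_lineages <- function(ti, clades, cand, target_b, target_c) {
  take <- function(target) {
    got <- integer(0L)
    for (v in sample(cand)) {
      lv <- clades[[v]]
      if (any(lv %in% got)) next
      got <- c(got, lv)
      if (length(got) >= target) break
    }
    got
  }
  list(B = take(max(2L, target_b)), C = take(max(2L, target_c)))
}

# choose two disjoint lineage (leaf) sets of roughly the target sizes
pick_disjoint_lineages <- function(ti, clades, cand, target_b, target_c) {
  ord <- sample(cand)
  used <- logical(ti$ntip)
  take <- function(target) {
    got <- integer(0L)
    for (v in ord) {
      lv <- clades[[v]]
      if (any(used[lv])) next
      got <- c(got, lv)
      used[lv] <<- TRUE
      if (length(got) >= target) break
    }
    got
  }
  B <- take(max(2L, target_b))
  C <- take(max(2L, target_c))
  list(B = B, C = C)
}

# presence of a module member: A's presence, minus its assigned lineages
# (lost with probability q per lineage species), plus noise flips
module_profile <- function(a_pres, lineage, q, noise) {
  p <- a_pres
  lose <- lineage[stats::runif(length(lineage)) < q]
  p[lose] <- FALSE
  flip <- stats::runif(length(p)) < noise
  p[flip] <- !p[flip]
  if (!any(p)) p[sample(which(a_pres), 1L)] <- TRUE
  p
}

#' One-call synthetic data set
#'
#' Simulates a tree, gene content and planted complex architectures, and
#' returns everything the pipeline consumes plus ground truth. Truth labels
#' are kept in a separate element so analysis code cannot accidentally
#' consume them.
#'
#' @param cfg a [sim_config].
#' @param seed RNG seed (mandatory; all stages derive their streams from
#'   it).
#' @return list `tree`, `profiles`, `complexes`, `network`, `og_network`,
#'   `og_map`, `truth`.
#' @export
simulate_cooccur <- function(cfg = sim_config(), seed = 1L) {
  sim <- simulate_gene_content(cfg, seed = seed)
  planted <- plant_complexes(cfg, sim, seed = seed)
  planted$truth$origin <- sim$truth$origin
  planted$truth$regenerated <- sim$truth$regenerated
  planted
}

#' Planted pair cohort for classification recovery
#'
#' Generates profile pairs with known ground-truth categories on a given
#' tree: `matching` partners share all loss events (up to noise),
#' `taxonomic` partners are later inventions confined to a clade of the
#' partner's range, `subset` partners lose a scattered set of species from
#' a near-ubiquitous partner, and `other` pairs evolve independently. The
#' pairs form the edges of an OG-level network whose node set also defines
#' the background distribution.
#'
#' @param tree rooted species tree.
#' @param n_per_category planted pairs per category.
#' @param seed RNG seed.
#' @param p_loss background per-branch loss probability.
#' @param noise per-species presence flip probability on matching partners.
#' @return list `profiles`, `network` (OG-level), `truth` (data.frame
#'   `og_a`, `og_b`, `category`).
#' @export
plant_pair_cohort <- function(tree, n_per_category = 50L, seed = 1L,
                              p_loss = 0.04, noise = 0.005) {
  ti <- tree_index(tree)
  n <- ti$ntip
  old <- set_local_seed(seed + 3L)
  on.exit(restore_seed(old), add = TRUE)
  profs <- list(); truth <- list(); eid <- 0L
  new_id <- function() sprintf("PG%04d", length(profs) + 1L)
  internal <- setdiff((ti$ntip + 1L):ti$nbranch, ti$root)
  clade_sz <- vapply(internal, function(v) length(which_leaves(ti, v)),
                     integer(1L))
  mid_clades <- internal[clade_sz >= 5L & clade_sz <= floor(n / 2)]
  root_presence <- function(p_loss) {
    repeat {
      pres <- drop(simulate_presence(ti, ti$root, p_loss))
      if (sum(pres) >= ceiling(n / 2)) return(pres)
    }
  }
  flip_noise <- function(p, rate) {
    fl <- stats::runif(length(p)) < rate
    p[fl] <- !p[fl]
    if (!any(p)) p[sample.int(length(p), 1L)] <- TRUE
    p
  }
  add_pair <- function(pa, pb, category) {
    ia <- new_id(); profs[[ia]] <<- pa
    ib <- new_id(); profs[[ib]] <<- pb
    truth[[length(truth) + 1L]] <<- data.frame(og_a = ia, og_b = ib,
                                               category = category,
                                               stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_per_category)) {
    # matching: identical loss history, independent noise
    base <- root_presence(p_loss)
    add_pair(flip_noise(base, noise), flip_noise(base, noise), "matching")
    # taxonomic: partner invented inside a clade
    a <- root_presence(p_loss)
    cl <- if (length(mid_clades) > 0L) sample(mid_clades, 1L) else internal[1L]
    b <- logical(n)
    lv <- which_leaves(ti, cl)
    b[lv] <- drop(simulate_presence(ti, cl, p_loss))[lv]
    if (!any(b)) b[sample(lv, 1L)] <- TRUE
    add_pair(a, b, "taxonomic")
    # subset: scattered extra losses from a near-ubiquitous partner
    a <- root_presence(0.005)
    b <- a
    k_extra <- sample(8:14, 1L)
    drop_leaves <- sample(which(a), min(k_extra, sum(a) - 2L))
    b[drop_leaves] <- FALSE
    if (!any(b)) b[which(a)[1L]] <- TRUE
    add_pair(a, b, "subset")
    # other: independent histories
    add_pair(root_presence(0.06), root_presence(0.06), "other")
  }
  Pm <- do.call(rbind, profs) * 1L
  dimnames(Pm) <- list(names(profs), ti$labels)
  pm <- profile_matrix(Pm)
  truth <- do.call(rbind, truth)
  net <- interaction_network(data.frame(a = truth$og_a, b = truth$og_b,
                                        stringsAsFactors = FALSE),
                             nodes = rownames(pm), level = "og")
  list(profiles = pm, network = net, truth = truth)
}
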