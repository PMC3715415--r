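test_that("covered complexes are removed in a single pass", {
  cs <- complex_set(list(K1 = c("a", "b", "c"), K2 = c("a", "b")))
  kept <- remove_covered_complexes(cs)
  expect_identical(names(kept), "K1")
  expect_identical(attr(kept, "removed"), "K2")

  cs <- complex_set(list(K1 = c("a", "b"), K2 = c("c", "d")))
  expect_identical(names(remove_covered_complexes(cs)), c("K1", "K2"))

  # mutual union-coverage: every member occurs in two complexes, so the
  # single pass against the original set removes all three
  cs <- complex_set(list(K1 = c("a", "b"), K2 = c("b", "c"),
                         K3 = c("a", "c")))
  kept <- remove_covered_complexes(cs)
  expect_length(kept, 0L)
  expect_setequal(attr(kept, "removed"), c("K1", "K2", "K3"))
  # brute-force check of member uniqueness for each complex
  for (id in names(cs)) {
    others <- unique(unlist(cs[setdiff(names(cs), id)]))
    expect_true(all(cs[[id]] %in% others))
  }
})

test_that("complexes expand to unique unordered pairs", {
  cs <- complex_set(list(K1 = c("a", "b", "c")))
  net <- complexes_to_pairs(cs)
  expect_identical(net$edges,
                   data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                              stringsAsFactors = FALSE))
  cs <- complex_set(list(K1 = c("a", "b"), K2 = c("b", "a")))
  expect_identical(nrow(complexes_to_pairs(cs)$edges), 1L)
})

test_that("pair expansion equals the brute-force double loop", {
  set.seed(21)
  prots <- sprintf("p%02d", 1:40)
  cs <- complex_set(stats::setNames(
    lapply(1:60, function(i) sample(prots, sample(2:6, 1L))),
    paste0("K", 1:60)))
  net <- complexes_to_pairs(cs)
  seen <- new.env(parent = emptyenv())
  for (mem in cs) for (i in seq_along(mem)) for (j in seq_along(mem))
    if (i < j) {
      k <- paste(sort(c(mem[i], mem[j])), collapse = "|")
      assign(k, TRUE, envir = seen)
    }
  expect_identical(nrow(net$edges), length(ls(seen)))
  expect_setequal(paste0(net$edges$a, "|", net$edges$b), ls(seen))
})

test_that("pair expansion is invariant to complex iteration order", {
  set.seed(22)
  cs <- complex_set(stats::setNames(
    lapply(1:10, function(i) sample(letters, sample(2:5, 1L))),
    paste0("K", 1:10)))
  n1 <- complexes_to_pairs(cs)
  n2 <- complexes_to_pairs(complex_set(unclass(cs)[sample(10)]))
  expect_identical(n1$edges, n2$edges)
})

test_that("OG projection keeps provenance and counts intra-OG edges", {
  om <- c(a1 = "OG_A", a2 = "OG_A", b = "OG_B")
  net <- make_net("a1", "b", level = "protein")
  og <- project_to_ogs(net, om)
  expect_identical(og$edges, data.frame(a = "OG_A", b = "OG_B",
                                        stringsAsFactors = FALSE))
  expect_identical(og$provenance[["OG_A|OG_B"]]$protein_a, "a1")

  net <- make_net("a1", "a2", level = "protein")
  og <- project_to_ogs(net, om)
  expect_identical(nrow(og$edges), 0L)
  expect_identical(og$n_intra, 1L)

  expect_error(project_to_ogs(make_net("a1", "zz", level = "protein"), om),
               "unmapped")
})

test_that("a toy projection matches the hand result", {
  om <- c(x1 = "OGX", x2 = "OGX", y1 = "OGY", y2 = "OGY",
          stats::setNames(paste0("OG", 1:6), paste0("p", 1:6)))
  net <- make_net("x1", "y1", "x2", "y2", "x1", "p1", "p1", "p2",
                  "x1", "x2", "p3", "p4", level = "protein")
  og <- project_to_ogs(net, om)
  expect_setequal(paste0(og$edges$a, "|", og$edges$b),
                  c("OGX|OGY", "OG1|OGX", "OG1|OG2", "OG3|OG4"))
  expect_identical(og$n_intra, 1L)
  # both protein pairs realizing OGX-OGY are retained
  expect_identical(nrow(og$provenance[["OGX|OGY"]]), 2L)
})

test_that("projection never increases the component count", {
  set.seed(23)
  for (rep in 1:5) {
    prots <- sprintf("q%02d", 1:30)
    e <- t(replicate(40, sample(prots, 2L)))
    net <- interaction_network(data.frame(a = e[, 1L], b = e[, 2L]),
                               nodes = prots, level = "protein")
    om <- stats::setNames(paste0("OG", sample(1:12, 30, replace = TRUE)),
                          prots)
    og <- project_to_ogs(net, om)
    expect_lte(network_stats(og)$n_components,
               network_stats(net)$n_components)
  }
})

test_that("network statistics match their definitions", {
  tri <- make_net("a", "b", "b", "c", "a", "c")
  st <- network_stats(tri)
  expect_equal(st$average_degree, 2)
  expect_identical(st$n_components, 1L)
  expect_equal(st$average_component_size, 3)

  two <- make_net("a", "b", "c", "d")
  st <- network_stats(two)
  expect_identical(st$n_components, 2L)
  expect_equal(st$average_component_size, 2)

  expect_error(network_stats(interaction_network(
    data.frame(a = character(), b = character()), nodes = character())),
    "empty")
})

test_that("component stats agree with an independent BFS", {
  set.seed(24)
  nodes <- sprintf("n%03d", 1:100)
  e <- t(replicate(80, sample(nodes, 2L)))
  net <- interaction_network(data.frame(a = e[, 1L], b = e[, 2L]),
                             nodes = nodes, level = "protein")
  st <- network_stats(net)
  # BFS from scratch
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]; b <- net$edges$b[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0L); n_comp <- 0L
  for (v in nodes) {
    if (v %in% seen) next
    n_comp <- n_comp + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (x %in% seen) next
      seen <- c(seen, x)
      queue <- c(queue, setdiff(adj[[x]], seen))
    }
  }
  expect_identical(st$n_components, n_comp)
  expect_equal(st$average_degree, 2 * nrow(net$edges) / 100)
  expect_equal(st$average_component_size, 100 / n_comp)
})
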