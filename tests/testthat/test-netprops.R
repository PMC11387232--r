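test_that("canonical three-node fixtures count as expected", {
  ffl <- reg_network(tibble::tibble(tf = c("A", "A", "B"),
                                    target = c("B", "C", "C")))
  expect_equal(count_motifs(ffl), c(ffl = 1L, complex_ffl = 0L, fbl3 = 0L))

  cyc <- reg_network(tibble::tibble(tf = c("A", "B", "C"),
                                    target = c("B", "C", "A")))
  expect_equal(count_motifs(cyc), c(ffl = 0L, complex_ffl = 0L, fbl3 = 1L))

  cffl <- reg_network(tibble::tibble(tf = c("A", "B", "A", "B"),
                                     target = c("B", "A", "C", "C")))
  expect_equal(count_motifs(cffl), c(ffl = 0L, complex_ffl = 1L, fbl3 = 0L))

  # self-loops do not create motifs
  selfy <- reg_network(tibble::tibble(tf = c("A", "A", "B"),
                                      target = c("A", "B", "C")))
  expect_equal(count_motifs(selfy), c(ffl = 0L, complex_ffl = 0L, fbl3 = 0L))
})

test_that("motif counts equal exhaustive triple enumeration on random graphs", {
  set.seed(55)
  for (i in 1:30) {
    net <- random_net(sample(8:30, 1), p = runif(1, 0.05, 0.25),
                      self_loops = i %% 4 == 0)
    expect_equal(count_motifs(net), brute_motifs(net), info = paste("graph", i))
  }
})

test_that("potential motif formula matches hand values and its identity case", {
  expect_equal(potential_motifs(10, 4, 3, 2), 115.2)
  expect_equal(potential_motifs(4, 2, 3, 3), 3.0)
  expect_equal(potential_motifs(10, 0, 3, 2), 0)
  # full-regulator identity: n!/(n-3)!
  for (n in c(5, 12, 40)) {
    expect_equal(potential_motifs(n, n, 3, 2), n * (n - 1) * (n - 2))
    expect_equal(potential_motifs(n, n, 3, 3), n * (n - 1) * (n - 2))
  }
  expect_error(potential_motifs(2, 1, 3, 2), "at least")
  expect_error(potential_motifs(5, 6, 3, 2), "tfn")
})

test_that("saturated and star fixtures give the forced property values", {
  clique <- reg_network(tibble::tibble(
    tf = c("A", "A", "B", "B", "C", "C"),
    target = c("B", "C", "A", "C", "A", "B")))
  p <- compute_properties(clique)
  expect_equal(p$regulators_frac, 1)
  expect_equal(p$giant_component_frac, 1)
  expect_equal(p$density_times_reg_frac, 1)  # density 1 x regulator fraction 1
  expect_equal(p$avg_clustering, 1)

  star <- reg_network(tibble::tibble(tf = "hub", target = sprintf("l%d", 1:9)))
  ps <- compute_properties(star)
  expect_equal(ps$kmax_out_frac, 9 / 10)
  expect_equal(ps$selfreg_frac, 0)
  expect_equal(ps$avg_clustering, 0)
  expect_equal(ps$avg_shortest_path, 1)  # only hub->leaf pairs are reachable
})

test_that("properties match an independent naive reimplementation", {
  naive_props <- function(net) {
    genes <- net$nodes$gene
    n <- length(genes)
    e <- net$edges
    kout <- vapply(genes, function(g) sum(e$tf == g), integer(1))
    self <- sum(e$tf == e$target)
    # undirected simple adjacency, loops dropped
    adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
    for (i in seq_len(nrow(e))) {
      if (e$tf[i] != e$target[i]) {
        adj[e$tf[i], e$target[i]] <- TRUE
        adj[e$target[i], e$tf[i]] <- TRUE
      }
    }
    localc <- vapply(genes, function(g) {
      nb <- genes[adj[g, ]]
      if (length(nb) < 2) return(0)
      pairs <- utils::combn(nb, 2)
      sum(adj[cbind(pairs[1, ], pairs[2, ])]) / ncol(pairs)
    }, numeric(1))
    list(regulators_frac = mean(kout > 0), selfreg_frac = self / n,
         kmax_out_frac = max(kout) / n,
         density = (nrow(e) - self) / (n * (n - 1)),
         avg_clustering = mean(localc))
  }
  set.seed(77)
  for (i in 1:5) {
    net <- random_net(25, 0.1, self_loops = TRUE)
    p <- compute_properties(net)
    np <- naive_props(net)
    expect_equal(p$regulators_frac, np$regulators_frac)
    expect_equal(p$selfreg_frac, np$selfreg_frac)
    expect_equal(p$kmax_out_frac, np$kmax_out_frac)
    expect_equal(p$density_times_reg_frac, np$density * np$regulators_frac)
    expect_equal(p$avg_clustering, np$avg_clustering)
    # all fractions within [0,1], motif norms non-negative
    expect_true(all(unlist(p[c("regulators_frac", "selfreg_frac",
                               "kmax_out_frac", "giant_component_frac")]) >= 0))
    expect_true(all(unlist(p[c("regulators_frac", "selfreg_frac",
                               "kmax_out_frac", "giant_component_frac")]) <= 1))
    expect_true(all(unlist(p[c("ffl_norm", "complex_ffl_norm", "fbl3_norm")]) >= 0))
  }
})

test_that("diameter normalization supports both divisor readings", {
  chain <- reg_network(tibble::tibble(tf = c("a", "b", "c", "d"),
                                      target = c("b", "c", "d", "e")))
  p1 <- compute_properties(chain, diameter_divisor = "n-2")
  p2 <- compute_properties(chain, diameter_divisor = "n/2")
  expect_equal(p1$diameter_norm, 4 / 3)   # longest path 4, n - 2 = 3
  expect_equal(p2$diameter_norm, 4 / 2.5) # n / 2 = 2.5
})

test_that("ER replicates have exactly m edges, no loops, mean degree 2m/n", {
  er <- er_ensemble(50, 120, reps = 5, seed = 2)
  for (net in er$networks) {
    expect_equal(nrow(net$edges), 120L)
    expect_false(any(net$edges$tf == net$edges$target))
    expect_false(anyDuplicated(edge_key(net)) > 0)
    deg <- out_degrees(net) + vapply(net$nodes$gene, function(g) {
      sum(net$edges$target == g)
    }, integer(1))
    expect_equal(mean(deg), 2 * 120 / 50)
  }
  expect_error(er_ensemble(5, 100), "exceeds")
  # determinism
  er2 <- er_ensemble(50, 120, reps = 5, seed = 2)
  expect_equal(er$properties, er2$properties)
})

test_that("min-max scaling, Pearson and Ward behave on known profiles", {
  base <- compute_properties(random_net(20, 0.15))
  props <- dplyr::bind_rows(base, base, base)
  props$name <- c("n1", "n2", "n3")
  # plant one varying property: [2, 4, 6] scales to [0, 0.5, 1]
  props$avg_shortest_path <- c(2, 4, 6)
  cmp <- compare_networks(props)
  expect_equal(unname(cmp$scaled[, "avg_shortest_path"]), c(0, 0.5, 1))
  # constant columns scale to 0
  expect_true(all(cmp$scaled[, "regulators_frac"] == 0))

  # identical profiles: Pearson r = 1 and first merge in the dendrogram
  set.seed(3)
  p1 <- compute_properties(random_net(20, 0.15)); p1$name <- "a"
  p2 <- p1; p2$name <- "b"
  p3 <- compute_properties(random_net(40, 0.3)); p3$name <- "c"
  cmp2 <- compare_networks(dplyr::bind_rows(p1, p2, p3))
  expect_equal(cmp2$pearson["a", "b"], 1)
  first_merge <- cmp2$network_linkage$merge[1, ]
  expect_setequal(cmp2$network_linkage$labels[-first_merge], c("a", "b"))
})

test_that("shortcut fractions are forced on triangle, cycle and tree", {
  tri <- reg_network(tibble::tibble(tf = c("a", "a", "b"),
                                    target = c("b", "c", "c")))
  expect_equal(shortcut_fraction(tri), 0)
  cyc4 <- reg_network(tibble::tibble(tf = c("a", "b", "c", "d"),
                                     target = c("b", "c", "d", "a")))
  expect_equal(shortcut_fraction(cyc4), 1)
  tree <- reg_network(tibble::tibble(tf = c("r", "r", "a"),
                                     target = c("a", "b", "c")))
  expect_equal(shortcut_fraction(tree), 1)
})

test_that("regulator/structural proportions partition the node set", {
  nodes <- tibble::tibble(gene = sprintf("g%d", 1:10),
                          is_tf = c(rep(TRUE, 3), rep(FALSE, 7)),
                          is_sigma = FALSE)
  net <- reg_network(tibble::tibble(tf = "g1", target = "g5"), nodes = nodes)
  expect_equal(tf_structural_proportion(net),
               c(regulator_frac = 0.3, structural_frac = 0.7))
  set.seed(12)
  for (i in 1:5) {
    net <- random_net(sample(10:30, 1), 0.1)
    expect_equal(sum(tf_structural_proportion(net)), 1)
  }
})

test_that("synthetic hub networks separate from their ER average", {
  # planted networks have hubs and heavy regulator structure; the scaled
  # profile distance to the ER mean should exceed the spread between two ER
  # replicates in a clear majority of seeds
  wins <- 0L
  for (s in 1:20) {
    cfg <- synth_config(n_genes = 120, n_tfs = 15, n_sigma = 2, seed = s)
    g <- generate_genome(cfg)
    net <- generate_truth_network(g, cfg)
    m <- nrow(net$edges)
    er <- er_ensemble(nrow(net$nodes), m, reps = 4, seed = s + 1000L)
    pn <- compute_properties(net); pn$name <- "deduced"
    props <- dplyr::bind_rows(pn, er$er_avg,
                              er$properties[1:2, ] |>
                                dplyr::mutate(name = c("rep1", "rep2")))
    cmp <- suppressMessages(compare_networks(props))
    d <- as.matrix(dist(cmp$scaled))
    if (d["deduced", "ER_avg"] > d["rep1", "rep2"]) wins <- wins + 1L
  }
  expect_gte(wins, 16L)  # >= 80% of seeds
})
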