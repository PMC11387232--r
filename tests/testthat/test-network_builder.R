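test_that("stratified search follows the three-pass hand traces", {
  tfs <- c("T1", "T2")
  cands <- c("T1", "T2", "g1", "g2")

  # g1 is captured in the strict pass, so T2's medium hit is excluded
  hits <- scan_hits(c("T1", "T2"), c("g1", "g1"), c(1e-07, 1e-05))
  net <- stratified_target_search(tfs, cands, hits)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$tf, "T1")
  expect_equal(net$edges$tier, "STRICT")

  # g2 is never hit strictly: both TFs qualify at the medium pass
  hits <- scan_hits(c("T1", "T2"), c("g2", "g2"), c(5e-06, 1e-05))
  net <- stratified_target_search(tfs, cands, hits)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$tier, "MEDIUM")
  expect_setequal(net$edges$tf, c("T1", "T2"))

  # self-regulation is retained
  net <- stratified_target_search(tfs, cands, scan_hits("T1", "T1", 1e-08))
  expect_equal(edge_key(net), "T1 T1")
  expect_equal(net$edges$tier, "STRICT")

  # inclusive boundary: exactly 1e-06 is strict
  net <- stratified_target_search(tfs, cands, scan_hits("T1", "g1", 1e-06))
  expect_equal(net$edges$tier, "STRICT")
})

test_that("duplicate hits collapse to the minimum p-value per pair", {
  net <- stratified_target_search(
    "T1", c("T1", "g1"),
    scan_hits(rep("T1", 3), rep("g1", 3), c(2e-05, 3e-07, 9e-06)))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$p_value, 3e-07)
  expect_equal(net$edges$tier, "STRICT")

  # the collapsed minimum decides the tier: 3e-06 is medium, not strict
  net2 <- stratified_target_search(
    "T1", c("T1", "g1"),
    scan_hits(rep("T1", 2), rep("g1", 2), c(2e-05, 3e-06)))
  expect_equal(net2$edges$p_value, 3e-06)
  expect_equal(net2$edges$tier, "MEDIUM")
})

test_that("hits outside the searched sets are ignored, bad p-values error", {
  hits <- scan_hits(c("T1", "TX"), c("g1", "g1"), c(1e-07, 1e-07))
  expect_message(net <- stratified_target_search("T1", c("T1", "g1"), hits),
                 "ignored")
  expect_equal(nrow(net$edges), 1L)
  bad <- tibble::tibble(tf_id = "T1", target_id = "g1", p_value = -1)
  expect_error(stratified_target_search("T1", c("T1", "g1"), bad),
               "non-positive")
})

test_that("every target sits in its brute-force minimum stratum, once", {
  tiers <- c(1e-06, 1e-05, 1e-04)
  set.seed(99)
  for (i in 1:25) {
    n_tf <- sample(3:8, 1); n_g <- sample(10:40, 1)
    tfs <- sprintf("T%d", seq_len(n_tf))
    genes <- c(tfs, sprintf("g%d", seq_len(n_g)))
    n_hits <- sample(20:120, 1)
    hits <- scan_hits(sample(tfs, n_hits, TRUE), sample(genes, n_hits, TRUE),
                      10^runif(n_hits, -8, -2))
    net <- stratified_target_search(tfs, genes, hits)
    # oracle: minimum stratum over all of a target's hits
    collapsed <- aggregate(p_value ~ target_id, data = hits, FUN = min)
    for (tg in unique(net$edges$target)) {
      pmin_t <- collapsed$p_value[collapsed$target_id == tg]
      expected_tier <- c("STRICT", "MEDIUM", "LOW")[findInterval(
        pmin_t, c(0, tiers), rightmost.closed = FALSE)]
      got <- unique(net$edges$tier[net$edges$target == tg])
      expect_length(got, 1L)
      expect_equal(got, expected_tier, info = tg)
    }
    # union over tiers = candidates with any hit at p <= 1e-04
    expect_setequal(unique(net$edges$target),
                    collapsed$target_id[collapsed$p_value <= 1e-04])
  }
})

test_that("tightening tier thresholds never adds edges", {
  set.seed(17)
  for (i in 1:10) {
    tfs <- sprintf("T%d", 1:5)
    genes <- c(tfs, sprintf("g%d", 1:25))
    hits <- scan_hits(sample(tfs, 60, TRUE), sample(genes, 60, TRUE),
                      10^runif(60, -8, -3))
    loose <- stratified_target_search(tfs, genes, hits)
    tight <- stratified_target_search(tfs, genes, hits,
                                      tiers = c(1e-07, 1e-06, 1e-05))
    expect_true(all(edge_key(tight) %in% edge_key(loose)))
  }
})

test_that("tier composition percentages sum to 100 and count per tier", {
  tfs <- c("T1", "T2")
  hits <- scan_hits(c("T1", "T1", "T2"), c("a", "b", "c"),
                    c(1e-07, 5e-06, 5e-05))
  net <- stratified_target_search(tfs, c(tfs, "a", "b", "c"), hits)
  comp <- tier_composition(net)
  expect_equal(comp$n_edges, c(1L, 1L, 1L))
  expect_equal(sum(comp$percent), 100)
})

test_that("regulons form one per out-connected regulator with annotation", {
  genome <- tiny_genome(6, tf = c(1L, 2L))
  hits <- scan_hits(c("G001", "G001", "G002"), c("G003", "G004", "G002"),
                    c(1e-07, 1e-07, 1e-07))
  net <- stratified_target_search(c("G001", "G002"), genome$locus_tag, hits,
                                  genome = genome)
  regs <- build_regulons(net, genome)
  expect_length(regs, 2L)
  expect_setequal(regs[["G001"]]$target, c("G003", "G004"))
  expect_true(all(c("ordinal", "cog") %in% names(regs[["G001"]])))
  # a TF with only a self-loop forms a regulon of itself
  expect_equal(regs[["G002"]]$target, "G002")
  expect_length(build_regulons(reg_network(tibble::tibble())), 0L)
})

test_that("most-regulated ranking is by in-degree with lexicographic ties", {
  edges <- tibble::tibble(
    tf = c("a", "b", "c", "a", "b", "a"),
    target = c("hub", "hub", "hub", "zz", "zz", "mm"))
  net <- reg_network(edges)
  top <- most_regulated(net, 3)
  expect_equal(top$gene, c("hub", "zz", "mm"))
  expect_equal(top$in_degree, c(3L, 2L, 1L))

  # tie at equal in-degree: lexicographic order, both reported
  net2 <- reg_network(tibble::tibble(tf = c("a", "a"), target = c("y", "x")))
  expect_equal(most_regulated(net2, 2)$gene, c("x", "y"))

  expect_equal(nrow(most_regulated(reg_network(tibble::tibble()), 5)), 0L)
  expect_error(most_regulated(net, 0), "positive")
})

test_that("exclusive regulators are plain set differences", {
  mk <- function(tfs, tg) {
    reg_network(tibble::tibble(tf = tfs, target = tg))
  }
  a <- mk(c("t1", "t2"), c("x", "y"))
  b <- mk(c("t2", "t3"), c("x", "y"))
  ex <- exclusive_tfs(a, b)
  expect_equal(ex$only_A$gene, "t1")
  expect_equal(ex$only_B$gene, "t3")
  same <- exclusive_tfs(a, a)
  expect_equal(nrow(same$only_A), 0L)
  expect_equal(nrow(same$only_B), 0L)
  empty <- reg_network(tibble::tibble())
  expect_equal(exclusive_tfs(a, empty)$only_A$gene, c("t1", "t2"))
})
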