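test_that("lowly expressed TFs are excluded by total raw count", {
  cnt <- rbind(tf1 = c(0L, 1L, 2L, 3L),    # total 6 -> excluded
               tf2 = c(10L, 0L, 0L, 0L),   # total 10 -> retained (boundary)
               g1 = c(5L, 5L, 5L, 5L))
  colnames(cnt) <- paste0("s", 1:4)
  Q <- toy_count_matrix(cnt, condition = rep(c("control", "drought"), 2))
  res <- filter_low_expression_tfs(Q, c("tf1", "tf2", "ghost"))
  expect_equal(res$active, "tf2")
  expect_setequal(res$excluded$tf, c("tf1", "ghost"))
  expect_equal(res$excluded$reason[res$excluded$tf == "ghost"], "absent")
  res0 <- filter_low_expression_tfs(Q, c("tf1", "tf2"), threshold = 0)
  expect_setequal(res0$active, c("tf1", "tf2"))
})

test_that("top-edge selection keeps the ceiling and whole tie groups", {
  mk <- function(imp) structure(
    list(edges = data.frame(tf = paste0("t", seq_along(imp)),
                            target = paste0("g", seq_along(imp)),
                            importance = imp, stringsAsFactors = FALSE),
         stage = "raw", species = "A"), class = "grn_edge_set")
  expect_equal(nrow(select_top_edges(mk(seq_len(100) / 100))$edges), 10L)
  expect_equal(nrow(select_top_edges(mk(c(0.5, 0.4, 0.3, 0.2, 0.1)))$edges), 1L)
  expect_equal(nrow(select_top_edges(mk(rep(0.3, 10)))$edges), 10L)
})

test_that("motif filtering keeps edges whose target holds the TF's motif", {
  E <- structure(list(edges = data.frame(
    tf = c("tf1", "tf1", "tf2"), target = c("g1", "g2", "g1"),
    importance = c(0.5, 0.4, 0.3), stringsAsFactors = FALSE),
    stage = "top_fraction", species = "A"), class = "grn_edge_set")
  pres <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(c("g1", "g2"), "m1"))
  t2m <- data.frame(tf = "tf1", motif_id = "m1", stringsAsFactors = FALSE)
  expect_message(out <- motif_filter_edges(E, pres, t2m), "without a motif")
  expect_equal(out$edges$tf, "tf1")
  expect_equal(out$edges$target, "g1")
  expect_equal(out$stage, "motif_filtered")
})

test_that("Jaccard handles identity, disjointness and published counts", {
  mk <- function(tf, tg) structure(
    list(edges = data.frame(tf = tf, target = tg,
                            importance = rep(1, length(tf)),
                            stringsAsFactors = FALSE),
         stage = "raw", species = "A"), class = "grn_edge_set")
  e1 <- mk(c("a", "b"), c("x", "y"))
  expect_equal(jaccard_index(e1, e1), 1)
  e2 <- mk(c("c", "d"), c("x", "y"))
  expect_equal(jaccard_index(e1, e2), 0)
  empty <- mk(character(0), character(0))
  expect_error(jaccard_index(empty, empty), "empty")
  expect_equal(jaccard_from_counts(236, 12551), 236 / 12551)
  expect_error(jaccard_from_counts(10, 0), "empty union")
  expect_error(jaccard_from_counts(10, 5), "exceeds")
})

test_that("cross-species Jaccard maps endpoints through the ortholog pairs", {
  map <- structure(list(pairs = data.frame(
    gene_A = c("a1", "a2", "a3"), gene_B = c("b1", "b2", "b3"),
    stringsAsFactors = FALSE), unpaired_A = "a9", unpaired_B = "b9"),
    class = "ortholog_map")
  eA <- structure(list(edges = data.frame(
    tf = c("a1", "a1"), target = c("a2", "a9"), importance = 1,
    stringsAsFactors = FALSE), stage = "raw", species = "A"),
    class = "grn_edge_set")
  eB <- structure(list(edges = data.frame(
    tf = c("b1", "b3"), target = c("b2", "b9"), importance = 1,
    stringsAsFactors = FALSE), stage = "raw", species = "B"),
    class = "grn_edge_set")
  # a1->a2 and b1->b2 coincide; the unmapped-endpoint edges only pad the union
  expect_equal(jaccard_index(eA, eB, map), 1 / 3)
  summ <- network_summary(eA, eB, map)
  expect_equal(summ$intersection$edges, 1L)
  expect_equal(summ$union$edges, 3L)
  expect_equal(summ$union$edges,
               summ$network_A$edges + summ$network_B$edges -
                 summ$intersection$edges)
  expect_equal(summ$jaccard, 1 / 3)
})

test_that("a planted regulator dominates its targets' importances", {
  sim <- simulate_regulated_expression(n_tfs = 2, targets_per_tf = 3,
                                       n_decoys = 10, n_samples = 80,
                                       seed = 2)
  grn <- infer_grn(sim$X, sim$tfs, targets = sim$true_edges$target,
                   n_trees = 100, seed = 2, species = "A")
  top_reg <- vapply(split(grn$edges, grn$edges$target), function(e)
    e$tf[which.max(e$importance)], character(1))
  expect_equal(unname(top_reg[sim$true_edges$target]), sim$true_edges$tf)
  # per-target importances are normalized
  sums <- tapply(grn$edges$importance, grn$edges$target, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  # identical seeds give identical edge sets
  grn2 <- infer_grn(sim$X, sim$tfs, targets = sim$true_edges$target,
                    n_trees = 100, seed = 2, species = "A")
  expect_identical(grn$edges, grn2$edges)
  # permuting samples leaves the planted regulator on top
  perm <- sample(ncol(sim$X))
  grn3 <- infer_grn(sim$X[, perm], sim$tfs, targets = sim$true_edges$target,
                    n_trees = 100, seed = 2, species = "A")
  top3 <- vapply(split(grn3$edges, grn3$edges$target), function(e)
    e$tf[which.max(e$importance)], character(1))
  expect_equal(top3[names(top_reg)], top_reg)
})

test_that("constant targets are skipped and tiny designs rejected", {
  X <- rbind(tf1 = rnorm(10), tf2 = rnorm(10), flat = rep(1, 10))
  colnames(X) <- paste0("s", 1:10)
  expect_warning(grn <- infer_grn(X, c("tf1", "tf2"), targets = "flat",
                                  n_trees = 10, seed = 1),
                 "constant")
  expect_equal(nrow(grn$edges), 0L)
  expect_error(infer_grn(X[, 1:2], c("tf1", "tf2"), n_trees = 10, seed = 1),
               "3 samples")
  expect_error(infer_grn(X, "tf1", n_trees = 10, seed = 1), "2 candidate")
})
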