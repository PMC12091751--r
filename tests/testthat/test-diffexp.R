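test_that("size factors follow median-of-ratios with geometric mean 1", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1, s2 = 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  zero <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(zero), "median-of-ratios")
})

test_that("size factors equal a step-by-step hand computation", {
  set.seed(11)
  m <- matrix(rpois(15, 50) + 1, 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  # independent computation, explicit loops
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  raw <- numeric(3)
  for (j in 1:3) raw[j] <- stats::median(m[, j] / geo)
  manual <- raw / prod(raw)^(1 / 3)
  expect_equal(unname(size_factors(m)), manual)
})

test_that("BH adjustment matches the closed form and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("identical groups give null results and planted signal is found", {
  set.seed(2)
  x <- matrix(rnbinom(400, mu = 100, size = 20), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  # groups are exact copies of each other
  Q <- toy_count_matrix(cbind(x, x), condition = rep(c("control", "drought"),
                                                     each = 4))
  colnames(Q$counts) <- Q$samples$sample_id <- paste0("s", 1:8)
  res <- nb_contrast(Q, contrast_spec("null", paste0("s", 1:4),
                                      paste0("s", 5:8)))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$pvalue == 1))

  # large-sample limit: m2 = 4 * m1 with negligible dispersion -> lfc ~ 2
  set.seed(3)
  n <- 50
  big <- cbind(matrix(rnbinom(20 * n, mu = 1e4, size = 1e4), 20, n),
               matrix(rnbinom(20 * n, mu = 4e4, size = 1e4), 20, n))
  dimnames(big) <- list(paste0("g", 1:20), paste0("s", seq_len(2 * n)))
  Qb <- toy_count_matrix(big, condition = rep(c("control", "drought"),
                                              each = n))
  resb <- nb_contrast(Qb, contrast_spec("big", paste0("s", 1:n),
                                        paste0("s", (n + 1):(2 * n))),
                      sf = stats::setNames(rep(1, 2 * n), colnames(big)))
  expect_true(all(abs(resb$log2fc - 2) < 0.05))
  expect_true(all(resb$padj < 1e-6))
})

test_that("swapping the groups negates log2fc and keeps p-values", {
  set.seed(4)
  x <- matrix(rnbinom(300, mu = 80, size = 10), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  Q <- toy_count_matrix(x, condition = rep(c("control", "drought"), each = 5))
  g1 <- paste0("s", 1:5); g2 <- paste0("s", 6:10)
  fwd <- nb_contrast(Q, contrast_spec("fwd", g1, g2))
  rev_ <- nb_contrast(Q, contrast_spec("rev", g2, g1))
  expect_equal(rev_$log2fc, -fwd$log2fc)
  expect_equal(rev_$pvalue, fwd$pvalue)
  # padj is invariant to gene ordering
  perm <- sample(30)
  Qp <- toy_count_matrix(x[perm, ], condition = rep(c("control", "drought"),
                                                    each = 5))
  fwd_p <- nb_contrast(Qp, contrast_spec("fwd", g1, g2))
  expect_equal(fwd_p$padj[match(fwd$gene, fwd_p$gene)], fwd$padj)
})

test_that("all-zero genes are reported as no-change", {
  x <- rbind(g1 = rep(0L, 6), g2 = c(5L, 6L, 7L, 50L, 60L, 70L))
  colnames(x) <- paste0("s", 1:6)
  Q <- toy_count_matrix(x, condition = rep(c("control", "drought"), each = 3))
  res <- nb_contrast(Q, contrast_spec("c", paste0("s", 1:3), paste0("s", 4:6)))
  expect_equal(res$log2fc[res$gene == "g1"], 0)
  expect_equal(res$pvalue[res$gene == "g1"], 1)
  expect_true(is.na(res$se[res$gene == "g1"]))
})

test_that("the six standard contrasts carry the stated conventions", {
  truth <- generate_truth(150, seed = 5)
  sim <- simulate_counts(truth, seed = 5)
  qa <- length_normalize(sim$E_A, sim$lengths_A, sim$samples_A)
  qb <- length_normalize(sim$E_B, sim$lengths_B, sim$samples_B)
  map <- structure(list(pairs = truth[, c("gene_A", "gene_B")],
                        unpaired_A = character(0),
                        unpaired_B = character(0)), class = "ortholog_map")
  joint <- pair_by_orthologs(qa, qb, map)
  ct <- run_standard_contrasts(joint)
  expect_named(ct, c("A", "B", "C", "D", "E", "F"))
  # planted shared-up genes rise in both within-species contrasts
  up <- truth$gene_A[truth$model == "shared" & truth$case == 1]
  expect_true(all(ct$A$log2fc[ct$A$gene %in% up] > 1))
  expect_true(all(ct$B$log2fc[ct$B$gene %in% up] > 1))
  # no-response case 1 has a positive baseline contrast (B above A)
  nr1 <- truth$gene_A[truth$model == "no_response" & truth$case == 1]
  expect_true(mean(ct$C$log2fc[ct$C$gene %in% nr1] > 1) > 0.9)
  bundle <- contrast_bundle(ct)
  expect_equal(nrow(bundle), nrow(joint$counts))
  expect_true(all(c("sigA", "lfcA", "sigF", "lfcF") %in% names(bundle)))
})
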