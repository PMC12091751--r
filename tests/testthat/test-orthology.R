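test_that("hit tables parse with field mapping, flags and errors", {
  tf <- withr::local_tempfile()
  writeLines(c("g1\tg2\t90.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\t200",
               "g3\tg3\t100\t80\t0\t0\t1\t80\t1\t80\t1e-60\t300"), tf)
  hits <- parse_hit_table(tf)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$query_id[1], "g1")
  expect_equal(hits$subject_id[1], "g2")
  expect_equal(hits$evalue[1], 1e-50)
  expect_equal(hits$bitscore[1], 200)
  expect_equal(hits$self_hit, c(FALSE, TRUE))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(parse_hit_table(empty)), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("g1\tg2\t90.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\t200",
               paste(rep("x", 11), collapse = "\t")), bad)
  expect_error(parse_hit_table(bad), "line 2")

  nonnum <- withr::local_tempfile()
  writeLines("g1\tg2\tninety\t100\t5\t1\t1\t100\t1\t100\t1e-50\t200", nonnum)
  expect_error(parse_hit_table(nonnum), "non-numeric")
})

test_that("best hit maximizes bitscore with evalue then lexicographic ties", {
  mk <- function(s, e, b) data.frame(
    query_id = rep("q", length(s)), subject_id = s,
    percent_identity = rep(80, length(s)), length = rep(100, length(s)),
    mismatch = rep(0L, length(s)), gapopen = rep(0L, length(s)),
    qstart = rep(1L, length(s)), qend = rep(100L, length(s)),
    sstart = rep(1L, length(s)), send = rep(100L, length(s)),
    evalue = e, bitscore = b, stringsAsFactors = FALSE)
  expect_equal(best_hit(mk(c("a", "b"), c(1e-10, 1e-10), c(100, 200)), "q"), "b")
  expect_equal(best_hit(mk(c("a", "b"), c(1e-30, 1e-40), c(100, 100)), "q"), "b")
  expect_equal(best_hit(mk(c("a", "b"), c(1e-30, 1e-30), c(100, 100)), "q"), "a")
  expect_true(is.na(best_hit(mk(character(0), numeric(0), numeric(0)), "q")))
})

test_that("reciprocal best pairs form and asymmetry is excluded", {
  mk <- function(q, s, b) data.frame(
    query_id = q, subject_id = s, percent_identity = 80, length = 100,
    mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 1e-30, bitscore = b, stringsAsFactors = FALSE)
  # a1 <-> b1 reciprocal; a2's best is b1 but b1 points back to a1
  ab <- mk(c("a1", "a2"), c("b1", "b1"), c(200, 150))
  ba <- mk("b1", "a1", 200)
  map <- best_bidirectional_hits(ab, ba)
  expect_equal(map$pairs, data.frame(gene_A = "a1", gene_B = "b1",
                                     stringsAsFactors = FALSE))
  expect_true("a2" %in% map$unpaired_A)
  expect_error(best_bidirectional_hits(ab, mk("a1", "b1", 100)),
               "both hit tables")
})

test_that("reciprocal best pairs match the brute-force oracle on random tables", {
  for (seed in 1:5) {
    tabs <- random_hit_tables(20, 20, seed)
    map <- best_bidirectional_hits(tabs$ab, tabs$ba)
    oracle <- oracle_bbh_pairs(tabs$ab, tabs$ba)
    got <- map$pairs
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("pairing is symmetric under species swap", {
  tabs <- random_hit_tables(15, 15, 42)
  m1 <- best_bidirectional_hits(tabs$ab, tabs$ba)
  m2 <- best_bidirectional_hits(tabs$ba, tabs$ab)
  k1 <- paste(m1$pairs$gene_A, m1$pairs$gene_B)
  k2 <- paste(m2$pairs$gene_B, m2$pairs$gene_A)
  expect_setequal(k1, k2)
  expect_lte(nrow(m1$pairs), min(length(unique(tabs$ab$query_id)),
                                 length(unique(tabs$ba$query_id))))
})

test_that("symbols transfer to both pair members and tolerate missing hits", {
  mk <- function(q, s, b) data.frame(
    query_id = q, subject_id = s, percent_identity = 80, length = 100,
    mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 1e-30, bitscore = b, stringsAsFactors = FALSE)
  map <- best_bidirectional_hits(mk(c("a1", "a2"), c("b1", "b2"), c(200, 200)),
                                 mk(c("b1", "b2"), c("a1", "a2"), c(200, 200)))
  # a1 hits the reference; a2 has no reference hit; two queries may share a
  # symbol
  ref <- mk(c("a1", "a1"), c("AT1G01010", "AT9G9"), c(300, 100))
  map <- assign_symbols(map, ref)
  expect_equal(unname(map$symbols["a1"]), "AT1G01010")
  expect_equal(map$pairs$symbol[map$pairs$gene_A == "a1"], "AT1G01010")
  expect_true(is.na(map$pairs$symbol[map$pairs$gene_A == "a2"]))
})

test_that("ortholog maps round-trip through the TSV writer", {
  tabs <- random_hit_tables(10, 10, 7)
  map <- best_bidirectional_hits(tabs$ab, tabs$ba)
  out <- withr::local_tempfile()
  write_ortholog_map(map, out)
  back <- utils::read.table(out, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back$gene_A, map$pairs$gene_A)
  expect_equal(back$gene_B, map$pairs$gene_B)
  expect_equal(readLines(paste0(out, ".unpaired_A.txt")), map$unpaired_A)
})

test_that("synthetic hit tables encode the planted map, decoys behave", {
  truth <- generate_truth(60, seed = 3)
  sim <- simulate_annotations_and_hits(truth, decoy_rate = 0, seed = 3)
  map <- best_bidirectional_hits(sim$hits_ab, sim$hits_ba)
  expect_equal(map$pairs$gene_A, truth$gene_A)
  expect_equal(map$pairs$gene_B, truth$gene_B)

  # weaker decoys leave the map intact
  sim2 <- simulate_annotations_and_hits(truth, decoy_rate = 0.3, seed = 4)
  map2 <- best_bidirectional_hits(sim2$hits_ab, sim2$hits_ba)
  expect_equal(map2$pairs$gene_A, truth$gene_A)

  # a decoy outscoring the true reciprocal hit breaks that pair
  sim3 <- simulate_annotations_and_hits(truth, decoy_rate = 0, seed = 3)
  strong <- sim3$hits_ab[1, ]
  strong$subject_id <- truth$gene_B[2]
  strong$bitscore <- strong$bitscore + 1000
  map3 <- best_bidirectional_hits(rbind(sim3$hits_ab, strong), sim3$hits_ba)
  expect_false(truth$gene_A[1] %in% map3$pairs$gene_A)
})
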