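test_that("pwm construction validates probabilities", {
  m <- matrix(0.25, 4, 3)
  expect_s3_class(pwm("ok", m), "pwm")
  bad <- m; bad[1, 1] <- 0.5
  expect_error(pwm("bad", bad), "sum to 1")
  expect_error(pwm("bg", m, background = c(0.5, 0.5, 0.5, 0.5)), "background")
})

test_that("MEME minimal files round-trip", {
  pwms <- make_motif_library(c("TF01", "TF02"), width = 6, seed = 1)
  path <- withr::local_tempfile()
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_named(back, names(pwms))
  for (id in names(pwms)) {
    expect_equal(unname(back[[id]]$matrix), unname(pwms[[id]]$matrix),
                 tolerance = 1e-5)
    expect_equal(back[[id]]$tf_id, pwms[[id]]$tf_id)
    expect_equal(unname(back[[id]]$background), unname(pwms[[id]]$background),
                 tolerance = 1e-5)
  }
})

test_that("promoter extraction follows strand-aware upstream arithmetic", {
  set.seed(3)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(ctg1 = contig))
  coords <- data.frame(
    contig = "ctg1", start = c(3000, 500, 1), end = c(3500, 900, 3000),
    gene = c("plus", "clipped", "minus"), score = 0,
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  prom <- extract_promoters(genome, coords)
  expect_equal(as.character(prom[["plus"]]), substr(contig, 1000, 2999))
  expect_equal(unname(nchar(as.character(prom[["clipped"]]))), 499L)
  expect_equal(as.character(prom[["clipped"]]), substr(contig, 1, 499))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 3001, 5000))))
  expect_equal(as.character(prom[["minus"]]), rc)
  expect_error(extract_promoters(genome, transform(coords, contig = "nope")),
               "unknown contig")
  # a gene flush against the contig start has no promoter
  flush <- data.frame(contig = "ctg1", start = 1, end = 100, gene = "flush",
                      score = 0, strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- extract_promoters(genome, flush), "empty promoters")
  expect_equal(length(out), 0L)
})

test_that("a width-1 consensus column scores 2 bits with p = 0.25", {
  p1 <- pwm("w1", matrix(c(1, 0, 0, 0), 4, 1))
  nd <- pwm_exact_pvalues(p1)
  top <- nd[nrow(nd), ]
  expect_equal(top$score_bits, 2)
  expect_equal(top$p, 0.25)
  hits <- scan_motif(p1, c(g1 = "AACT"), p_threshold = 0.25, q_threshold = NA)
  # every A on either strand: offsets 0,1 on + and the T at offset 3 on -
  expect_equal(sum(hits$strand == "+"), 2L)
  expect_equal(sum(hits$strand == "-"), 1L)
  expect_true(all(hits$p == 0.25))
})

test_that("a one-hot width-4 consensus matches the 256-word enumeration", {
  m <- matrix(0, 4, 4)
  m[cbind(c(1, 2, 3, 4), 1:4)] <- 1  # consensus ACGT
  p <- pwm("acgt", m)
  nd <- pwm_exact_pvalues(p)
  top <- nd[nrow(nd), ]
  expect_equal(top$score_bits, 8)
  expect_equal(top$p, 1 / 256)
  oracle <- oracle_score_tail(p)
  expect_equal(oracle$p[oracle$score_int == top$score_int], top$p)
})

test_that("exact-p dynamic programme equals exhaustive enumeration", {
  set.seed(5)
  for (w in 3:4) {
    m <- matrix(stats::rgamma(4 * w, 1), 4, w)
    m <- sweep(m, 2, colSums(m), "/")
    p <- pwm(paste0("r", w), m, background = c(0.3, 0.2, 0.2, 0.3))
    nd <- pwm_exact_pvalues(p)
    oracle <- oracle_score_tail(p)
    idx <- match(oracle$score_int, nd$score_int)
    expect_false(anyNA(idx))
    expect_lt(max(abs(nd$p[idx] - oracle$p)), 1e-9)
  }
})

test_that("reverse-complementing a promoter flips strands and mirrors offsets", {
  pwms <- make_motif_library("TF01", width = 10, seed = 6)
  p <- pwms[[1]]
  set.seed(7)
  seqs <- c(g1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                       collapse = ""))
  # plant one consensus instance
  cons <- paste(c("A", "C", "G", "T")[apply(p$matrix, 2, which.max)],
                collapse = "")
  substr(seqs[["g1"]], 101, 110) <- cons
  h_f <- scan_motif(p, seqs, q_threshold = NA)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs[["g1"]])))
  h_r <- scan_motif(p, c(g1 = rc), q_threshold = NA)
  expect_equal(nrow(h_f), nrow(h_r))
  L <- nchar(seqs[["g1"]]); w <- pwm_width(p)
  key_f <- paste(h_f$offset, h_f$strand)
  key_r <- paste(L - w - h_r$offset,
                 ifelse(h_r$strand == "+", "-", "+"))
  expect_setequal(key_f, key_r)
  expect_equal(sort(h_f$p), sort(h_r$p))
})

test_that("positions containing unknown bases are skipped", {
  pwms <- make_motif_library("TF01", width = 8, seed = 8)
  p <- pwms[[1]]
  cons <- paste(c("A", "C", "G", "T")[apply(p$matrix, 2, which.max)],
                collapse = "")
  clean <- paste0(strrep("A", 50), cons, strrep("C", 50))
  broken <- clean
  substr(broken, 53, 53) <- "N"  # inside the planted instance
  h_clean <- scan_motif(p, c(g = clean), q_threshold = NA)
  h_broken <- scan_motif(p, c(g = broken), q_threshold = NA)
  expect_true(50 %in% h_clean$offset)
  expect_false(50 %in% h_broken$offset)
  expect_lt(attr(h_broken, "n_scanned"), attr(h_clean, "n_scanned"))
})

test_that("motif presence collapses hits per gene and motif", {
  hits <- data.frame(motif_id = c("m1", "m1", "m2"),
                     gene = c("g1", "g1", "g2"),
                     offset = c(1L, 5L, 7L), strand = "+",
                     score = 10, p = 1e-6, q = 0.01,
                     stringsAsFactors = FALSE)
  pres <- motif_presence(hits, c("g1", "g2", "g3"), c("m1", "m2"))
  expect_equal(sum(pres), 2L)
  expect_true(pres["g1", "m1"])
  expect_true(pres["g2", "m2"])
  empty <- motif_presence(hits[0, ], c("g1", "g2"), c("m1"))
  expect_false(any(empty))
})

test_that("group enrichment has the closed-form tail and degenerate cases", {
  genes <- sprintf("g%03d", 1:110)
  pres <- matrix(FALSE, 110, 2, dimnames = list(genes, c("m1", "m2")))
  pres[1:10, "m1"] <- TRUE  # only the group carries m1; m2 is absent
  res <- motif_group_enrichment(genes[1:10], genes[11:110], pres)
  expect_equal(res$p[res$motif_id == "m1"], 1 / choose(110, 10),
               tolerance = 1e-12)
  expect_equal(res$p[res$motif_id == "m2"], 1)
  # identical presence rates carry no signal
  pres2 <- matrix(FALSE, 100, 1, dimnames = list(genes[1:100], "m1"))
  pres2[seq(1, 100, by = 2), 1] <- TRUE
  res2 <- motif_group_enrichment(genes[1:20], genes[21:100], pres2)
  expect_gte(res2$p, 0.5)
  expect_error(motif_group_enrichment(character(0), genes, pres), "empty")
  expect_error(motif_group_enrichment(genes[1:5], genes[3:10], pres),
               "overlap")
})

test_that("random-set controls reproduce and flag one-off enrichments", {
  set.seed(30)
  genes <- sprintf("g%04d", 1:400)
  pres <- matrix(stats::runif(400 * 20) < 0.3, 400, 20,
                 dimnames = list(genes, sprintf("m%02d", 1:20)))
  c1 <- random_set_control(c(60, 120), pres, reps = 3, seed = 5)
  c2 <- random_set_control(c(60, 120), pres, reps = 3, seed = 5)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$tests), 2 * 3 * 20)
  counts <- stats::aggregate(enriched ~ group_size + motif_id, c1$tests, sum)
  expect_setequal(
    paste(c1$inconsistent$group_size, c1$inconsistent$motif_id),
    paste(counts$group_size, counts$motif_id)[counts$enriched == 1])
})

test_that("planted instances are recovered at their planted coordinates", {
  pwms <- make_motif_library(c("TF01", "TF02"), seed = 11)
  genes <- sprintf("g%02d", 1:40)
  planting <- data.frame(tf = rep(c("TF01", "TF02"), each = 8),
                         target = genes[1:16], stringsAsFactors = FALSE)
  sp <- simulate_promoters_and_motifs(genes, pwms, planting, seed = 11)
  prom <- extract_promoters(sp$genome, sp$coords)
  expect_equal(as.character(prom), as.character(sp$promoters)[names(prom)])
  hits <- scan_motifs(pwms, prom)
  merged <- merge(sp$planted_offsets, hits,
                  by.x = c("target", "offset", "strand"),
                  by.y = c("gene", "offset", "strand"))
  # most planted instances are found exactly where they were inserted
  expect_gte(nrow(merged), 0.6 * nrow(planting))
  # and background genes carry almost nothing
  pres <- motif_presence(hits, genes, names(pwms))
  expect_lte(sum(pres[17:40, ]), 2)
})
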