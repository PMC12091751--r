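# Independent oracles, deliberately written as flat conditionals / explicit
# loops so they share no code path with the implementation they check.

# Flat-conditional expression-model oracle: each of the fifteen cases is a
# standalone boolean over the five contrasts; exactly one must fire.
oracle_classify <- function(sigA, sigB, sigC, sigE, sigF, lfcA, lfcB, lfcC) {
  sr1 <- !sigA & sigB & lfcB > 0 & !sigE & sigC & lfcC < 0
  sr2 <- !sigA & sigB & lfcB <= 0 & !sigE & sigC & lfcC > 0
  sr3 <- sigA & !sigB & lfcA > 0 & !sigF & sigC & lfcC > 0
  sr4 <- sigA & !sigB & lfcA <= 0 & !sigF & sigC & lfcC < 0
  cases <- list(
    shared_1 = sigA & sigB & lfcA > 0 & lfcB > 0,
    shared_2 = sigA & sigB & lfcA <= 0 & lfcB <= 0,
    opposite_1 = sigA & sigB & lfcA > 0 & lfcB <= 0,
    opposite_2 = sigA & sigB & lfcA <= 0 & lfcB > 0,
    stress_ready_1 = sr1,
    stress_ready_2 = sr2,
    stress_ready_3 = sr3,
    stress_ready_4 = sr4,
    unique_1 = sigA & !sigB & lfcA > 0 & !sr3,
    unique_2 = sigA & !sigB & lfcA <= 0 & !sr4,
    unique_3 = !sigA & sigB & lfcB > 0 & !sr1,
    unique_4 = !sigA & sigB & lfcB <= 0 & !sr2,
    no_response_1 = !sigA & !sigB & sigC & lfcC > 0,
    no_response_2 = !sigA & !sigB & sigC & lfcC <= 0,
    no_response_3 = !sigA & !sigB & !sigC)
  fired <- names(cases)[vapply(cases, isTRUE, logical(1))]
  if (length(fired) != 1L)
    stop("oracle fired ", length(fired), " cases")
  list(model = sub("_[0-9]+$", "", fired),
       case = as.integer(sub("^.*_", "", fired)))
}

# Full grid of significance patterns x log2fc signs for the five contrasts.
classifier_truth_table <- function(lfc_values = c(-1.5, 0, 1.5)) {
  expand.grid(sigA = c(TRUE, FALSE), sigB = c(TRUE, FALSE),
              sigC = c(TRUE, FALSE), sigE = c(TRUE, FALSE),
              sigF = c(TRUE, FALSE), lfcA = lfc_values, lfcB = lfc_values,
              lfcC = lfc_values, KEEP.OUT.ATTRS = FALSE)
}

# Sequential-scan best hit (max bitscore, then min evalue, then smallest
# subject id), independent of the radix-order implementation.
oracle_best_hit <- function(hits, q) {
  rows <- hits[hits$query_id == q, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_character_)
  best <- 1L
  for (i in seq_len(nrow(rows))[-1]) {
    better <- rows$bitscore[i] > rows$bitscore[best] ||
      (rows$bitscore[i] == rows$bitscore[best] &&
         rows$evalue[i] < rows$evalue[best]) ||
      (rows$bitscore[i] == rows$bitscore[best] &&
         rows$evalue[i] == rows$evalue[best] &&
         rows$subject_id[i] < rows$subject_id[best])
    if (better) best <- i
  }
  rows$subject_id[best]
}

# O(n^2) brute-force reciprocal-best pairs.
oracle_bbh_pairs <- function(hits_ab, hits_ba) {
  pairs <- list()
  for (a in unique(hits_ab$query_id)) {
    b <- oracle_best_hit(hits_ab, a)
    if (is.na(b)) next
    back <- oracle_best_hit(hits_ba, b)
    if (!is.na(back) && back == a)
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0L)
    return(data.frame(gene_A = character(0), gene_B = character(0)))
  m <- do.call(rbind, pairs)
  out <- data.frame(gene_A = m[, 1], gene_B = m[, 2],
                    stringsAsFactors = FALSE)
  out[order(out$gene_A), , drop = FALSE]
}

# Random dense hit tables between two gene sets (integer bitscores from a
# small range so ties occur).
random_hit_tables <- function(n_a, n_b, seed) {
  set.seed(seed)
  ga <- sprintf("a%02d", seq_len(n_a))
  gb <- sprintf("b%02d", seq_len(n_b))
  mk <- function(q, s) {
    grid <- expand.grid(query_id = q, subject_id = s,
                        stringsAsFactors = FALSE)
    data.frame(grid,
               percent_identity = 80, length = 100, mismatch = 0,
               gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
               evalue = sample(c(1e-50, 1e-40, 1e-30), nrow(grid), TRUE),
               bitscore = sample(90:110, nrow(grid), TRUE),
               stringsAsFactors = FALSE)
  }
  list(ab = mk(ga, gb), ba = mk(gb, ga))
}

# Enumerate all 4^w words and accumulate background-weighted tail
# probabilities of the discretized log-odds score (independent of the DP).
oracle_score_tail <- function(p, score_step = 0.001) {
  m <- p$matrix
  bg <- p$background
  w <- ncol(m)
  S <- log2(m / bg)
  S[is.finite(S)] <- round(S[is.finite(S)] / score_step)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    sc[i] <- sum(S[cbind(words[i, ], seq_len(w))])
    pr[i] <- prod(bg[words[i, ]])
  }
  fin <- is.finite(sc)
  tapply_scores <- sort(unique(sc[fin]))
  tail_p <- vapply(tapply_scores,
                   function(s) sum(pr[fin & sc >= s]), numeric(1))
  data.frame(score_int = tapply_scores, p = tail_p)
}

# A quick two-species count matrix for unit tests.
toy_count_matrix <- function(counts, species = "A",
                             condition = rep(c("control", "drought"),
                                             each = ncol(counts) / 2)) {
  samples <- data.frame(sample_id = colnames(counts), species = species,
                        condition = condition,
                        replicate = seq_len(ncol(counts)),
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}
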