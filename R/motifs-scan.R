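# PWM promoter scanning with exact p-values, and motif enrichment.
#
# Every promoter position (both strands) is scored as the log-odds
# sum_j log2(pwm[b_j, j] / bg[b_j]) in bits. Column scores are discretized to
# a fixed step (default 1e-3 bits) and the exact null distribution of the
# total score under the background model is obtained by dynamic programming
# (column-wise convolution), giving an exact p-value P(score >= observed) for
# every position. q-values are Benjamini-Hochberg over all scanned positions
# of the motif, computed from the tally of discretized scores (an exact,
# memory-light equivalent of BH over the per-position p-value list). Reported
# hits satisfy p <= p_threshold and q < q_threshold.

# Integer (discretized) log-odds score matrix; zero motif probabilities score
# -Inf (such letters can never contribute to a hit).
pwm_int_scores <- function(p, score_step = 0.001) {
  m <- p$matrix
  bg <- p$background
  if (any(bg == 0 & apply(m > 0, 1, any)))
    stopf("pwm '%s': zero background probability with nonzero motif probability; add a pseudocount to the background",
          p$motif_id)
  s <- log2(sweep(m, 1, bg, "/"))  # -Inf where m == 0
  s[is.finite(s)] <- round(s[is.finite(s)] / score_step)
  s
}

#' Exact null distribution of a PWM's log-odds score
#'
#' Dynamic programme over the discretized per-column score distribution under
#' the background model: the exact probability of every achievable total
#' score for a random background word, and the tail `p = P(score >= s)`.
#'
#' @param p A `pwm`.
#' @param score_step Discretization step in bits (default 1e-3).
#' @return Data frame `score_int` (discretized units), `score_bits`, `prob`,
#'   `p` (upper tail); the probability mass of words containing a
#'   zero-probability letter (score -Inf) is carried in
#'   `attr(, "minus_inf_mass")`.
#' @export
pwm_exact_pvalues <- function(p, score_step = 0.001) {
  S <- pwm_int_scores(p, score_step)
  bg <- p$background
  probs <- 1
  offset <- 0L  # probs[i] = P(total == offset + i - 1)
  for (j in seq_len(ncol(S))) {
    sj <- S[, j]
    fin <- is.finite(sj)
    smin <- min(sj[fin]); smax <- max(sj[fin])
    new <- numeric(length(probs) + (smax - smin))
    for (b in which(fin)) {
      sh <- sj[b] - smin
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new
    offset <- offset + as.integer(smin)
  }
  tail_p <- rev(cumsum(rev(probs)))
  out <- data.frame(score_int = offset + seq_along(probs) - 1L,
                    prob = probs, p = pmin(tail_p, 1))
  out$score_bits <- out$score_int * score_step
  out <- out[, c("score_int", "score_bits", "prob", "p")]
  attr(out, "minus_inf_mass") <- 1 - sum(probs)
  out
}

# Map DNA characters to codes 1..4 (A C G T); anything else is NA.
dna_codes <- local({
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  function(seq_chr) lut[utf8ToInt(seq_chr)]
})

# Score every start position of a coded sequence against an integer score
# matrix; positions touching an unknown base (NA code) come back NA.
score_positions <- function(code, S) {
  w <- ncol(S)
  npos <- length(code) - w + 1L
  if (npos < 1L) return(numeric(0))
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    col <- S[, j]
    # NA codes (unknown bases) index to NA and propagate through the sum
    sc <- sc + col[code[j:(j + npos - 1L)]]
  }
  sc
}

#' Scan promoters with a PWM
#'
#' Scores every position of every promoter on both strands, attaches the
#' exact background p-value of each score, and applies the p- and q-value
#' thresholds. Positions containing an unknown base (N) are skipped.
#' Promoters shorter than the motif are dropped with a warning.
#'
#' @param p A `pwm`.
#' @param promoters A `DNAStringSet` (or named character vector) of promoter
#'   sequences named by gene.
#' @param p_threshold Raw p-value cutoff for candidate hits (default 1e-4).
#' @param q_threshold BH q-value cutoff for reported hits (default 0.05);
#'   `NA` disables the q filter.
#' @param score_step Discretization step in bits.
#' @return Data frame of hits: `motif_id`, `gene`, `offset` (0-based on the
#'   promoter's forward representation), `strand`, `score` (bits), `p`, `q`.
#'   `attr(, "n_scanned")` records the number of scanned positions.
#' @export
scan_motif <- function(p, promoters, p_threshold = 1e-4, q_threshold = 0.05,
                       score_step = 0.001) {
  if (inherits(promoters, "DNAStringSet"))
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  if (length(promoters) == 0L) stopf("no promoters to scan")
  S <- pwm_int_scores(p, score_step)
  w <- ncol(S)
  # minus strand == plus strand scored with the reverse-complemented matrix
  S_rc <- S[4:1, w:1, drop = FALSE]
  null_dist <- pwm_exact_pvalues(p, score_step)
  pmap_min <- null_dist$score_int[1]
  pmap <- null_dist$p
  p_of <- function(s) ifelse(is.na(s) | !is.finite(s), 1,
                             pmap[pmax(1, s - pmap_min + 1)])
  short <- nchar(promoters) < w
  if (any(short)) {
    warnf("dropping %d promoter(s) shorter than the motif width (%d)",
          sum(short), w)
    promoters <- promoters[!short]
  }
  hit_rows <- vector("list", length(promoters))
  # tally of discretized scores over all scanned positions (for BH)
  tally <- new.env(parent = emptyenv())
  tally$counts <- numeric(nrow(null_dist))
  tally$n_inf <- 0
  add_tally <- function(sc) {
    fin <- sc[!is.na(sc)]
    tally$n_inf <- tally$n_inf + sum(!is.finite(fin))
    fin <- fin[is.finite(fin)]
    if (length(fin) > 0L) {
      tb <- tabulate(fin - pmap_min + 1L, nbins = length(tally$counts))
      tally$counts <- tally$counts + tb
    }
  }
  for (i in seq_along(promoters)) {
    code <- dna_codes(promoters[[i]])
    sc_f <- score_positions(code, S)
    sc_r <- score_positions(code, S_rc)
    add_tally(sc_f); add_tally(sc_r)
    cand <- function(sc, strand) {
      pv <- p_of(sc)
      sel <- which(!is.na(sc) & is.finite(sc) & pv <= p_threshold)
      if (length(sel) == 0L) return(NULL)
      data.frame(motif_id = p$motif_id, gene = names(promoters)[i],
                 offset = sel - 1L, strand = strand,
                 score = sc[sel] * score_step, score_int = sc[sel],
                 p = pv[sel], stringsAsFactors = FALSE)
    }
    hit_rows[[i]] <- rbind(cand(sc_f, "+"), cand(sc_r, "-"))
  }
  hits <- do.call(rbind, hit_rows)
  n_scanned <- sum(tally$counts) + tally$n_inf
  if (is.null(hits)) {
    hits <- data.frame(motif_id = character(0), gene = character(0),
                       offset = integer(0), strand = character(0),
                       score = numeric(0), p = numeric(0), q = numeric(0),
                       stringsAsFactors = FALSE)
    attr(hits, "n_scanned") <- n_scanned
    return(hits)
  }
  # BH over all scanned positions, grouped by discretized score: for a score
  # with tail p, its BH rank is the count of scanned positions at least as
  # significant (p=1 positions, including -Inf scores, rank last).
  cum_ge <- rev(cumsum(rev(tally$counts)))  # positions with score >= s
  qraw <- pmin(1, pmap * n_scanned / pmax(cum_ge, 1))
  # BH step-up: q at score s is the minimum raw q over all scores s' <= s
  # (i.e., over all p-values at least as large); cumulative minimum along
  # ascending score order.
  qmon <- cummin(qraw)
  hits$q <- qmon[hits$score_int - pmap_min + 1L]
  hits$score_int <- NULL
  if (!is.na(q_threshold)) hits <- hits[hits$q < q_threshold, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_scanned") <- n_scanned
  hits
}

#' Scan promoters with a motif library
#'
#' @param pwms List of `pwm` objects.
#' @param promoters Promoter sequences (see [scan_motif()]).
#' @param ... Passed to [scan_motif()].
#' @return Row-bound hit table across motifs.
#' @export
scan_motifs <- function(pwms, promoters, ...) {
  res <- lapply(pwms, scan_motif, promoters = promoters, ...)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene x motif presence table
#'
#' @param hits Hit table from [scan_motif()]/[scan_motifs()] (already
#'   q-filtered).
#' @param genes All genes to index (rows); presence is FALSE for genes with
#'   no hit.
#' @param motif_ids All motifs to index (columns); defaults to the motifs in
#'   `hits`.
#' @return Logical matrix, genes x motifs: TRUE iff the gene's promoter holds
#'   at least one retained hit of the motif.
#' @export
motif_presence <- function(hits, genes, motif_ids = NULL) {
  if (is.null(motif_ids)) motif_ids <- sort(unique(hits$motif_id))
  out <- matrix(FALSE, length(genes), length(motif_ids),
                dimnames = list(genes, motif_ids))
  keep <- hits$gene %in% genes & hits$motif_id %in% motif_ids
  if (any(keep))
    out[cbind(hits$gene[keep], hits$motif_id[keep])] <- TRUE
  out
}

#' One-tailed Fisher motif enrichment of a gene group
#'
#' Per motif, tests the 2x2 table (in-group with/without the motif vs the
#' rest with/without) for over-representation with the exact one-tailed
#' (greater) test; no multiplicity adjustment is applied, per the design's
#' stated convention.
#'
#' @param group,rest Disjoint character vectors of genes, both indexed in
#'   `presence`.
#' @param presence Logical gene x motif matrix from [motif_presence()].
#' @param p_threshold Significance threshold on the raw p (default 0.05).
#' @return Data frame `motif_id`, `group_with`, `group_size`, `rest_with`,
#'   `rest_size`, `p`, `enriched`.
#' @export
motif_group_enrichment <- function(group, rest, presence, p_threshold = 0.05) {
  if (length(group) == 0L) stopf("empty group")
  if (length(intersect(group, rest)) > 0L) stopf("group and rest overlap")
  a <- colSums(presence[group, , drop = FALSE])
  c_ <- colSums(presence[rest, , drop = FALSE])
  n_g <- length(group); n_r <- length(rest)
  # one-tailed greater: P(X >= a), X ~ Hypergeom(N = n_g + n_r, K = a + c_,
  # draws = n_g)
  p <- stats::phyper(a - 1, a + c_, (n_g - a) + (n_r - c_), n_g,
                     lower.tail = FALSE)
  data.frame(motif_id = colnames(presence), group_with = as.integer(a),
             group_size = n_g, rest_with = as.integer(c_), rest_size = n_r,
             p = unname(p), enriched = unname(p) < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random-gene negative control for motif enrichment
#'
#' Draws random gene groups of matched sizes and reruns
#' [motif_group_enrichment()] against the complement; motifs significant in
#' exactly one of the replicates (the hallmark of inconsistent, chance
#' enrichment) are reported separately.
#'
#' @param group_sizes Integer vector of group sizes to emulate.
#' @param presence Logical gene x motif matrix.
#' @param reps Replicates (default 3).
#' @param seed Seed for the draws.
#' @param p_threshold Raw-p significance threshold (default 0.05).
#' @return List with `tests` (rep, group_size, motif_id, p, enriched) and
#'   `inconsistent` (group_size, motif_id significant in exactly one rep).
#' @export
random_set_control <- function(group_sizes, presence, reps = 3, seed = NULL,
                               p_threshold = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(presence)
  rows <- list()
  for (r in seq_len(reps)) {
    for (gs in group_sizes) {
      grp <- sample(genes, gs)
      res <- motif_group_enrichment(grp, setdiff(genes, grp), presence,
                                    p_threshold)
      res$rep <- r
      res$group_size <- gs
      rows[[length(rows) + 1L]] <- res[, c("rep", "group_size", "motif_id",
                                           "p", "enriched")]
    }
  }
  tests <- do.call(rbind, rows)
  agg <- stats::aggregate(enriched ~ group_size + motif_id, tests, sum)
  inconsistent <- agg[agg$enriched == 1L, c("group_size", "motif_id")]
  rownames(inconsistent) <- NULL
  list(tests = tests, inconsistent = inconsistent)
}
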