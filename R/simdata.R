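# Ground-truth synthetic data for the whole pipeline.
#
# The generator emulates every input the analysis consumes: two species x
# {control, drought} x replicate negative-binomial count matrices whose
# per-ortholog mean structure realizes a chosen expression-model case,
# per-species transcript lengths, promoter sequences with planted motif
# instances embedded in synthetic contigs, a MEME-minimal motif library, flat
# gene -> term annotations with planted over-representation, and reciprocal
# alignment hit tables encoding the true ortholog map (with optional weaker
# decoy paralog hits). All randomness flows from one master seed through
# named substreams.

#' Default expression-model case proportions
#'
#' The study conditions this generator emulates: roughly 63% of orthologs
#' show no drought response; responders split about 43% unique, 35% shared,
#' 20% stress-ready (its four cases in the 217:230:570:537 ratio observed in
#' the motivating system) and 2% opposite.
#'
#' @return Named numeric vector over the fifteen `model_case` labels,
#'   summing to 1.
#' @export
default_case_proportions <- function() {
  c(stress_ready_1 = 0.011, stress_ready_2 = 0.012,
    stress_ready_3 = 0.029, stress_ready_4 = 0.028,
    shared_1 = 0.080, shared_2 = 0.060,
    unique_1 = 0.050, unique_2 = 0.040, unique_3 = 0.040, unique_4 = 0.040,
    opposite_1 = 0.005, opposite_2 = 0.005,
    no_response_1 = 0.100, no_response_2 = 0.100, no_response_3 = 0.400)
}

# Group means (A control/drought, B control/drought) realizing one case, from
# a baseline b and fold change f = 2^effect. Exact equalities implement
# "matching" levels; noise supplies the realism.
case_means <- function(model, case, b, f) {
  key <- paste(model, case, sep = "_")
  switch(key,
    shared_1       = c(b, b * f, b, b * f),
    shared_2       = c(b, b / f, b, b / f),
    opposite_1     = c(b, b * f, b, b / f),
    opposite_2     = c(b, b / f, b, b * f),
    unique_1       = c(b, b * f, b, b),
    unique_2       = c(b, b / f, b, b),
    unique_3       = c(b, b, b, b * f),
    unique_4       = c(b, b, b, b / f),
    stress_ready_1 = c(b, b, b / f, b),
    stress_ready_2 = c(b, b, b * f, b),
    stress_ready_3 = c(b, b * f, b * f, b * f),
    stress_ready_4 = c(b, b / f, b / f, b / f),
    no_response_1  = c(b, b, b * f, b * f),
    no_response_2  = c(b, b, b / f, b / f),
    no_response_3  = c(b, b, b, b),
    stopf("unknown case '%s'", key))
}

#' Check that a mean pattern satisfies its claimed case definition
#'
#' Machine-checkable form of each case: e.g., stress-ready case 1 demands
#' `mu_B_drought == mu_A_control`, an unchanged species A, and a lower
#' species-B baseline.
#'
#' @param model,case Model name and case number.
#' @param mu Numeric length-4 vector: A control, A drought, B control,
#'   B drought.
#' @return TRUE if the pattern is valid, otherwise FALSE.
#' @export
validate_case_pattern <- function(model, case, mu) {
  ac <- mu[1]; ad <- mu[2]; bc <- mu[3]; bd <- mu[4]
  eq <- function(x, y) isTRUE(all.equal(x, y, tolerance = 1e-9))
  key <- paste(model, case, sep = "_")
  switch(key,
    shared_1       = ad > ac && bd > bc,
    shared_2       = ad < ac && bd < bc,
    opposite_1     = ad > ac && bd < bc,
    opposite_2     = ad < ac && bd > bc,
    unique_1       = ad > ac && eq(bd, bc),
    unique_2       = ad < ac && eq(bd, bc),
    unique_3       = eq(ad, ac) && bd > bc,
    unique_4       = eq(ad, ac) && bd < bc,
    stress_ready_1 = eq(ad, ac) && bd > bc && eq(bd, ac),
    stress_ready_2 = eq(ad, ac) && bd < bc && eq(bd, ac),
    stress_ready_3 = ad > ac && eq(bd, bc) && eq(ad, bc),
    stress_ready_4 = ad < ac && eq(bd, bc) && eq(ad, bc),
    no_response_1  = eq(ad, ac) && eq(bd, bc) && bc > ac,
    no_response_2  = eq(ad, ac) && eq(bd, bc) && bc < ac,
    no_response_3  = eq(ad, ac) && eq(bd, bc) && eq(bc, ac),
    stopf("unknown case '%s'", key))
}

#' Generate per-ortholog ground truth
#'
#' Assigns each ortholog a (model, case) by multinomial draw and realizes the
#' case's mean pattern from a log-uniform baseline and a fixed log2 effect
#' size. Every record's pattern is validated against its case definition
#' before being returned.
#'
#' @param n Number of orthologs.
#' @param case_proportions Named proportions over the fifteen cases
#'   (must sum to 1; see [default_case_proportions()]).
#' @param effect Planted |log2 fold change| (default 2).
#' @param baseline_range Baseline mean range, drawn log-uniformly
#'   (default 50-500).
#' @param dispersion NB dispersion alpha (default 0.05).
#' @param seed Seed.
#' @return Data frame: `ortholog`, `gene_A`, `gene_B`, `model`, `case`,
#'   `mu_A_control`, `mu_A_drought`, `mu_B_control`, `mu_B_drought`,
#'   `dispersion`.
#' @export
generate_truth <- function(n, case_proportions = default_case_proportions(),
                           effect = 2, baseline_range = c(50, 500),
                           dispersion = 0.05, seed = 1) {
  if (any(case_proportions < 0)) stopf("negative case proportions")
  if (abs(sum(case_proportions) - 1) > 1e-9)
    stopf("case proportions must sum to 1")
  if (n == 0L) {
    return(data.frame(ortholog = character(0), gene_A = character(0),
                      gene_B = character(0), model = character(0),
                      case = integer(0), mu_A_control = numeric(0),
                      mu_A_drought = numeric(0), mu_B_control = numeric(0),
                      mu_B_drought = numeric(0), dispersion = numeric(0)))
  }
  set.seed(derive_seed(seed, "truth"))
  keys <- sample(names(case_proportions), n, replace = TRUE,
                 prob = case_proportions)
  b <- exp(stats::runif(n, log(baseline_range[1]), log(baseline_range[2])))
  f <- 2^effect
  model <- sub("_[0-9]+$", "", keys)
  case <- as.integer(sub("^.*_", "", keys))
  mus <- t(mapply(function(m, cs, bi) case_means(m, cs, bi, f),
                  model, case, b))
  ok <- mapply(validate_case_pattern, model, case,
               split(mus, row(mus)))
  if (!all(ok)) stopf("internal error: generated pattern violates its case")
  data.frame(ortholog = sprintf("GA%05d", seq_len(n)),
             gene_A = sprintf("GA%05d", seq_len(n)),
             gene_B = sprintf("GB%05d", seq_len(n)),
             model = model, case = case,
             mu_A_control = mus[, 1], mu_A_drought = mus[, 2],
             mu_B_control = mus[, 3], mu_B_drought = mus[, 4],
             dispersion = dispersion, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate expression estimates and transcript lengths from a truth table
#'
#' Counts are NB(mean = s_j * mu, dispersion alpha) with per-sample library
#' factors jittered uniformly around 1. Per-species transcript lengths are
#' drawn independently (log-uniform, default 0.5-10 kb), and the emitted
#' expression estimates are E = Q * L so that length normalization recovers
#' the planted counts while the two species' raw estimates disagree by their
#' ortholog length ratio.
#'
#' @param truth Data frame from [generate_truth()].
#' @param n_reps Replicates per (species, condition), default 5.
#' @param lib_size_jitter Half-width of the uniform library-size factor
#'   jitter (default 0.15).
#' @param length_range_kb Transcript-length range in kb.
#' @param seed Seed.
#' @return List: `E_A`, `E_B` (expression-estimate matrices), `lengths_A`,
#'   `lengths_B` (kb), `samples_A`, `samples_B` (sample tables),
#'   `size_factors_A`, `size_factors_B` (the planted factors).
#' @export
simulate_counts <- function(truth, n_reps = 5, lib_size_jitter = 0.15,
                            length_range_kb = c(0.5, 10), seed = 1) {
  if (n_reps < 2L) stopf("need n_reps >= 2")
  set.seed(derive_seed(seed, "counts"))
  n <- nrow(truth)
  sample_table <- function(sp) {
    data.frame(
      sample_id = paste0(sp, "_", rep(c("control", "drought"), each = n_reps),
                         "_", rep(seq_len(n_reps), 2)),
      species = sp,
      condition = rep(c("control", "drought"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2), stringsAsFactors = FALSE)
  }
  draw_species <- function(mu_c, mu_d, genes) {
    sf <- stats::runif(2 * n_reps, 1 - lib_size_jitter, 1 + lib_size_jitter)
    mu <- cbind(matrix(rep(mu_c, n_reps), ncol = n_reps),
                matrix(rep(mu_d, n_reps), ncol = n_reps))
    mu <- sweep(mu, 2, sf, "*")
    q <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / truth$dispersion),
                nrow = n, dimnames = list(genes, NULL))
    list(q = q, sf = sf)
  }
  a <- draw_species(truth$mu_A_control, truth$mu_A_drought, truth$gene_A)
  b <- draw_species(truth$mu_B_control, truth$mu_B_drought, truth$gene_B)
  samples_A <- sample_table("A"); samples_B <- sample_table("B")
  colnames(a$q) <- samples_A$sample_id
  colnames(b$q) <- samples_B$sample_id
  lengths_A <- stats::setNames(
    exp(stats::runif(n, log(length_range_kb[1]), log(length_range_kb[2]))),
    truth$gene_A)
  lengths_B <- stats::setNames(
    exp(stats::runif(n, log(length_range_kb[1]), log(length_range_kb[2]))),
    truth$gene_B)
  list(E_A = a$q * lengths_A, E_B = b$q * lengths_B,
       lengths_A = lengths_A, lengths_B = lengths_B,
       samples_A = samples_A, samples_B = samples_B,
       size_factors_A = a$sf, size_factors_B = b$sf)
}

#' Build a library of near-consensus motifs
#'
#' Each motif has one dominant base per column (probability
#' 1 - 3 * leak) and is attached to one TF gene.
#'
#' @param tf_ids TF gene ids, one motif each.
#' @param width Motif width (default 12).
#' @param leak Probability assigned to each non-consensus base per column
#'   (default 0.02).
#' @param background Background base probabilities.
#' @param seed Seed.
#' @return Named list of `pwm` objects (names `M_<tf>`).
#' @export
make_motif_library <- function(tf_ids, width = 12, leak = 0.01,
                               background = rep(0.25, 4), seed = 1) {
  set.seed(derive_seed(seed, "motifs"))
  out <- list()
  for (tf in tf_ids) {
    cons <- sample(4, width, replace = TRUE)
    m <- matrix(leak, 4, width)
    m[cbind(cons, seq_len(width))] <- 1 - 3 * leak
    id <- paste0("M_", tf)
    out[[id]] <- pwm(id, m, tf_id = tf, background = background)
  }
  out
}

#' Simulate promoters with planted motif instances, inside synthetic contigs
#'
#' Each gene gets an i.i.d. background promoter of `promoter_length` nt; for
#' every planted (tf, target) link one instance sampled from the TF's motif is
#' inserted at a random offset on a random strand. Each promoter is then
#' embedded in a contig with the gene body downstream on a random strand, so
#' promoter extraction is exercised on both strands.
#'
#' @param genes Character vector of gene ids.
#' @param pwms Motif library from [make_motif_library()] (or any `pwm` list).
#' @param planting Data frame with columns `tf` and `target`; the TF's motif
#'   (by `tf_id`) is planted in each target's promoter.
#' @param background Background base probabilities (A, C, G, T).
#' @param promoter_length Promoter length in nt (default 2000).
#' @param body_length Gene-body length in the synthetic contig.
#' @param seed Seed.
#' @return List: `promoters` (`DNAStringSet`), `genome` (`DNAStringSet`),
#'   `coords` (contig, start, end, gene, score, strand), `tf_to_motif`
#'   (data frame), `planted_offsets` (data frame tf, target, offset, strand).
#' @export
simulate_promoters_and_motifs <- function(genes, pwms, planting = NULL,
                                          background = rep(0.25, 4),
                                          promoter_length = 2000,
                                          body_length = 100, seed = 1) {
  set.seed(derive_seed(seed, "promoters"))
  tf_of <- vapply(pwms, function(p) p$tf_id, character(1))
  tf_to_motif <- data.frame(tf = unname(tf_of),
                            motif_id = names(pwms), stringsAsFactors = FALSE)
  widths <- vapply(pwms, pwm_width, integer(1))
  if (any(widths > promoter_length))
    stopf("motif wider than the promoter")
  prom <- vapply(genes, function(g) {
    paste(sample(DNA_BASES, promoter_length, replace = TRUE,
                 prob = background), collapse = "")
  }, character(1))
  offsets <- NULL
  if (!is.null(planting) && nrow(planting) > 0L) {
    unknown_tf <- setdiff(planting$tf, tf_to_motif$tf)
    if (length(unknown_tf) > 0L)
      stopf("planting references TF(s) without a motif: %s",
            paste(utils::head(unknown_tf, 3), collapse = ", "))
    unknown_g <- setdiff(planting$target, genes)
    if (length(unknown_g) > 0L)
      stopf("planting references unknown gene(s): %s",
            paste(utils::head(unknown_g, 3), collapse = ", "))
    rows <- list()
    for (i in seq_len(nrow(planting))) {
      tf <- planting$tf[i]; tgt <- planting$target[i]
      p <- pwms[[tf_to_motif$motif_id[tf_to_motif$tf == tf][1]]]
      w <- pwm_width(p)
      inst <- paste(DNA_BASES[apply(p$matrix, 2, function(col)
        sample(4, 1, prob = col))], collapse = "")
      strand <- sample(c("+", "-"), 1)
      if (strand == "-")
        inst <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(inst)))
      off <- sample.int(promoter_length - w + 1L, 1) - 1L  # 0-based
      substr(prom[[tgt]], off + 1L, off + w) <- inst
      rows[[i]] <- data.frame(tf = tf, target = tgt, offset = off,
                              strand = strand, stringsAsFactors = FALSE)
    }
    offsets <- do.call(rbind, rows)
  }
  gene_strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  contigs <- character(length(genes))
  coords <- data.frame(contig = paste0("ctg_", genes), start = NA_integer_,
                       end = NA_integer_, gene = genes, score = 0,
                       strand = gene_strand, stringsAsFactors = FALSE)
  body <- function() paste(sample(DNA_BASES, body_length, replace = TRUE,
                                  prob = background), collapse = "")
  for (i in seq_along(genes)) {
    if (gene_strand[i] == "+") {
      contigs[i] <- paste0(prom[[i]], body())
      coords$start[i] <- promoter_length + 1L
      coords$end[i] <- promoter_length + body_length
    } else {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(prom[[i]])))
      contigs[i] <- paste0(body(), rc)
      coords$start[i] <- 1L
      coords$end[i] <- body_length
    }
  }
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- coords$contig
  promoters <- Biostrings::DNAStringSet(unname(prom))
  names(promoters) <- genes
  list(promoters = promoters, genome = genome, coords = coords,
       tf_to_motif = tf_to_motif, planted_offsets = offsets)
}

#' Simulate flat annotations and reciprocal alignment hit tables
#'
#' Annotations: each (gene, term) is present with the background probability;
#' an enrichment plan lifts chosen terms to `fold` times that rate inside
#' chosen cases. Hit tables: the true ortholog pairs as mutual best hits,
#' optionally shadowed by weaker decoy paralog hits; a reference table gives
#' every species-A gene a best hit for symbol transfer.
#'
#' @param truth Data frame from [generate_truth()].
#' @param n_terms Number of terms (default 50).
#' @param base_rate Background P(gene has term) (default 0.1, i.e. ~5 terms
#'   per gene at the default `n_terms`).
#' @param enrichment_plan Optional data frame `term`, `model`, `case`,
#'   `fold` (default fold 5).
#' @param decoy_rate Fraction of pairs that also receive a weaker decoy hit.
#' @param seed Seed.
#' @return List: `annotations` (`annotation_table` over gene_A ids),
#'   `hits_ab`, `hits_ba`, `hits_ref` (hit data frames), `symbols_true`
#'   (named vector gene_A -> reference id).
#' @export
simulate_annotations_and_hits <- function(truth, n_terms = 50,
                                          base_rate = 0.1,
                                          enrichment_plan = NULL,
                                          decoy_rate = 0.1, seed = 1) {
  set.seed(derive_seed(seed, "annotations"))
  n <- nrow(truth)
  terms <- sprintf("T%04d", seq_len(n_terms))
  prob <- matrix(base_rate, n, n_terms, dimnames = list(truth$gene_A, terms))
  if (!is.null(enrichment_plan)) {
    for (i in seq_len(nrow(enrichment_plan))) {
      pl <- enrichment_plan[i, ]
      fold <- if (is.null(pl$fold) || is.na(pl$fold)) 5 else pl$fold
      sel <- truth$model == pl$model & truth$case == pl$case
      if (!any(sel)) stopf("enrichment plan references an empty case %s_%s",
                           pl$model, pl$case)
      prob[sel, pl$term] <- pmin(1, fold * base_rate)
    }
  }
  has <- matrix(stats::runif(n * n_terms) < prob, n, n_terms)
  idx <- which(has, arr.ind = TRUE)
  annotations <- annotation_table(data.frame(
    gene = truth$gene_A[idx[, 1]], term = terms[idx[, 2]],
    stringsAsFactors = FALSE))
  hit_row <- function(q, s, bits) {
    data.frame(query_id = q, subject_id = s, percent_identity = 80,
               length = 300, mismatch = 10, gapopen = 1, qstart = 1,
               qend = 300, sstart = 1, send = 300,
               evalue = 2^(-bits / 2), bitscore = bits,
               stringsAsFactors = FALSE)
  }
  bits <- stats::runif(n, 300, 600)
  hits_ab <- hit_row(truth$gene_A, truth$gene_B, bits)
  hits_ba <- hit_row(truth$gene_B, truth$gene_A, bits)
  n_decoy <- round(decoy_rate * n)
  if (n_decoy > 0L && n > 1L) {
    di <- sample.int(n, n_decoy)
    decoy_subject <- truth$gene_B[(di %% n) + 1L]  # some other B gene
    hits_ab <- rbind(hits_ab,
                     hit_row(truth$gene_A[di], decoy_subject,
                             bits[di] - stats::runif(n_decoy, 50, 100)))
  }
  refs <- sprintf("REF%05d", sample.int(max(n, 1000), n))
  hits_ref <- hit_row(truth$gene_A, refs, stats::runif(n, 300, 600))
  list(annotations = annotations, hits_ab = hits_ab, hits_ba = hits_ba,
       hits_ref = hits_ref,
       symbols_true = stats::setNames(refs, truth$gene_A))
}

#' Simulate a regulated expression matrix for network recovery
#'
#' Ground truth for the network stage: each true TF's expression is i.i.d.
#' noise; each of its targets is a linear function of the TF plus Gaussian
#' noise; decoy TFs are pure noise. Values are shifted to be positive, like
#' log-scale normalized expression.
#'
#' @param n_tfs Number of true TFs (default 5).
#' @param targets_per_tf Targets per true TF (default 20).
#' @param n_decoys Decoy TFs (default 50).
#' @param n_samples Samples (default 60).
#' @param coef Linear coefficient of target on TF (default 2).
#' @param noise_sd Target noise standard deviation (default 0.1).
#' @param seed Seed.
#' @return List: `X` (genes x samples matrix), `tfs` (all candidate TFs),
#'   `true_edges` (data frame tf, target).
#' @export
simulate_regulated_expression <- function(n_tfs = 5, targets_per_tf = 20,
                                          n_decoys = 50, n_samples = 60,
                                          coef = 2, noise_sd = 0.1, seed = 1) {
  set.seed(derive_seed(seed, "grn"))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  decoy_ids <- sprintf("DTF%02d", seq_len(n_decoys))
  tgt_ids <- sprintf("TGT%03d", seq_len(n_tfs * targets_per_tf))
  tf_x <- matrix(stats::rnorm(n_tfs * n_samples), n_tfs,
                 dimnames = list(tf_ids, NULL))
  decoy_x <- matrix(stats::rnorm(n_decoys * n_samples), n_decoys,
                    dimnames = list(decoy_ids, NULL))
  reg <- rep(tf_ids, each = targets_per_tf)
  tgt_x <- coef * tf_x[reg, , drop = FALSE] +
    matrix(stats::rnorm(length(tgt_ids) * n_samples, sd = noise_sd),
           length(tgt_ids))
  rownames(tgt_x) <- tgt_ids
  X <- rbind(tf_x, decoy_x, tgt_x) + 10
  colnames(X) <- paste0("s", seq_len(n_samples))
  list(X = X, tfs = c(tf_ids, decoy_ids),
       true_edges = data.frame(tf = reg, target = tgt_ids,
                               stringsAsFactors = FALSE))
}

#' Write a hit data frame as a 12-column tabular hit file
#'
#' @param hits Hit data frame (the layout of [parse_hit_table()], minus
#'   `self_hit`).
#' @param path Output path (no header, tab-separated).
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
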