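# Expression containers and transcript-length normalization.
#
# Expression estimates E (e.g., estimated counts from a pseudo-aligner) are
# converted to discrete quantification values Q = round(E / L) with L the
# transcript length in kilobases, so that orthologs of different length can be
# compared across species on a common scale. Each species uses its own
# transcript length for the same ortholog pair -- that is the point of the
# normalization.

#' Construct a count matrix with sample metadata
#'
#' A light container in the `DGEList` tradition: an integer gene x sample
#' matrix plus a sample table with `sample_id`, `species`, `condition`
#' (`control`/`drought`) and `replicate`.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns; column names must match `samples$sample_id`.
#' @param samples Data frame with columns `sample_id`, `species`, `condition`,
#'   `replicate`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stopf("counts must have gene row names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene rows: %s",
          rownames(counts)[anyDuplicated(rownames(counts))])
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be integers")
  req <- c("sample_id", "species", "condition", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0L)
    stopf("samples table missing column(s): %s", paste(miss, collapse = ", "))
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stopf("counts column names must match samples$sample_id (same order)")
  if (!all(samples$condition %in% c("control", "drought")))
    stopf("condition must be 'control' or 'drought'")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(species = x$samples$species, condition = x$samples$condition))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Length-normalize expression estimates to discrete counts
#'
#' Computes `Q[g, s] = round(E[g, s] / L[g])` with L in kilobases. Rounding is
#' half-to-even by default (`"half_up"` rounds 0.5 away from zero instead);
#' with `normalization = "none"` the estimates are rounded unchanged, the
#' non-normalized variant used to probe quantification biases.
#'
#' @param E Non-negative numeric matrix of expression estimates
#'   (genes x samples) with gene row names.
#' @param lengths Named numeric vector of transcript lengths in kilobases,
#'   covering every gene in `E`; all values must be positive.
#' @param samples Optional sample table; when supplied a `count_matrix` is
#'   returned, otherwise a plain integer matrix.
#' @param rounding `"half_even"` (default) or `"half_up"`.
#' @param normalization `"length"` (default, divide by `lengths`) or `"none"`.
#' @return Integer matrix of quantification values, or a `count_matrix` when
#'   `samples` is given.
#' @export
length_normalize <- function(E, lengths, samples = NULL,
                             rounding = c("half_even", "half_up"),
                             normalization = c("length", "none")) {
  rounding <- match.arg(rounding)
  normalization <- match.arg(normalization)
  E <- as.matrix(E)
  if (any(E < 0)) stopf("expression estimates must be non-negative")
  if (normalization == "length") {
    missing_len <- setdiff(rownames(E), names(lengths))
    if (length(missing_len) > 0L)
      stopf("no transcript length for gene(s): %s",
            paste(utils::head(missing_len, 3), collapse = ", "))
    L <- lengths[rownames(E)]
    if (any(L <= 0)) stopf("transcript lengths must be positive")
    x <- E / L
  } else {
    x <- E
  }
  Q <- if (rounding == "half_even") round(x) else floor(x + 0.5)
  storage.mode(Q) <- "integer"
  if (is.null(samples)) Q else count_matrix(Q, samples)
}

#' Join two species' count matrices by ortholog pairs
#'
#' Rows of the joint matrix are ortholog pairs, keyed by the species-A gene
#' id; columns are the union of both species' samples. Pairs whose member is
#' absent from either matrix are dropped with a warning; genes without an
#' ortholog are simply not represented (they remain in the per-species
#' matrices).
#'
#' @param q_a,q_b `count_matrix` objects for species A and B.
#' @param map An `ortholog_map`.
#' @return A `count_matrix` over ortholog pairs with a `pairs` element
#'   recording the gene_A/gene_B identity of every row.
#' @export
pair_by_orthologs <- function(q_a, q_b, map) {
  stopifnot(inherits(q_a, "count_matrix"), inherits(q_b, "count_matrix"),
            inherits(map, "ortholog_map"))
  pairs <- map$pairs
  keep <- pairs$gene_A %in% rownames(q_a$counts) &
    pairs$gene_B %in% rownames(q_b$counts)
  if (any(!keep))
    warnf("dropping %d ortholog pair(s) absent from a count matrix",
          sum(!keep))
  pairs <- pairs[keep, , drop = FALSE]
  joint <- cbind(q_a$counts[pairs$gene_A, , drop = FALSE],
                 q_b$counts[pairs$gene_B, , drop = FALSE])
  rownames(joint) <- pairs$gene_A
  samples <- rbind(q_a$samples, q_b$samples)
  out <- count_matrix(joint, samples)
  out$pairs <- pairs
  out
}

#' Normalize counts for network inference
#'
#' Size-factor scaling (median-of-ratios, computed within each species unless
#' `per_species = FALSE`) followed by log2(x + 1). This is the "normalized
#' gene counts" input to the regulatory-network stage.
#'
#' @param Q A `count_matrix`.
#' @param per_species Compute size factors within each species separately
#'   (default) or jointly.
#' @return A numeric matrix of the same shape as `Q$counts`.
#' @export
normalize_for_grn <- function(Q, per_species = TRUE) {
  stopifnot(inherits(Q, "count_matrix"))
  if (ncol(Q$counts) < 2L) stopf("need at least 2 samples")
  out <- matrix(0, nrow(Q$counts), ncol(Q$counts),
                dimnames = dimnames(Q$counts))
  groups <- if (per_species) split(seq_len(ncol(Q$counts)), Q$samples$species)
            else list(all = seq_len(ncol(Q$counts)))
  for (idx in groups) {
    sub <- Q$counts[, idx, drop = FALSE]
    sf <- size_factors(sub)
    out[, idx] <- log2(sweep(sub, 2, sf, "/") + 1)
  }
  out
}
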