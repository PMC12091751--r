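# Term enrichment of gene sets against a population background.
#
# One-sided hypergeometric over-representation test per term, BH correction
# across tested terms, and the "purified" filter: terms that are depleted in
# the study set (k/n <= K/N) are reported but never retained. Annotations are
# consumed as a flat gene -> term table assumed already propagated.

#' Construct an annotation table
#'
#' @param gene_term Data frame with columns `gene` and `term`; an optional
#'   `name` column carries human-readable term names.
#' @return An `annotation_table` object (de-duplicated).
#' @export
annotation_table <- function(gene_term) {
  miss <- setdiff(c("gene", "term"), names(gene_term))
  if (length(miss) > 0L)
    stopf("annotation table needs column(s): %s", paste(miss, collapse = ", "))
  gene_term <- unique(gene_term[, intersect(c("gene", "term", "name"),
                                            names(gene_term))])
  rownames(gene_term) <- NULL
  structure(gene_term, class = c("annotation_table", "data.frame"))
}

#' Read a two-column gene -> term TSV
#'
#' @param path TSV with header columns `gene` and `term`.
#' @return An `annotation_table`.
#' @export
read_annotations <- function(path) annotation_table(read_tsv(path))

#' Hypergeometric term enrichment
#'
#' For each term annotated to at least one population gene, tests whether the
#' study set holds more annotated genes than expected:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Unannotated genes count
#' toward the population and study sizes with zero terms. Direction is
#' `enriched` when `k/n > K/N`, else `purified`; only enriched terms below the
#' FDR threshold are retained.
#'
#' @param study Character vector of study genes (must be a subset of
#'   `population`).
#' @param population Character vector of background genes.
#' @param ann An `annotation_table`.
#' @param fdr_threshold Retention threshold on the BH value (default 0.05).
#' @return Data frame `term`, `k`, `n`, `K`, `N`, `p`, `fdr`, `direction`,
#'   `retained`, sorted by p; the retained subset is also available via
#'   `attr(, "retained_terms")`.
#' @export
term_enrichment <- function(study, population, ann, fdr_threshold = 0.05) {
  study <- unique(study)
  population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside) > 0L)
    stopf("study gene(s) outside the population: %s",
          paste(utils::head(outside, 3), collapse = ", "))
  ann <- ann[ann$gene %in% population, , drop = FALSE]
  N <- length(population)
  n <- length(study)
  K_tab <- table(ann$term)
  k_tab <- table(ann$term[ann$gene %in% study])
  terms <- names(K_tab)
  K <- as.integer(K_tab)
  k <- as.integer(k_tab[terms])
  k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  direction <- ifelse(k / n > K / N, "enriched", "purified")
  fdr <- bh_adjust(p)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    fdr = fdr, direction = direction,
                    retained = direction == "enriched" & fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_terms") <- out$term[out$retained]
  out
}

#' Random-gene negative control for term enrichment
#'
#' For each study-set size, draws `reps` random gene sets of that size from
#' the population (without replacement) and runs [term_enrichment()]; on null
#' annotations virtually no term should be retained.
#'
#' @param case_sizes Integer vector of study-set sizes (e.g., the per-case
#'   gene counts of the expression models).
#' @param population Background gene set.
#' @param ann An `annotation_table`.
#' @param reps Replicates per size (default 3).
#' @param seed Seed for the draws.
#' @param fdr_threshold Passed to [term_enrichment()].
#' @return Data frame `rep`, `case_size`, `retained_terms` (comma-joined,
#'   empty string when none) and `n_retained`.
#' @export
random_gene_control <- function(case_sizes, population, ann, reps = 3,
                                seed = NULL, fdr_threshold = 0.05) {
  if (any(case_sizes > length(population)))
    stopf("case size exceeds population size")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(reps)) {
    for (cs in case_sizes) {
      g <- sample(population, cs)
      res <- term_enrichment(g, population, ann, fdr_threshold)
      ret <- attr(res, "retained_terms")
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, case_size = cs, n_retained = length(ret),
        retained_terms = paste(ret, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
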