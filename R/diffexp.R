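# Two-group negative-binomial differential-expression contrasts.
#
# A deliberately small surrogate for a full NB GLM framework: median-of-ratios
# size factors, per-gene method-of-moments dispersion pooled within groups,
# log2 fold change on shrunken means (+0.5), a delta-method standard error
# under the NB variance function mu + alpha*mu^2, and a Wald statistic
# referred to a t distribution with n1+n2-2 degrees of freedom. The t
# reference (rather than a normal) keeps the test calibrated at the small
# replicate numbers this design targets; see the methods vignette. Downstream
# classification consumes only (significance, sign of log2fc).

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: for each sample, the median ratio of its
#' counts to the per-gene geometric mean, over genes expressed in every
#' sample; factors are then normalized to geometric mean 1.
#'
#' @param counts Non-negative count matrix (genes x samples) or a
#'   `count_matrix`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use))
    stopf("no gene is expressed in all samples; cannot compute median-of-ratios size factors (consider a pseudo-reference fallback)")
  lograt <- logc[use, , drop = FALSE] - loggeo[use]
  logsf <- apply(lograt, 2, stats::median)
  logsf <- logsf - mean(logsf)  # geometric mean 1
  stats::setNames(exp(logsf), colnames(counts))
}

#' Define a two-group contrast
#'
#' @param name Contrast name.
#' @param group1,group2 Character vectors of sample ids; the reported log2
#'   fold change is `log2(mean(group2) / mean(group1))`.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(name, group1, group2) {
  if (length(intersect(group1, group2)) > 0L)
    stopf("contrast '%s': groups must be disjoint", name)
  if (length(group1) < 2L || length(group2) < 2L)
    stopf("contrast '%s': each group needs >= 2 samples", name)
  structure(list(name = name, group1 = group1, group2 = group2),
            class = "contrast_spec")
}

#' Negative-binomial two-group contrast
#'
#' @param Q A `count_matrix`.
#' @param spec A `contrast_spec`.
#' @param sf Size factors to use; defaults to factors computed jointly over
#'   all samples of `Q` (so inter-species contrasts share one scaling).
#' @param dispersion_floor Lower bound for the method-of-moments dispersion.
#' @return A `ContrastTable` data frame: `gene`, `mean1`, `mean2`, `log2fc`,
#'   `se`, `pvalue`, `padj`.
#' @export
nb_contrast <- function(Q, spec, sf = NULL, dispersion_floor = 1e-8) {
  stopifnot(inherits(Q, "count_matrix"), inherits(spec, "contrast_spec"))
  counts <- Q$counts
  if (any(counts < 0)) stopf("negative counts")
  missing_s <- setdiff(c(spec$group1, spec$group2), colnames(counts))
  if (length(missing_s) > 0L)
    stopf("contrast '%s': unknown sample(s) %s", spec$name,
          paste(missing_s, collapse = ", "))
  if (is.null(sf)) sf <- size_factors(counts)
  K <- sweep(counts, 2, sf[colnames(counts)], "/")
  k1 <- K[, spec$group1, drop = FALSE]
  k2 <- K[, spec$group2, drop = FALSE]
  n1 <- ncol(k1); n2 <- ncol(k2)
  m1 <- rowMeans(k1); m2 <- rowMeans(k2)
  v1 <- apply(k1, 1, stats::var)
  v2 <- apply(k2, 1, stats::var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mpool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- ifelse(mpool > 0, pmax((vpool - mpool) / mpool^2, dispersion_floor),
                  dispersion_floor)
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  se2 <- (m1 + alpha * m1^2) / n1 / ((m1 + 0.5)^2 * log(2)^2) +
         (m2 + alpha * m2^2) / n2 / ((m2 + 0.5)^2 * log(2)^2)
  se <- sqrt(se2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  zero <- m1 == 0 & m2 == 0
  log2fc[zero] <- 0
  pvalue[zero] <- 1
  se[zero] <- NA_real_
  data.frame(gene = rownames(counts), mean1 = m1, mean2 = m2,
             log2fc = log2fc, se = se, pvalue = pvalue,
             padj = bh_adjust(pvalue), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper over the standard step-up procedure.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' The six standard contrasts of the two-species drought design
#'
#' Given the joint ortholog-paired matrix, runs (with jointly computed size
#' factors): A = A-drought vs A-control; B = B-drought vs B-control;
#' C = B-control vs A-control; D = B-drought vs A-drought;
#' E = B-drought vs A-control; F = A-drought vs B-control. In each case the
#' log2 fold change is log2 of the first-named group over the second
#' (group2 / group1). D is reported but unused by the classifier.
#'
#' @param Q Joint `count_matrix` from [pair_by_orthologs()] with species
#'   labels `"A"` and `"B"`.
#' @param species_a,species_b Species labels in `Q$samples$species`.
#' @return Named list of `ContrastTable` data frames (`A`..`F`).
#' @export
run_standard_contrasts <- function(Q, species_a = "A", species_b = "B") {
  stopifnot(inherits(Q, "count_matrix"))
  s <- Q$samples
  pick <- function(sp, cond) s$sample_id[s$species == sp & s$condition == cond]
  AC <- pick(species_a, "control"); AD <- pick(species_a, "drought")
  BC <- pick(species_b, "control"); BD <- pick(species_b, "drought")
  sf <- size_factors(Q$counts)
  specs <- list(
    A = contrast_spec("A_drought_vs_control_speciesA", AC, AD),
    B = contrast_spec("B_drought_vs_control_speciesB", BC, BD),
    C = contrast_spec("C_control_B_vs_control_A", AC, BC),
    D = contrast_spec("D_drought_B_vs_drought_A", AD, BD),
    E = contrast_spec("E_drought_B_vs_control_A", AC, BD),
    F = contrast_spec("F_drought_A_vs_control_B", BC, AD))
  lapply(specs, function(sp) nb_contrast(Q, sp, sf = sf))
}

#' Bundle contrast results for the classifier
#'
#' @param tables Named list of contrast tables containing at least
#'   `A`, `B`, `C`, `E`, `F` (as from [run_standard_contrasts()]).
#' @param threshold Adjusted-p significance threshold (default 0.05).
#' @return Data frame with one row per ortholog: `ortholog`, then `sigX` and
#'   `lfcX` for X in A, B, C, E, F.
#' @export
contrast_bundle <- function(tables, threshold = 0.05) {
  need <- c("A", "B", "C", "E", "F")
  miss <- setdiff(need, names(tables))
  if (length(miss) > 0L)
    stopf("missing contrast table(s): %s", paste(miss, collapse = ", "))
  genes <- tables$A$gene
  out <- data.frame(ortholog = genes, stringsAsFactors = FALSE)
  for (x in need) {
    tb <- tables[[x]]
    if (!identical(tb$gene, genes)) {
      idx <- match(genes, tb$gene)
      if (anyNA(idx)) stopf("contrast '%s' is missing some orthologs", x)
      tb <- tb[idx, , drop = FALSE]
    }
    out[[paste0("sig", x)]] <- !is.na(tb$padj) & tb$padj < threshold
    out[[paste0("lfc", x)]] <- tb$log2fc
  }
  out
}
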