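# Gene-regulatory-network inference and cross-species comparison.
#
# Per species: a randomized regression-tree ensemble (GENIE3-style) predicts
# each target gene from all candidate TFs except itself; the ensemble's
# impurity importances, normalized to sum one per target, weight the directed
# TF -> target edges. Edges are then thinned to the top fraction by importance
# and to those whose target promoter holds one of the TF's binding motifs.
# Networks are compared by the Jaccard index over directed edges mapped into
# the shared ortholog namespace.

new_grn_edge_set <- function(edges, stage, species = NA_character_) {
  stopifnot(all(c("tf", "target", "importance") %in% names(edges)))
  if (any(edges$tf == edges$target)) stopf("self-edges are not allowed")
  if (any(!is.finite(edges$importance)) || any(edges$importance < 0))
    stopf("importances must be finite and non-negative")
  structure(list(edges = edges, stage = stage, species = species),
            class = "grn_edge_set")
}

#' @export
print.grn_edge_set <- function(x, ...) {
  cat(sprintf("grn_edge_set [%s, species %s]: %d edges, %d TFs, %d targets\n",
              x$stage, x$species, nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$target))))
  invisible(x)
}

#' Exclude lowly expressed transcription factors
#'
#' A TF is excluded when its total raw (pre-normalization) count summed over
#' all samples falls below the threshold; TFs absent from the matrix are
#' excluded with reason `"absent"`.
#'
#' @param Q_raw `count_matrix` of raw counts.
#' @param tfs Character vector of candidate TF genes.
#' @param threshold Minimum total raw count (default 10); totals `>=`
#'   threshold are retained.
#' @param mode `"total"` (default) or `"per_sample_mean"` (threshold applied
#'   to the mean count per sample instead).
#' @return List with `active` (character vector) and `excluded` (data frame
#'   `tf`, `reason`, `total`).
#' @export
filter_low_expression_tfs <- function(Q_raw, tfs, threshold = 10,
                                      mode = c("total", "per_sample_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(Q_raw, "count_matrix"))
  present <- tfs %in% rownames(Q_raw$counts)
  totals <- rep(NA_real_, length(tfs))
  totals[present] <- rowSums(Q_raw$counts[tfs[present], , drop = FALSE])
  stat <- if (mode == "total") totals else totals / ncol(Q_raw$counts)
  low <- present & stat < threshold
  excluded <- rbind(
    data.frame(tf = tfs[!present], reason = rep("absent", sum(!present)),
               total = totals[!present], stringsAsFactors = FALSE),
    data.frame(tf = tfs[low], reason = rep("low_expression", sum(low)),
               total = totals[low], stringsAsFactors = FALSE))
  rownames(excluded) <- NULL
  list(active = tfs[present & !low], excluded = excluded)
}

#' Infer a gene regulatory network with a tree ensemble
#'
#' For every target gene, fits a random-forest regression of the target's
#' normalized expression on all candidate TFs except the target itself
#' (mtry = floor(sqrt(#predictors)), impurity importance) and emits every
#' TF -> target edge with positive normalized importance (importances sum to
#' one per target). Constant-expression targets are skipped with a warning.
#'
#' @param X Numeric genes x samples matrix of normalized expression (see
#'   [normalize_for_grn()]).
#' @param tfs Candidate TF genes (must have >= 2 entries present in `X`).
#' @param targets Target genes; defaults to all rows of `X`.
#' @param n_trees Trees per ensemble (default 1000).
#' @param seed Master seed; per-target streams are derived from it, so a
#'   fixed seed gives identical output.
#' @param species Species label carried on the edge set.
#' @return A `grn_edge_set` with stage `"raw"`.
#' @export
infer_grn <- function(X, tfs, targets = rownames(X), n_trees = 1000,
                      seed = 1, species = NA_character_) {
  if (ncol(X) < 3L) stopf("need at least 3 samples for network inference")
  tfs <- intersect(tfs, rownames(X))
  if (length(tfs) < 2L) stopf("need at least 2 candidate TFs present in X")
  targets <- intersect(targets, rownames(X))
  Xt <- t(X)  # samples x genes
  res <- vector("list", length(targets))
  skipped <- 0L
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    y <- Xt[, tgt]
    if (stats::var(y) == 0) { skipped <- skipped + 1L; next }
    preds <- setdiff(tfs, tgt)
    fit <- ranger::ranger(
      x = Xt[, preds, drop = FALSE], y = y, num.trees = n_trees,
      mtry = max(1L, floor(sqrt(length(preds)))),
      importance = "impurity", num.threads = 1,
      seed = derive_seed(seed, paste0("grn_", tgt)))
    imp <- fit$variable.importance
    imp[imp < 0] <- 0
    if (sum(imp) > 0) imp <- imp / sum(imp)
    pos <- imp > 0
    if (!any(pos)) next
    res[[i]] <- data.frame(tf = preds[pos], target = tgt,
                           importance = unname(imp[pos]),
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warnf("skipped %d constant-expression target(s)", skipped)
  edges <- do.call(rbind, res)
  if (is.null(edges))
    edges <- data.frame(tf = character(0), target = character(0),
                        importance = numeric(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new_grn_edge_set(edges, stage = "raw", species = species)
}

#' Retain the top fraction of edges by importance
#'
#' Keeps the `ceiling(fraction * n)` highest-importance edges; ties at the
#' cutoff importance are all kept.
#'
#' @param E A `grn_edge_set`.
#' @param fraction Fraction of edges to keep (default 0.10).
#' @return A `grn_edge_set` with stage `"top_fraction"`.
#' @export
select_top_edges <- function(E, fraction = 0.10) {
  stopifnot(inherits(E, "grn_edge_set"))
  n <- nrow(E$edges)
  if (n == 0L) stopf("empty edge set")
  k <- ceiling(fraction * n)
  cutoff <- sort(E$edges$importance, decreasing = TRUE)[k]
  keep <- E$edges$importance >= cutoff
  out <- new_grn_edge_set(E$edges[keep, , drop = FALSE],
                          stage = "top_fraction", species = E$species)
  rownames(out$edges) <- NULL
  out
}

#' Filter edges by motif presence in the target promoter
#'
#' An edge TF -> target survives iff at least one of the TF's binding motifs
#' has a retained hit in the target's promoter. TFs with no motif in the
#' library lose all their edges (reported via a message).
#'
#' @param E A `grn_edge_set` (normally the top-fraction stage).
#' @param presence Logical gene x motif matrix from [motif_presence()].
#' @param tf_to_motif Data frame with columns `tf` and `motif_id`.
#' @return A `grn_edge_set` with stage `"motif_filtered"`.
#' @export
motif_filter_edges <- function(E, presence, tf_to_motif) {
  stopifnot(inherits(E, "grn_edge_set"))
  no_motif <- setdiff(unique(E$edges$tf), tf_to_motif$tf)
  if (length(no_motif) > 0L)
    message(sprintf("motif_filter_edges: %d TF(s) without a motif lose all edges",
                    length(no_motif)))
  keep <- vapply(seq_len(nrow(E$edges)), function(i) {
    tf <- E$edges$tf[i]; tgt <- E$edges$target[i]
    if (!tgt %in% rownames(presence)) return(FALSE)
    motifs <- tf_to_motif$motif_id[tf_to_motif$tf == tf]
    motifs <- intersect(motifs, colnames(presence))
    length(motifs) > 0L && any(presence[tgt, motifs])
  }, logical(1))
  out <- new_grn_edge_set(E$edges[keep, , drop = FALSE],
                          stage = "motif_filtered", species = E$species)
  rownames(out$edges) <- NULL
  out
}

# Map a species' edge endpoints into the shared ortholog namespace (the
# species-A gene id of each pair); unmapped endpoints keep a species-tagged
# name so they can never match the other network's edges.
map_edges_to_orthologs <- function(E, map, species = c("A", "B")) {
  species <- match.arg(species)
  edges <- E$edges
  if (species == "A") {
    known <- map$pairs$gene_A
    trans <- stats::setNames(map$pairs$gene_A, map$pairs$gene_A)
  } else {
    known <- map$pairs$gene_B
    trans <- stats::setNames(map$pairs$gene_A, map$pairs$gene_B)
  }
  conv <- function(g) ifelse(g %in% known, unname(trans[g]),
                             paste0(species, ":", g))
  edges$tf <- conv(edges$tf)
  edges$target <- conv(edges$target)
  edges
}

edge_keys <- function(edges) paste(edges$tf, edges$target, sep = "->")

#' Jaccard index of two directed edge sets
#'
#' `J = |E1 intersect E2| / |E1 union E2|` over directed (tf, target) pairs.
#' When an ortholog map is supplied, both networks' endpoints are first mapped
#' into the shared ortholog namespace; edges with unmapped endpoints cannot
#' match and only enlarge the union.
#'
#' @param E1,E2 `grn_edge_set` objects (E1 from species A, E2 from species B
#'   when `map` is given).
#' @param map Optional `ortholog_map` for cross-species comparison.
#' @return Jaccard index in [0, 1].
#' @export
jaccard_index <- function(E1, E2, map = NULL) {
  k1 <- if (is.null(map)) edge_keys(E1$edges)
        else edge_keys(map_edges_to_orthologs(E1, map, "A"))
  k2 <- if (is.null(map)) edge_keys(E2$edges)
        else edge_keys(map_edges_to_orthologs(E2, map, "B"))
  k1 <- unique(k1); k2 <- unique(k2)
  if (length(k1) == 0L && length(k2) == 0L)
    stopf("Jaccard undefined: both edge sets are empty")
  length(intersect(k1, k2)) / length(union(k1, k2))
}

#' Jaccard index from bookkeeping counts
#'
#' @param n_intersection,n_union Directed-edge intersection and union sizes.
#' @return `n_intersection / n_union`.
#' @export
jaccard_from_counts <- function(n_intersection, n_union) {
  if (n_union <= 0) stopf("Jaccard undefined: empty union")
  if (n_intersection > n_union) stopf("intersection exceeds union")
  n_intersection / n_union
}

#' Node/edge bookkeeping for a pair of networks
#'
#' The per-network and intersection/union node, TF-node and edge counts for
#' two species' networks at one stage, plus their Jaccard index, after mapping
#' both into the shared ortholog namespace.
#'
#' @param E1,E2 `grn_edge_set` objects for species A and B.
#' @param map An `ortholog_map`.
#' @return A list (JSON-friendly) of counts and the Jaccard value.
#' @export
network_summary <- function(E1, E2, map) {
  e1 <- map_edges_to_orthologs(E1, map, "A")
  e2 <- map_edges_to_orthologs(E2, map, "B")
  nodes <- function(e) unique(c(e$tf, e$target))
  k1 <- unique(edge_keys(e1)); k2 <- unique(edge_keys(e2))
  list(
    stage = E1$stage,
    network_A = list(nodes = length(nodes(e1)),
                     nodes_acting_as_tf = length(unique(e1$tf)),
                     edges = length(k1)),
    network_B = list(nodes = length(nodes(e2)),
                     nodes_acting_as_tf = length(unique(e2$tf)),
                     edges = length(k2)),
    intersection = list(nodes = length(intersect(nodes(e1), nodes(e2))),
                        nodes_acting_as_tf = length(intersect(unique(e1$tf),
                                                              unique(e2$tf))),
                        edges = length(intersect(k1, k2))),
    union = list(nodes = length(union(nodes(e1), nodes(e2))),
                 nodes_acting_as_tf = length(union(unique(e1$tf),
                                                   unique(e2$tf))),
                 edges = length(union(k1, k2))),
    jaccard = jaccard_from_counts(length(intersect(k1, k2)),
                                  length(union(k1, k2))))
}
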