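# End-to-end orchestration on synthetic two-species data.
#
# One config drives: truth generation -> counts/lengths -> ortholog
# identification from hit tables -> length normalization -> the six standard
# contrasts -> expression-model classification -> term enrichment with random
# controls -> promoter scanning and motif enrichment -> per-species network
# inference with top-fraction and motif filters -> cross-species Jaccard.
# Every stage's tables can be written to an output directory and the summary
# is machine-readable (JSON-friendly list).

#' Build a pipeline configuration
#'
#' Defaults are the study conditions the synthetic generator emulates;
#' thresholds follow the analysis conventions (padj < 0.05, motif q < 0.05,
#' Fisher p < 0.05 unadjusted, top 10% of edges, TFs under 10 raw reads
#' excluded).
#'
#' @param n_orthologs Number of ortholog pairs (default 3000).
#' @param n_reps Replicates per (species, condition) (default 5).
#' @param effect Planted |log2 fold change| (default 2).
#' @param dispersion NB dispersion (default 0.05).
#' @param baseline_range Baseline mean range (default 50-500).
#' @param case_proportions Case mix (see [default_case_proportions()]).
#' @param padj_threshold DE significance threshold (default 0.05).
#' @param normalization `"length"` or `"none"` (the non-normalized variant).
#' @param require_baseline_difference Stress-ready baseline requirement.
#' @param n_tfs,targets_per_tf Planted regulatory structure for the motif and
#'   network stages.
#' @param motif_width,motif_p_threshold,motif_q_threshold Scanner settings.
#' @param grn_fraction Top-edge fraction (default 0.10).
#' @param tf_min_raw_count Raw-count TF exclusion threshold (default 10).
#' @param n_trees Trees per ensemble (default 100 at desk scale).
#' @param n_terms Annotation terms (default 50).
#' @param go_min_genes Smallest case size tested for term enrichment.
#' @param decoy_rate Decoy paralog hit rate for the ortholog stage.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(n_orthologs = 3000, n_reps = 5, effect = 2,
                       dispersion = 0.05, baseline_range = c(50, 500),
                       case_proportions = default_case_proportions(),
                       padj_threshold = 0.05,
                       normalization = c("length", "none"),
                       require_baseline_difference = TRUE,
                       n_tfs = 8, targets_per_tf = 25,
                       motif_width = 12, motif_p_threshold = 1e-4,
                       motif_q_threshold = 0.05,
                       grn_fraction = 0.10, tf_min_raw_count = 10,
                       n_trees = 100, n_terms = 50, go_min_genes = 10,
                       decoy_rate = 0.1, seed = 1) {
  normalization <- match.arg(normalization)
  cfg <- as.list(environment())
  for (thr in c("padj_threshold", "motif_p_threshold", "motif_q_threshold"))
    if (cfg[[thr]] <= 0 || cfg[[thr]] >= 1)
      stopf("%s must lie in (0, 1)", thr)
  if (cfg$grn_fraction <= 0 || cfg$grn_fraction > 1)
    stopf("grn_fraction must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(vals$case_proportions))
    vals$case_proportions <- unlist(vals$case_proportions)
  do.call(run_config, vals)
}

#' Run the whole pipeline on synthetic data
#'
#' @param config A `run_config`.
#' @param outdir Optional directory for stage TSVs and the summary JSON.
#' @return List with stage objects (`truth`, `map`, `joint`, `contrasts`,
#'   `assignments`, `model_summary`, `go`, `motifs`, `network`) and a
#'   JSON-friendly `summary`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log_msg <- function(fmt, ...) message(sprintf(paste0("[stressready] ", fmt), ...))

  # --- synthetic inputs ------------------------------------------------------
  truth <- generate_truth(config$n_orthologs, config$case_proportions,
                          effect = config$effect,
                          baseline_range = config$baseline_range,
                          dispersion = config$dispersion, seed = seed)
  sim <- simulate_counts(truth, n_reps = config$n_reps, seed = seed)
  ann_hits <- simulate_annotations_and_hits(
    truth, n_terms = config$n_terms,
    enrichment_plan = data.frame(term = "T0001", model = "stress_ready",
                                 case = 3, fold = 5,
                                 stringsAsFactors = FALSE),
    decoy_rate = config$decoy_rate, seed = seed)

  # --- orthology -------------------------------------------------------------
  map <- best_bidirectional_hits(ann_hits$hits_ab, ann_hits$hits_ba)
  map <- assign_symbols(map, ann_hits$hits_ref)
  true_keys <- paste(truth$gene_A, truth$gene_B)
  bbh_recovery <- 100 * mean(true_keys %in%
                               paste(map$pairs$gene_A, map$pairs$gene_B))
  log_msg("orthology: %d pairs (%.1f%% of planted pairs recovered)",
          nrow(map$pairs), bbh_recovery)

  # --- expression ------------------------------------------------------------
  q_a <- length_normalize(sim$E_A, sim$lengths_A, sim$samples_A,
                          normalization = config$normalization)
  q_b <- length_normalize(sim$E_B, sim$lengths_B, sim$samples_B,
                          normalization = config$normalization)
  joint <- pair_by_orthologs(q_a, q_b, map)

  # --- differential expression and classification ---------------------------
  contrasts <- run_standard_contrasts(joint)
  deg_counts <- vapply(contrasts, function(tb)
    sum(tb$padj < config$padj_threshold, na.rm = TRUE), integer(1))
  bundle <- contrast_bundle(contrasts, threshold = config$padj_threshold)
  assignments <- classify_orthologs(
    bundle, require_baseline_difference = config$require_baseline_difference)
  model_summary <- summarize_models(assignments)
  truth_idx <- match(assignments$ortholog, truth$gene_A)
  accuracy <- 100 * mean(assignments$model == truth$model[truth_idx] &
                           assignments$case == truth$case[truth_idx])
  log_msg("classification: %.1f%% of orthologs assigned their planted case",
          accuracy)

  # --- term enrichment -------------------------------------------------------
  population <- rownames(joint$counts)
  case_sets <- split(assignments$ortholog,
                     paste(assignments$model, assignments$case, sep = "_"))
  case_sets <- case_sets[lengths(case_sets) >= config$go_min_genes]
  go_tables <- lapply(case_sets, term_enrichment, population = population,
                      ann = ann_hits$annotations)
  go_retained <- vapply(go_tables, function(tb) sum(tb$retained), integer(1))
  go_control <- random_gene_control(lengths(case_sets), population,
                                    ann_hits$annotations, reps = 3,
                                    seed = derive_seed(seed, "go_control"))

  # --- promoters, motifs -----------------------------------------------------
  tf_rows <- which(truth$model == "no_response" & truth$case == 3)[
    seq_len(config$n_tfs)]
  if (anyNA(tf_rows)) stopf("not enough flat genes to host the planted TFs")
  tfs_a <- truth$gene_A[tf_rows]
  tfs_b <- truth$gene_B[tf_rows]
  pwms <- make_motif_library(tfs_a, width = config$motif_width, seed = seed)
  set.seed(derive_seed(seed, "grn_targets"))
  target_rows <- lapply(seq_along(tf_rows), function(i)
    sample(setdiff(seq_len(nrow(truth)), tf_rows), config$targets_per_tf))
  planting_a <- data.frame(
    tf = rep(tfs_a, each = config$targets_per_tf),
    target = truth$gene_A[unlist(target_rows)], stringsAsFactors = FALSE)
  planting_b <- data.frame(
    tf = rep(tfs_a, each = config$targets_per_tf),  # motif ids keyed by A TF
    target = truth$gene_B[unlist(target_rows)], stringsAsFactors = FALSE)
  sim_prom_a <- simulate_promoters_and_motifs(
    truth$gene_A, pwms, planting_a, seed = derive_seed(seed, "prom_A"))
  sim_prom_b <- simulate_promoters_and_motifs(
    truth$gene_B, pwms, planting_b, seed = derive_seed(seed, "prom_B"))
  prom_a <- extract_promoters(sim_prom_a$genome, sim_prom_a$coords)
  prom_b <- extract_promoters(sim_prom_b$genome, sim_prom_b$coords)
  hits_a <- scan_motifs(pwms, prom_a, p_threshold = config$motif_p_threshold,
                        q_threshold = config$motif_q_threshold)
  hits_b <- scan_motifs(pwms, prom_b, p_threshold = config$motif_p_threshold,
                        q_threshold = config$motif_q_threshold)
  presence_a <- motif_presence(hits_a, truth$gene_A, names(pwms))
  presence_b <- motif_presence(hits_b, truth$gene_B, names(pwms))
  motif_enrich <- lapply(case_sets, function(g)
    motif_group_enrichment(g, setdiff(population, g), presence_a))
  motif_control <- random_set_control(lengths(case_sets), presence_a, reps = 3,
                                      seed = derive_seed(seed, "motif_control"))

  # --- networks --------------------------------------------------------------
  tf_filter_a <- filter_low_expression_tfs(q_a, tfs_a,
                                           threshold = config$tf_min_raw_count)
  tf_filter_b <- filter_low_expression_tfs(q_b, tfs_b,
                                           threshold = config$tf_min_raw_count)
  x_a <- normalize_for_grn(q_a)
  x_b <- normalize_for_grn(q_b)
  grn_a <- infer_grn(x_a, tf_filter_a$active, n_trees = config$n_trees,
                     seed = derive_seed(seed, "grnA"), species = "A")
  grn_b <- infer_grn(x_b, tf_filter_b$active, n_trees = config$n_trees,
                     seed = derive_seed(seed, "grnB"), species = "B")
  top_a <- select_top_edges(grn_a, config$grn_fraction)
  top_b <- select_top_edges(grn_b, config$grn_fraction)
  # B-species TF -> motif mapping goes through the ortholog pairing
  tf_to_motif_b <- data.frame(tf = tfs_b,
                              motif_id = paste0("M_", tfs_a),
                              stringsAsFactors = FALSE)
  filt_a <- motif_filter_edges(top_a, presence_a, sim_prom_a$tf_to_motif)
  filt_b <- motif_filter_edges(top_b, presence_b, tf_to_motif_b)
  net_before <- network_summary(top_a, top_b, map)
  net_after <- network_summary(filt_a, filt_b, map)
  nesting_ok <- all(edge_keys(filt_a$edges) %in% edge_keys(top_a$edges)) &&
    all(edge_keys(top_a$edges) %in% edge_keys(grn_a$edges)) &&
    all(edge_keys(filt_b$edges) %in% edge_keys(top_b$edges)) &&
    all(edge_keys(top_b$edges) %in% edge_keys(grn_b$edges))

  summary <- list(
    settings = config[setdiff(names(config), "case_proportions")],
    orthology = list(pairs = nrow(map$pairs),
                     unpaired_A = length(map$unpaired_A),
                     unpaired_B = length(map$unpaired_B),
                     bbh_recovery_pct = bbh_recovery),
    de = list(deg_counts = as.list(deg_counts)),
    classification = list(
      case_counts = stats::setNames(as.list(model_summary$count),
                                    paste(model_summary$model,
                                          model_summary$case, sep = "_")),
      n_total = attr(model_summary, "n_total"),
      n_responders = attr(model_summary, "n_responders"),
      stress_ready_pct_of_responders =
        attr(model_summary, "stress_ready_pct_of_responders"),
      accuracy_pct = accuracy),
    go = list(retained_per_case = as.list(go_retained),
              control_retained_total = sum(go_control$n_retained)),
    motifs = list(
      enriched_per_case = lapply(motif_enrich, function(tb) sum(tb$enriched)),
      control_inconsistent = nrow(motif_control$inconsistent)),
    network = list(before_motif_filter = net_before,
                   after_motif_filter = net_after,
                   excluded_tfs_A = nrow(tf_filter_a$excluded),
                   excluded_tfs_B = nrow(tf_filter_b$excluded),
                   stage_nesting_ok = nesting_ok))

  result <- list(truth = truth, map = map, joint = joint,
                 contrasts = contrasts, bundle = bundle,
                 assignments = assignments, model_summary = model_summary,
                 go = go_tables, go_control = go_control,
                 motif_hits = list(A = hits_a, B = hits_b),
                 motif_enrichment = motif_enrich,
                 motif_control = motif_control,
                 network = list(raw = list(A = grn_a, B = grn_b),
                                top = list(A = top_a, B = top_b),
                                filtered = list(A = filt_a, B = filt_b)),
                 summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_ortholog_map(map, file.path(outdir, "ortholog_map.tsv"))
    for (x in names(contrasts))
      write_tsv(contrasts[[x]], file.path(outdir,
                                          sprintf("contrast_%s.tsv", x)))
    write_tsv(assignments, file.path(outdir, "model_assignments.tsv"))
    write_tsv(model_summary, file.path(outdir, "model_summary.tsv"))
    for (cs in names(go_tables))
      write_tsv(go_tables[[cs]], file.path(outdir,
                                           sprintf("go_%s.tsv", cs)))
    for (st in c("raw", "top", "filtered")) for (sp in c("A", "B"))
      write_tsv(result$network[[st]][[sp]]$edges,
                file.path(outdir, sprintf("grn_%s_%s.tsv", st, sp)))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
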