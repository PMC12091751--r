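# Expression-model assignment: the rule-based decision tree.
#
# Every ortholog pair is assigned exactly one of five models (fifteen cases)
# from the significance and sign of five contrasts:
#   A: within species A, drought vs control        (lfcA = log2 AD/AC)
#   B: within species B, drought vs control        (lfcB = log2 BD/BC)
#   C: baseline between species, control vs control (lfcC = log2 BC/AC)
#   E: B drought vs A control                       (lfcE = log2 BD/AC)
#   F: A drought vs B control                       (lfcF = log2 AD/BC)
#
# Models:
#   shared       - both species respond in the same direction (case 1 up,
#                  case 2 down).
#   opposite     - both respond, in opposite directions (case 1: A up / B
#                  down; case 2: A down / B up).
#   stress_ready - exactly one species responds and converges on the other
#                  species' control level: the responder's drought level is
#                  indistinguishable from the other species' control (the
#                  cross contrast E or F is not significant) while the
#                  baselines differ (C significant) in the consistent
#                  direction. Cases 1/2: B rises/falls to A's control level;
#                  cases 3/4: A rises/falls to B's control level.
#   unique       - exactly one species responds but the convergence test
#                  fails. Cases 1/2: A up/down; cases 3/4: B up/down.
#   no_response  - neither species responds; baselines higher in B (case 1),
#                  lower in B (case 2) or indistinguishable (case 3).
#
# Reading "match" as failure to reject equality (non-significant E or F) is a
# deliberate, documented weakness (absence of evidence); an equivalence-test
# variant can be layered on top by recomputing sigE/sigF before bundling.

MODEL_CASES <- data.frame(
  model = rep(c("stress_ready", "shared", "unique", "opposite", "no_response"),
              times = c(4L, 2L, 4L, 2L, 3L)),
  case = c(1:4, 1:2, 1:4, 1:2, 1:3),
  stringsAsFactors = FALSE)

#' Classify one ortholog from its contrast bundle entry
#'
#' First-match rule order: (1) both within-species contrasts significant ->
#' shared or opposite by sign agreement; (2) only B significant -> stress-ready
#' cases 1/2 when non-significant E, significant C and consistent signs, else
#' unique cases 3/4; (3) only A significant -> stress-ready cases 3/4 when
#' non-significant F, significant C and consistent signs, else unique cases
#' 1/2; (4) neither significant -> no-response by the baseline contrast C.
#' A log2 fold change of exactly 0 on a significant contrast is treated as
#' non-positive (down cases).
#'
#' @param sigA,sigB,sigC,sigE,sigF Logical significance flags (padj below the
#'   chosen threshold) for the five contrasts.
#' @param lfcA,lfcB,lfcC Log2 fold changes for contrasts A, B and C.
#' @param require_baseline_difference Demand a significant baseline contrast
#'   (C) with a consistent sign for the stress-ready call (default TRUE).
#' @return List with `model`, `case` and `rule_trace` (the fired predicates).
#' @export
classify_ortholog <- function(sigA, sigB, sigC, sigE, sigF,
                              lfcA, lfcB, lfcC,
                              require_baseline_difference = TRUE) {
  flags <- c(sigA, sigB, sigC, sigE, sigF)
  if (anyNA(flags) || anyNA(c(lfcA, lfcB, lfcC)))
    stopf("classify_ortholog: missing contrast value")
  trace <- character(0)
  push <- function(x) trace <<- c(trace, x)
  if (sigA && sigB) {
    push("sigA&sigB")
    if (lfcA > 0 && lfcB > 0) { push("bothUp");   return(list(model = "shared",   case = 1L, rule_trace = trace)) }
    if (lfcA <= 0 && lfcB <= 0) { push("bothDown"); return(list(model = "shared", case = 2L, rule_trace = trace)) }
    if (lfcA > 0) { push("AupBdown"); return(list(model = "opposite", case = 1L, rule_trace = trace)) }
    push("AdownBup"); return(list(model = "opposite", case = 2L, rule_trace = trace))
  }
  if (sigB && !sigA) {
    push("sigB&!sigA")
    converges <- !sigE && (!require_baseline_difference || sigC)
    if (converges && lfcB > 0 && (!require_baseline_difference || lfcC < 0)) {
      push("!sigE&sigC&Bup&Cdown")
      return(list(model = "stress_ready", case = 1L, rule_trace = trace))
    }
    if (converges && lfcB <= 0 && (!require_baseline_difference || lfcC > 0)) {
      push("!sigE&sigC&Bdown&Cup")
      return(list(model = "stress_ready", case = 2L, rule_trace = trace))
    }
    push(if (lfcB > 0) "Bup" else "Bdown")
    return(list(model = "unique", case = if (lfcB > 0) 3L else 4L,
                rule_trace = trace))
  }
  if (sigA && !sigB) {
    push("sigA&!sigB")
    converges <- !sigF && (!require_baseline_difference || sigC)
    if (converges && lfcA > 0 && (!require_baseline_difference || lfcC > 0)) {
      push("!sigF&sigC&Aup&Cup")
      return(list(model = "stress_ready", case = 3L, rule_trace = trace))
    }
    if (converges && lfcA <= 0 && (!require_baseline_difference || lfcC < 0)) {
      push("!sigF&sigC&Adown&Cdown")
      return(list(model = "stress_ready", case = 4L, rule_trace = trace))
    }
    push(if (lfcA > 0) "Aup" else "Adown")
    return(list(model = "unique", case = if (lfcA > 0) 1L else 2L,
                rule_trace = trace))
  }
  push("!sigA&!sigB")
  if (sigC && lfcC > 0) { push("Cup");   return(list(model = "no_response", case = 1L, rule_trace = trace)) }
  if (sigC) { push("Cdown"); return(list(model = "no_response", case = 2L, rule_trace = trace)) }
  push("!sigC")
  list(model = "no_response", case = 3L, rule_trace = trace)
}

#' Classify every ortholog in a contrast bundle
#'
#' @param bundle Data frame from [contrast_bundle()].
#' @param require_baseline_difference See [classify_ortholog()].
#' @return A `ModelAssignment` data frame: `ortholog`, `model`, `case`,
#'   `rule_trace` (semicolon-joined predicates).
#' @export
classify_orthologs <- function(bundle, require_baseline_difference = TRUE) {
  need <- c("ortholog", paste0("sig", c("A", "B", "C", "E", "F")),
            paste0("lfc", c("A", "B", "C")))
  miss <- setdiff(need, names(bundle))
  if (length(miss) > 0L)
    stopf("bundle missing column(s): %s", paste(miss, collapse = ", "))
  res <- mapply(function(sa, sb, sc, se_, sf_, la, lb, lc) {
    r <- classify_ortholog(sa, sb, sc, se_, sf_, la, lb, lc,
                           require_baseline_difference)
    list(r$model, r$case, paste(r$rule_trace, collapse = ";"))
  }, bundle$sigA, bundle$sigB, bundle$sigC, bundle$sigE, bundle$sigF,
     bundle$lfcA, bundle$lfcB, bundle$lfcC, SIMPLIFY = FALSE)
  data.frame(ortholog = bundle$ortholog,
             model = vapply(res, `[[`, character(1), 1L),
             case = vapply(res, `[[`, integer(1), 2L),
             rule_trace = vapply(res, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Summarize model assignments
#'
#' Per (model, case): gene count, percentage of all orthologs, and percentage
#' of responders (orthologs outside no_response). All fifteen cases are
#' listed, including empty ones.
#'
#' @param assignments A `ModelAssignment` data frame.
#' @return Data frame `model`, `case`, `count`, `pct_total`, `pct_responders`
#'   with attributes `n_total`, `n_responders` and
#'   `stress_ready_pct_of_responders` (NA, flagged via the
#'   `no_responders` attribute, when there are no responders).
#' @export
summarize_models <- function(assignments) {
  if (nrow(assignments) == 0L) stopf("no assignments to summarize")
  key <- paste(assignments$model, assignments$case)
  tab <- table(factor(key, levels = paste(MODEL_CASES$model, MODEL_CASES$case)))
  n <- nrow(assignments)
  responders <- sum(assignments$model != "no_response")
  out <- data.frame(model = MODEL_CASES$model, case = MODEL_CASES$case,
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out$pct_total <- 100 * out$count / n
  out$pct_responders <- ifelse(out$model == "no_response", NA_real_,
                               if (responders > 0) 100 * out$count / responders
                               else NA_real_)
  attr(out, "n_total") <- n
  attr(out, "n_responders") <- responders
  attr(out, "no_responders") <- responders == 0L
  attr(out, "stress_ready_pct_of_responders") <-
    if (responders > 0)
      100 * sum(out$count[out$model == "stress_ready"]) / responders
    else NA_real_
  out
}
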