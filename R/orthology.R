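# Ortholog identification from reciprocal protein-alignment hits.
#
# Orthology between the two species is defined operationally as the best
# bidirectional hit (BBH): gene a in species A and gene b in species B are
# orthologs iff b is a's single best alignment hit against the B proteome and
# a is b's single best hit against the A proteome. Gene symbols are then
# transferred from a reference proteome (e.g., Arabidopsis) via one-way best
# hits, and each paired partner inherits the same symbol.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse a 12-column tabular alignment hit file
#'
#' Reads the standard tab-separated hit layout (BLAST `outfmt 6`):
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score. Self-hits
#' (query == subject) are retained but flagged in the `self_hit` column.
#'
#' @param path Path to a tab-separated hit file with at least 12 columns.
#' @return A data frame of hit records with standard column names plus
#'   `self_hit` (logical).
#' @examples
#' tf <- tempfile()
#' writeLines("g1\tg2\t90.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\t200", tf)
#' parse_hit_table(tf)
#' @export
parse_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(HIT_COLUMNS)), HIT_COLUMNS))
    num <- c("percent_identity", "length", "mismatch", "gapopen", "qstart",
             "qend", "sstart", "send", "evalue", "bitscore")
    for (cn in num) out[[cn]] <- numeric(0)
    out$self_hit <- logical(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad) > 0L)
    stopf("malformed hit table '%s': line %d has %d columns (>= 12 required)",
          path, bad[1], nf[bad[1]])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    stringsAsFactors = FALSE)
  num_cols <- HIT_COLUMNS[3:12]
  for (i in seq_along(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, i + 2L]))
    if (anyNA(v)) {
      bad_line <- which(is.na(v))[1]
      stopf("malformed hit table '%s': non-numeric value '%s' in column %s at line %d",
            path, m[bad_line, i + 2L], num_cols[i], bad_line)
    }
    out[[num_cols[i]]] <- v
  }
  if (any(out$evalue < 0) || any(out$bitscore < 0))
    stopf("hit table '%s': negative evalue or bitscore", path)
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stopf("hit table '%s': percent identity outside [0, 100]", path)
  out$self_hit <- out$query_id == out$subject_id
  out
}

# Best subject per query for a whole hit table, as a named character vector.
# "Best" = maximal bitscore, ties broken by minimal evalue, then by
# lexicographically smallest subject id (a documented, deterministic chain;
# the underlying definition is simply "best hit").
best_hit_per_query <- function(hits, ignore_self = FALSE) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  if (ignore_self) hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$query_id)
  stats::setNames(hits$subject_id[first], hits$query_id[first])
}

#' Best hit for a single query
#'
#' @param hits Data frame of hit records (see [parse_hit_table()]).
#' @param query Query gene identifier.
#' @param ignore_self Drop hits where query == subject before ranking
#'   (used when the query species and the reference proteome coincide).
#' @return The best subject id, or `NA_character_` if the query has no hits.
#' @export
best_hit <- function(hits, query, ignore_self = FALSE) {
  hits <- hits[hits$query_id == query, , drop = FALSE]
  b <- best_hit_per_query(hits, ignore_self = ignore_self)
  if (length(b) == 0L) NA_character_ else unname(b[[query]])
}

new_ortholog_map <- function(pairs, unpaired_A, unpaired_B, symbols = NULL) {
  structure(list(pairs = pairs, unpaired_A = unpaired_A,
                 unpaired_B = unpaired_B, symbols = symbols),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d pairs, %d unpaired A genes, %d unpaired B genes\n",
              nrow(x$pairs), length(x$unpaired_A), length(x$unpaired_B)))
  if (!is.null(x$symbols))
    cat(sprintf("  symbols assigned for %d species-A genes\n", length(x$symbols)))
  invisible(x)
}

#' Best bidirectional hits between two species
#'
#' A pair (a, b) is emitted iff b is a's best hit in the A-to-B table and a is
#' b's best hit in the B-to-A table. Every other gene seen in either table
#' lands in the corresponding unpaired set.
#'
#' @param hits_ab Hit records with species-A genes as queries.
#' @param hits_ba Hit records with species-B genes as queries.
#' @return An `ortholog_map`: `pairs` (data frame with `gene_A`, `gene_B`),
#'   `unpaired_A`, `unpaired_B`.
#' @export
best_bidirectional_hits <- function(hits_ab, hits_ba) {
  shared <- intersect(unique(hits_ab$query_id), unique(hits_ba$query_id))
  if (length(shared) > 0L)
    stopf("gene(s) appear as query in both hit tables (mislabelled input?): %s",
          paste(utils::head(shared, 3), collapse = ", "))
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  a <- names(best_ab)
  b <- unname(best_ab)
  reciprocal <- !is.na(match(b, names(best_ba))) & best_ba[b] == a
  reciprocal[is.na(reciprocal)] <- FALSE
  pairs <- data.frame(gene_A = a[reciprocal], gene_B = b[reciprocal],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_A), , drop = FALSE]
  rownames(pairs) <- NULL
  genes_A <- sort(unique(c(hits_ab$query_id, hits_ba$subject_id)))
  genes_B <- sort(unique(c(hits_ba$query_id, hits_ab$subject_id)))
  new_ortholog_map(pairs,
                   unpaired_A = setdiff(genes_A, pairs$gene_A),
                   unpaired_B = setdiff(genes_B, pairs$gene_B))
}

#' Transfer gene symbols from a reference proteome
#'
#' Each species-A gene takes the subject id of its best hit against the
#' reference proteome as its symbol; the paired species-B gene inherits the
#' same symbol. Genes without a reference hit keep no symbol. Symbols need
#' not be unique.
#'
#' @param map An `ortholog_map`.
#' @param hits_to_reference Hit records with species-A genes as queries and
#'   reference proteins as subjects.
#' @param ignore_self Drop self-hits (when species A and the reference
#'   proteome coincide).
#' @return The map with `symbols` (named character vector over species-A
#'   genes) filled in and a `symbol` column added to `pairs`.
#' @export
assign_symbols <- function(map, hits_to_reference, ignore_self = FALSE) {
  stopifnot(inherits(map, "ortholog_map"))
  sym <- best_hit_per_query(hits_to_reference, ignore_self = ignore_self)
  map$symbols <- sym
  map$pairs$symbol <- unname(sym[map$pairs$gene_A])
  map
}

#' Write an ortholog map to disk
#'
#' Emits a 3-column TSV (gene_A, gene_B, symbol) plus one unpaired-gene list
#' per species alongside it.
#'
#' @param map An `ortholog_map`.
#' @param path Output TSV path; unpaired lists are written to
#'   `<path>.unpaired_A.txt` and `<path>.unpaired_B.txt`.
#' @return Invisibly, `path`.
#' @export
write_ortholog_map <- function(map, path) {
  df <- map$pairs
  if (is.null(df$symbol)) df$symbol <- NA_character_
  write_tsv(df, path)
  writeLines(map$unpaired_A, paste0(path, ".unpaired_A.txt"))
  writeLines(map$unpaired_B, paste0(path, ".unpaired_B.txt"))
  invisible(path)
}
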