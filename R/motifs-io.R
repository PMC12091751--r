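# Position weight matrices, MEME-minimal I/O, and promoter extraction.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param motif_id Motif identifier.
#' @param matrix 4 x w matrix of base probabilities; rows A, C, G, T; each
#'   column must sum to 1 (tolerance 1e-9).
#' @param tf_id Transcription-factor gene the motif belongs to (optional).
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, matrix, tf_id = NA_character_,
                background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L || ncol(matrix) < 1L)
    stopf("pwm '%s': matrix must be 4 x w with w >= 1", motif_id)
  rownames(matrix) <- DNA_BASES
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    stopf("pwm '%s': column(s) do not sum to 1", motif_id)
  if (any(matrix < 0)) stopf("pwm '%s': negative probabilities", motif_id)
  if (abs(sum(background) - 1) > 1e-9)
    stopf("pwm '%s': background must sum to 1", motif_id)
  structure(list(motif_id = motif_id, tf_id = tf_id, matrix = matrix,
                 background = stats::setNames(background, DNA_BASES)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (tf: %s), width %d\n", x$motif_id, x$tf_id,
              ncol(x$matrix)))
  invisible(x)
}

#' Width of a PWM
#' @param x A `pwm`.
#' @return Integer motif width.
#' @export
pwm_width <- function(x) ncol(x$matrix)

#' Read motifs from a MEME-minimal file
#'
#' Supports the minimal dialect: a `Background letter frequencies` block
#' (optional, uniform assumed otherwise) and `MOTIF <id> [<alt id>]` blocks
#' each followed by `letter-probability matrix:` and w rows of 4 numbers
#' (A C G T). The alternate name, when present, is taken as the TF id.
#'
#' @param path MEME file path.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L) {
    toks <- strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- stats::setNames(vals[!is.na(vals)][1:4], toks[is.na(vals)][1:4])
    bg <- unname(bg[DNA_BASES])
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(lines[s], "\\s+")[[1]]
    motif_id <- hdr[2]
    tf_id <- if (length(hdr) >= 3L) hdr[3] else NA_character_
    lp <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(lp)) stopf("MEME file '%s': motif %s has no probability matrix",
                         path, motif_id)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    m <- t(vapply(strsplit(rows, "\\s+"),
                  function(f) as.numeric(f[nzchar(f)])[1:4], numeric(4)))
    out[[motif_id]] <- pwm(motif_id, t(m), tf_id = tf_id, background = bg)
  }
  out
}

#' Write motifs to a MEME-minimal file
#'
#' @param pwms List of `pwm` objects (assumed to share a background).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), ""),
             con)
  for (p in pwms) {
    hdr <- if (is.na(p$tf_id)) sprintf("MOTIF %s", p$motif_id)
           else sprintf("MOTIF %s %s", p$motif_id, p$tf_id)
    writeLines(hdr, con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       pwm_width(p)), con)
    for (j in seq_len(pwm_width(p)))
      writeLines(paste(sprintf("%.6f", p$matrix[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Extract promoter sequences upstream of gene starts
#'
#' Promoters are the 2 kb (by default) upstream of the strand-aware
#' transcription start, clipped at contig boundaries: a plus-strand gene
#' starting at s yields bases [max(1, s - upstream), s - 1]; a minus-strand
#' gene ending at e yields the reverse complement of
#' [e + 1, min(contig length, e + upstream)]. Coordinates are 1-based
#' inclusive. Zero-length promoters (gene flush with the contig edge) are
#' dropped with a warning.
#'
#' @param genome A `Biostrings::DNAStringSet` (or named character vector) of
#'   contigs.
#' @param coords Data frame with columns `contig`, `start`, `end`, `gene`,
#'   `strand` (`+`/`-`); a BED-like 6th `score` column is tolerated.
#' @param upstream Promoter length in nt (default 2000).
#' @return A `DNAStringSet` named by gene, uppercase.
#' @export
extract_promoters <- function(genome, coords, upstream = 2000) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(c("contig", "start", "end", "gene", "strand"), names(coords))
  if (length(miss) > 0L)
    stopf("coordinate table missing column(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(coords$contig), names(genome))
  if (length(unknown) > 0L)
    stopf("gene(s) on unknown contig(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(coords))
  keep <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    L <- clen[[coords$contig[i]]]
    if (coords$strand[i] == "+") {
      from <- max(1L, coords$start[i] - upstream)
      to <- coords$start[i] - 1L
    } else {
      from <- coords$end[i] + 1L
      to <- min(L, coords$end[i] + upstream)
    }
    if (to < from || to < 1L || from > L) { keep[i] <- FALSE; next }
    s <- Biostrings::subseq(genome[[coords$contig[i]]], from, to)
    if (coords$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
    keep[i] <- TRUE
  }
  if (any(!keep))
    warnf("dropping %d gene(s) with empty promoters at contig edges",
          sum(!keep))
  out <- Biostrings::DNAStringSet(toupper(seqs[keep]))
  names(out) <- coords$gene[keep]
  out
}
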