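# Calling transcriptionally active transcripts: sense read density over the
# transcript body (TSS + 1 kb to the annotated gene end), with the activity
# cutoff chosen by maximal accuracy against labelled expressed /
# non-expressed genes.

#' Transcript body interval
#'
#' The body of a transcript runs from 1 kb downstream of the TSS (in the
#' direction of transcription) to the annotated gene end.  Transcripts at or
#' below `min_len_bp` (default 3 kb) carry no body and return `NULL`, as do
#' degenerate cases where the offset consumes the whole transcript.
#'
#' @param t one-row `transcript_table` entry.
#' @param offset_bp downstream offset from the TSS excluded from the body.
#' @param min_len_bp minimum transcript length to carry a body.
#' @return one-row interval data frame on the transcript strand, or `NULL`.
#' @export
transcript_body <- function(t, offset_bp = 1000, min_len_bp = 3000) {
  stopifnot(offset_bp >= 0, nrow(t) == 1)
  len <- t$end - t$start
  if (len <= min_len_bp || offset_bp >= len) return(NULL)
  if (t$strand == "+")
    genomic_intervals(t$chrom, t$start + offset_bp, t$end, "+")
  else
    genomic_intervals(t$chrom, t$start, t$end - offset_bp, "-")
}

#' Sense read density over transcript bodies
#'
#' @param transcripts a `transcript_table`.
#' @param track a `read_track`.
#' @param mapability a `mapability_track`.
#' @inheritParams transcript_body
#' @inheritParams window_density
#' @return data frame (accession, gene_symbol, length, density); transcripts
#'   without a body, or with undefined density, get `NA`.
#' @export
transcript_body_density <- function(transcripts, track, mapability,
                                    offset_bp = 1000, min_len_bp = 3000,
                                    map_floor = 0.05) {
  dens <- rep(NA_real_, nrow(transcripts))
  has_body <- transcripts$length > min_len_bp & transcripts$length > offset_bp
  if (any(has_body)) {
    tt <- transcripts[has_body, , drop = FALSE]
    bodies <- genomic_intervals(tt$chrom,
                                ifelse(tt$strand == "+", tt$start + offset_bp,
                                       tt$start),
                                ifelse(tt$strand == "+", tt$end,
                                       tt$end - offset_bp),
                                tt$strand)
    dens[has_body] <- window_density(track, bodies, mapability, "sense",
                                     map_floor)
  }
  data.frame(accession = transcripts$accession,
             gene_symbol = transcripts$gene_symbol,
             length = transcripts$length, density = dens,
             stringsAsFactors = FALSE)
}

#' Choose an activity cutoff by maximal accuracy
#'
#' Scans every observed density (plus one value above the maximum, the
#' all-negative rule) as a candidate threshold for the rule
#' "density >= cutoff means expressed", and returns the cutoff maximising
#' accuracy `(TP + TN) / (P + N)`.  Ties go to the smallest such cutoff.
#' The full ROC curve is returned alongside.
#'
#' @param densities named numeric vector (names are transcript ids).
#' @param labels named character vector, values `"expressed"` or
#'   `"non-expressed"`, same names as `densities`.
#' @return an object of class `roc_result`: list with `cutoff`, `accuracy`,
#'   `sensitivity`, `specificity`, and `curve` (data frame cutoff, tpr, fpr,
#'   accuracy sorted by increasing cutoff).
#' @export
maximal_accuracy_cutoff <- function(densities, labels) {
  labels <- labels[names(densities)]
  if (any(is.na(labels))) stop("every density needs a label")
  if (any(is.na(densities))) stop("every labelled transcript needs a defined density")
  pos <- labels == "expressed"
  if (!any(pos) || all(pos)) stop("both label classes must be non-empty")
  P <- sum(pos); N <- sum(!pos)
  cand <- sort(unique(densities))
  cand <- c(cand, max(cand) + 1)  # the all-negative rule
  # called expressed: density >= cutoff
  tp <- vapply(cand, function(cu) sum(densities[pos] >= cu), 0)
  fp <- vapply(cand, function(cu) sum(densities[!pos] >= cu), 0)
  tpr <- tp / P
  fpr <- fp / N
  acc <- (tp + (N - fp)) / (P + N)
  best <- which.max(acc)  # which.max takes the first = smallest cutoff
  structure(list(cutoff = cand[best], accuracy = acc[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 curve = data.frame(cutoff = cand, tpr = tpr, fpr = fpr,
                                    accuracy = acc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Maximal-accuracy cutoff: %.4g reads/kb/mapability\n", x$cutoff))
  cat(sprintf("  accuracy %.4f, sensitivity %.4f, specificity %.4f (%d thresholds scanned)\n",
              x$accuracy, x$sensitivity, x$specificity, nrow(x$curve)))
  invisible(x)
}

#' Call active transcripts at a density cutoff
#'
#' A transcript is active when its body density is at least `cutoff`
#' (boundary inclusive).  Also reports the subset collapsed to unique gene
#' symbols, keeping the longest transcript per symbol.
#'
#' @param body_density data frame from [transcript_body_density()].
#' @param cutoff activity threshold (reads/kb/mapability).
#' @return list with `active` (accessions), `unique_symbols` (data frame
#'   gene_symbol, accession of the longest active transcript per symbol).
#' @export
call_active_transcripts <- function(body_density, cutoff) {
  stopifnot(cutoff >= 0)
  act <- body_density[!is.na(body_density$density) &
                        body_density$density >= cutoff, , drop = FALSE]
  act <- act[order(act$gene_symbol, -act$length, act$accession), , drop = FALSE]
  uniq <- act[!duplicated(act$gene_symbol), c("gene_symbol", "accession"),
              drop = FALSE]
  rownames(uniq) <- NULL
  list(active = act$accession, unique_symbols = uniq)
}
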