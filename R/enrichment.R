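# Co-occurrence of BEST predictions with chromatin peak sets against random
# background windows, and input-normalised chromatin-mark representation.

#' Sample random background windows avoiding a mask
#'
#' Draws `n` seeded random windows of `window_bp` from the non-overlapping
#' genome tiling (the same search space the scan uses), rejecting any that
#' intersect the exclusion mask or the optional extra exclusions (e.g. the
#' peak set under test, or the predictions themselves).
#'
#' @param n number of windows.
#' @param window_bp window width.
#' @param mask an `exclusion_mask` (may be empty).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param seed RNG seed.
#' @param extra_exclusions optional interval data frame of further regions
#'   to avoid.
#' @param max_tries placement attempts per window.
#' @return interval data frame of `n` windows.
#' @export
sample_background_windows <- function(n, window_bp, mask, chrom_sizes,
                                      seed = 1, extra_exclusions = NULL,
                                      max_tries = 1000) {
  stopifnot(n > 0, window_bp > 0)
  full_mask <- unclass(mask)
  if (!is.null(extra_exclusions) && nrow(extra_exclusions) > 0) {
    both <- rbind(mask_to_intervals(full_mask),
                  extra_exclusions[c("chrom", "start", "end")] |>
                    (\(d) { d$strand <- "*"; d })())
    full_mask <- as_mask(both)
  }
  chroms <- names(chrom_sizes)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(chroms, 1, prob = chrom_sizes)
        nt <- floor(chrom_sizes[ch] / window_bp)
        if (nt < 1) next
        s <- window_bp * (sample.int(nt, 1) - 1)
        if (mask_hits(full_mask, ch, s, s + window_bp)) next
        out[[i]] <- data.frame(chrom = ch, start = s, end = s + window_bp,
                               strand = "*", stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place background window %d of %d after %d tries",
                     i, n, max_tries))
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Two-tailed Pearson chi-squared without continuity correction (df = 1),
#' the large-count regime appropriate for genome-scale window counts.
#'
#' @param tab 2x2 matrix of non-negative counts (rows: prediction vs
#'   background; columns: overlapping vs not).
#' @return list with `chi2` and `p`.
#' @export
chi_squared_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: zero marginal")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Overlap enrichment of windows against background
#'
#' Compares the fraction of observed windows overlapping a peak set with
#' the fraction among background windows: fold = observed frequency /
#' background frequency, with a two-tailed Pearson chi-squared test on the
#' 2x2 overlap table.
#'
#' @param windows observed interval data frame (e.g. high-confidence BEST
#'   predictions).
#' @param background background interval data frame.
#' @param peaks a `peak_set`.
#' @param min_overlap_bp minimum intersection to count as overlap.
#' @return object of class `enrichment_result`: list with `peak_set`,
#'   `n_obs`, `n_bg`, `frac_obs`, `frac_bg`, `fold`, `chi2`, `p`, `table`.
#' @export
overlap_enrichment <- function(windows, background, peaks,
                               min_overlap_bp = 1) {
  a <- sum(overlaps_peaks(windows, peaks, min_overlap_bp))
  c_ <- sum(overlaps_peaks(background, peaks, min_overlap_bp))
  n_obs <- nrow(windows); n_bg <- nrow(background)
  tab <- matrix(c(a, n_obs - a, c_, n_bg - c_), 2, 2, byrow = TRUE,
                dimnames = list(c("observed", "background"),
                                c("overlap", "no_overlap")))
  test <- chi_squared_2x2(tab)
  frac_obs <- a / n_obs; frac_bg <- c_ / n_bg
  structure(list(peak_set = attr(peaks, "name"), n_obs = n_obs, n_bg = n_bg,
                 frac_obs = frac_obs, frac_bg = frac_bg,
                 fold = if (frac_bg > 0) frac_obs / frac_bg else Inf,
                 chi2 = test$chi2, p = test$p, table = tab),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap enrichment vs %s: %.1f%% of %d observed vs %.1f%% of %d background (%.2f-fold)\n",
              x$peak_set %||% "peaks", 100 * x$frac_obs, x$n_obs,
              100 * x$frac_bg, x$n_bg, x$fold))
  cat(sprintf("  chi-squared = %.4g, two-tailed p = %.3g\n", x$chi2, x$p))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

track_reads_per_bp <- function(track, regions) {
  tot <- 0
  for (ch in unique(regions$chrom)) {
    sel <- regions$chrom == ch
    tot <- tot +
      sum(count_anchors(track, ch, regions$start[sel], regions$end[sel], "+")) +
      sum(count_anchors(track, ch, regions$start[sel], regions$end[sel], "-"))
  }
  tot / sum(regions$end - regions$start)
}

#' Input-normalised chromatin-mark representation at loci
#'
#' Pooled read density (reads/bp, both strands) of a mark at the given loci,
#' divided by its pooled density at length-matched background regions, and
#' then divided by the same enrichment computed for the sequencing input:
#' `ln_fold = ln[(treat@loci / treat@bg) / (input@loci / input@bg)]`.
#' Supply a list of treatment tracks (replicates) to get per-replicate
#' values, their mean, and standard deviation.
#'
#' @param treatment a `read_track` or list of replicate `read_track`s for
#'   the mark.
#' @param input the control (input) `read_track`.
#' @param loci interval data frame (e.g. high-confidence BEST windows).
#' @param background length-matched background interval data frame.
#' @param name mark label.
#' @return object of class `mark_representation`: list with `mark`,
#'   `ln_fold` (mean over replicates), `replicates`, `sd`; `ln_fold` is `NA`
#'   (flagged undefined) when any pooled density is zero.
#' @export
mark_representation <- function(treatment, input, loci, background,
                                name = "mark") {
  reps <- if (inherits(treatment, "read_track")) list(treatment) else treatment
  in_l <- track_reads_per_bp(input, loci)
  in_b <- track_reads_per_bp(input, background)
  vals <- vapply(reps, function(tr) {
    t_l <- track_reads_per_bp(tr, loci)
    t_b <- track_reads_per_bp(tr, background)
    if (t_l <= 0 || t_b <= 0 || in_l <= 0 || in_b <= 0) return(NA_real_)
    log((t_l / t_b) / (in_l / in_b))
  }, 0)
  structure(list(mark = name, ln_fold = mean(vals),
                 replicates = vals,
                 sd = if (length(vals) > 1) stats::sd(vals) else NA_real_),
            class = "mark_representation")
}

#' @export
print.mark_representation <- function(x, ...) {
  cat(sprintf("%s: ln fold-enrichment over background = %.4f", x$mark,
              x$ln_fold))
  if (length(x$replicates) > 1)
    cat(sprintf(" (sd %.4f over %d replicates)", x$sd, length(x$replicates)))
  cat("\n")
  invisible(x)
}
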