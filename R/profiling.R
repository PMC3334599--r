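# Proportional-distance sense/antisense metaprofiles at peaks and genes,
# peak categorisation, and the promoter-proximal pausing index.
#
# Proportional distance: genomic offset from the peak start divided by peak
# length, so every peak interior maps to [0, 1] regardless of size; flanks
# extend below 0 and above 1 (a 150-bp bin next to a 300-bp peak spans 0.5
# proportional units).

#' Categorise a peak relative to the annotation
#'
#' `transcribed_intragenic` if the peak intersects any active transcript
#' (active takes precedence), `nontranscribed_intragenic` if it intersects
#' only inactive transcripts, `intergenic` otherwise.
#'
#' @param peaks a `peak_set` or interval data frame.
#' @param transcripts full `transcript_table`.
#' @param active_accessions accessions of active transcripts.
#' @return character vector of categories, one per peak.
#' @export
categorize_peaks <- function(peaks, transcripts, active_accessions) {
  act <- transcripts[transcripts$accession %in% active_accessions, ,
                     drop = FALSE]
  in_active <- overlaps_peaks(peaks,
                              genomic_intervals(act$chrom, act$start,
                                                act$end))
  in_any <- overlaps_peaks(peaks,
                           genomic_intervals(transcripts$chrom,
                                             transcripts$start,
                                             transcripts$end))
  ifelse(in_active, "transcribed_intragenic",
         ifelse(in_any, "nontranscribed_intragenic", "intergenic"))
}

#' Discard promoter/gene-end-proximal peaks before profiling
#'
#' A peak is retained only when its flank-extended interval
#' `[start - flank_bp, end + flank_bp)` stays at least `radius_bp` away
#' from every TSS, annotated gene end, and H3K4me3 peak.
#'
#' @param peaks a `peak_set`.
#' @param transcripts full `transcript_table`.
#' @param h3k4me3 optional `peak_set` of promoter-mark peaks.
#' @param flank_bp flank extension applied to each peak.
#' @param radius_bp required clearance.
#' @return the retained subset of `peaks`.
#' @export
filter_promoter_proximal <- function(peaks, transcripts, h3k4me3 = NULL,
                                     flank_bp = 5000, radius_bp = 2000) {
  stopifnot(flank_bp >= 0, radius_bp >= 0)
  mask <- unclass(exclusion_mask(transcripts, h3k4me3, radius_bp))
  if (length(mask) == 0 || nrow(peaks) == 0) return(peaks)
  hit <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    hit[sel] <- mask_hits(mask, ch, pmax(0, peaks$start[sel] - flank_bp),
                          peaks$end[sel] + flank_bp)
  }
  out <- peaks[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportional-coordinate bins around one peak
#'
#' Tiles `bin_bp` windows outward from the peak boundaries: interior bins
#' from the peak start (last one truncated at the peak end), upstream bins
#' leftward from the peak start, downstream bins rightward from the peak
#' end, each flank covering `flank_bp` (outermost bin truncated).  Each
#' genomic bin is mapped to proportional coordinates
#' `(offset from peak start) / peak length`, so for a 300-bp peak with
#' 150-bp bins the first upstream bin spans -0.5 to 0, the interior bins 0
#' to 0.5 and 0.5 to 1, and the first downstream bin 1 to 1.5.
#'
#' @param peak_start,peak_end peak coordinates (0-based half-open).
#' @param flank_bp flank width on each side.
#' @param bin_bp bin width.
#' @return data frame with columns start, end (genomic), prop_lo, prop_hi,
#'   zone (`"upstream"`, `"peak"`, `"downstream"`), ordered left to right;
#'   bins extending below coordinate 0 are dropped.
#' @export
proportional_bins <- function(peak_start, peak_end, flank_bp = 5000,
                              bin_bp = 150) {
  L <- peak_end - peak_start
  stopifnot(L > 0, bin_bp > 0, flank_bp >= 0)
  tile_right <- function(from, to) {
    e <- seq(from, to, by = bin_bp)
    if (e[length(e)] < to) e <- c(e, to)
    cbind(start = e[-length(e)], end = e[-1])
  }
  tile_left <- function(from, to) {  # tile leftward from `to` down to `from`
    e <- seq(to, from, by = -bin_bp)
    if (e[length(e)] > from) e <- c(e, from)
    e <- rev(e)
    cbind(start = e[-length(e)], end = e[-1])
  }
  parts <- list()
  if (flank_bp > 0)
    parts$up <- cbind(tile_left(peak_start - flank_bp, peak_start),
                      zone = 1)
  parts$peak <- cbind(tile_right(peak_start, peak_end), zone = 2)
  if (flank_bp > 0)
    parts$down <- cbind(tile_right(peak_end, peak_end + flank_bp), zone = 3)
  m <- do.call(rbind, parts)
  df <- data.frame(start = m[, "start"], end = m[, "end"],
                   prop_lo = (m[, "start"] - peak_start) / L,
                   prop_hi = (m[, "end"] - peak_start) / L,
                   zone = c("upstream", "peak", "downstream")[m[, "zone"]])
  df <- df[df$start >= 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# length-weighted mean over defined bins; NA if nothing defined
lw_mean <- function(d, len) {
  ok <- !is.na(d)
  if (!any(ok)) return(NA_real_)
  sum(d[ok] * len[ok]) / sum(len[ok])
}

aggregate_profile <- function(contribs, grid_lo, grid_hi, grid_step) {
  edges <- seq(grid_lo, grid_hi, by = grid_step)
  nb <- length(edges) - 1
  sum_s <- sum_a <- cnt_s <- cnt_a <- numeric(nb)
  region_seen <- matrix(FALSE, length(contribs), nb)
  for (r in seq_along(contribs)) {
    d <- contribs[[r]]
    mid <- (d$prop_lo + d$prop_hi) / 2
    gi <- floor((mid - grid_lo) / grid_step) + 1
    ok <- gi >= 1 & gi <= nb
    for (k in which(ok)) {
      if (!is.na(d$rel_sense[k])) {
        sum_s[gi[k]] <- sum_s[gi[k]] + d$rel_sense[k]
        cnt_s[gi[k]] <- cnt_s[gi[k]] + 1
      }
      if (!is.na(d$rel_antisense[k])) {
        sum_a[gi[k]] <- sum_a[gi[k]] + d$rel_antisense[k]
        cnt_a[gi[k]] <- cnt_a[gi[k]] + 1
      }
      region_seen[r, gi[k]] <- TRUE
    }
  }
  out <- data.frame(bin_lo = edges[-(nb + 1)], bin_hi = edges[-1],
                    mean_sense = ifelse(cnt_s > 0, sum_s / pmax(cnt_s, 1), 0),
                    mean_antisense = ifelse(cnt_a > 0,
                                            sum_a / pmax(cnt_a, 1), 0),
                    n_regions = colSums(region_seen))
  class(out) <- c("proportional_profile", class(out))
  out
}

#' Sense/antisense proportional-distance profile at peaks
#'
#' For each (unstranded) peak, sense ("sense/plus") and antisense read
#' densities are computed in `bin_bp` windows from the peak start to the end
#' of the `flank_bp` flanking regions on either side, converted to
#' proportional distance, and divided by the average density over the whole
#' peak + flank region (per strand), so a flat region has relative density
#' 1 everywhere.  Region profiles are then averaged per strand onto a fixed
#' proportional grid; a region with zero total density on both strands is
#' skipped and counted.
#'
#' @param peaks a `peak_set` (after [filter_promoter_proximal()]).
#' @param track a `read_track`.
#' @param mapability a `mapability_track`.
#' @param flank_bp flank width.
#' @param bin_bp bin width.
#' @param grid_lo,grid_hi,grid_step fixed proportional aggregation grid.
#' @param map_floor mapability floor for defined bin densities.
#' @return data frame of class `proportional_profile` (bin_lo, bin_hi,
#'   mean_sense, mean_antisense, n_regions) with attribute `n_skipped`.
#' @export
proportional_profile <- function(peaks, track, mapability, flank_bp = 5000,
                                 bin_bp = 150, grid_lo = -2, grid_hi = 3,
                                 grid_step = 0.1, map_floor = 0.05) {
  stopifnot(nrow(peaks) > 0)
  contribs <- list()
  n_skipped <- 0
  for (i in seq_len(nrow(peaks))) {
    b <- proportional_bins(peaks$start[i], peaks$end[i], flank_bp, bin_bp)
    win <- genomic_intervals(peaks$chrom[i], b$start, b$end, "*")
    ds <- window_density(track, win, mapability, "plus", map_floor)
    da <- window_density(track, win, mapability, "minus", map_floor)
    len <- b$end - b$start
    ms <- lw_mean(ds, len); ma <- lw_mean(da, len)
    sense_ok <- !is.na(ms) && ms > 0
    anti_ok <- !is.na(ma) && ma > 0
    if (!sense_ok && !anti_ok) { n_skipped <- n_skipped + 1; next }
    b$rel_sense <- if (sense_ok) ds / ms else rep(NA_real_, nrow(b))
    b$rel_antisense <- if (anti_ok) da / ma else rep(NA_real_, nrow(b))
    contribs[[length(contribs) + 1]] <- b
  }
  if (!length(contribs)) stop("no peak had non-zero density to profile")
  out <- aggregate_profile(contribs, grid_lo, grid_hi, grid_step)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Strand-aware proportional metaprofile over active genes
#'
#' Proportional coordinate 0 at the TSS and 1 at the gene end (so minus
#' strand genes contribute mirror-reversed), with flanks of
#' `flank_fraction` gene lengths on each side.  Per transcript, sense and
#' antisense densities in `n_bins` equal proportional bins are divided by
#' the transcript's average density over the profiled extent, then averaged
#' across transcripts; transcripts with zero signal on both strands are
#' skipped.  A track with no reads at all yields an all-zero profile.
#'
#' @param transcripts `transcript_table` of (active) transcripts.
#' @param track a `read_track`.
#' @param mapability a `mapability_track`.
#' @param n_bins number of proportional bins across the profiled extent.
#' @param flank_fraction flank width in units of gene length.
#' @param map_floor mapability floor.
#' @return data frame of class `proportional_profile`.
#' @export
gene_metaprofile <- function(transcripts, track, mapability, n_bins = 40,
                             flank_fraction = 0.5, map_floor = 0.05) {
  stopifnot(nrow(transcripts) > 0, n_bins >= 2)
  pedges <- seq(-flank_fraction, 1 + flank_fraction, length.out = n_bins + 1)
  contribs <- list()
  n_skipped <- 0
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    L <- t$end - t$start
    if (t$strand == "+") {
      gs <- round(t$start + pedges[-(n_bins + 1)] * L)
      ge <- round(t$start + pedges[-1] * L)
    } else {
      gs <- round(t$end - pedges[-1] * L)
      ge <- round(t$end - pedges[-(n_bins + 1)] * L)
    }
    keep <- gs >= 0 & ge > gs
    if (!any(keep)) next
    win <- genomic_intervals(t$chrom, gs[keep], ge[keep], t$strand)
    ds <- da <- rep(NA_real_, n_bins)
    ds[keep] <- window_density(track, win, mapability, "sense", map_floor)
    da[keep] <- window_density(track, win, mapability, "antisense",
                               map_floor)
    len <- abs(ge - gs)
    ms <- lw_mean(ds, len); ma <- lw_mean(da, len)
    sense_ok <- !is.na(ms) && ms > 0
    anti_ok <- !is.na(ma) && ma > 0
    if (!sense_ok && !anti_ok) { n_skipped <- n_skipped + 1; next }
    contribs[[length(contribs) + 1]] <- data.frame(
      prop_lo = pedges[-(n_bins + 1)], prop_hi = pedges[-1],
      rel_sense = if (sense_ok) ds / ms else rep(NA_real_, n_bins),
      rel_antisense = if (anti_ok) da / ma else rep(NA_real_, n_bins))
  }
  step <- pedges[2] - pedges[1]
  if (!length(contribs)) {
    out <- data.frame(bin_lo = pedges[-(n_bins + 1)], bin_hi = pedges[-1],
                      mean_sense = 0, mean_antisense = 0, n_regions = 0L)
    class(out) <- c("proportional_profile", class(out))
  } else {
    out <- aggregate_profile(contribs, -flank_fraction, 1 + flank_fraction,
                             step)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @export
plot.proportional_profile <- function(x, ...) {
  mids <- (x$bin_lo + x$bin_hi) / 2
  ylim <- range(0, x$mean_sense, x$mean_antisense, na.rm = TRUE)
  graphics::plot(mids, x$mean_sense, type = "l", col = "darkorange",
                 lwd = 2, xlab = "proportional distance",
                 ylab = "relative read density", ylim = ylim, ...)
  graphics::lines(mids, x$mean_antisense, col = "steelblue", lwd = 2)
  graphics::abline(v = c(0, 1), lty = 3)
  graphics::legend("topright", c("sense", "antisense"),
                   col = c("darkorange", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

#' Promoter-proximal pausing index
#'
#' Ratio of the sense read density in the promoter-proximal window
#' `[TSS, TSS + promoter_window_bp)` (in the direction of transcription) to
#' the sense density over the transcript body (TSS + `body_offset_bp` to the
#' gene end).  High values indicate stalled polymerase.  The index is `NA`
#' (flagged undefined) when the body density is zero or either density is
#' undefined, and for transcripts too short to carry both windows.
#'
#' @param transcripts a `transcript_table`.
#' @param track a `read_track`.
#' @param mapability a `mapability_track`.
#' @param promoter_window_bp promoter-proximal window width.
#' @param body_offset_bp offset from TSS to the body start.
#' @param map_floor mapability floor.
#' @return data frame (accession, promoter_density, body_density, index).
#' @export
pausing_index <- function(transcripts, track, mapability,
                          promoter_window_bp = 1000, body_offset_bp = 1000,
                          map_floor = 0.05) {
  n <- nrow(transcripts)
  prom <- body <- idx <- rep(NA_real_, n)
  long_enough <- transcripts$length > body_offset_bp + promoter_window_bp
  for (i in which(long_enough)) {
    t <- transcripts[i, ]
    pw <- if (t$strand == "+")
      genomic_intervals(t$chrom, t$tss, t$tss + promoter_window_bp, "+")
    else
      genomic_intervals(t$chrom, t$end - promoter_window_bp, t$end, "-")
    bw <- transcript_body(t, body_offset_bp, min_len_bp = 0)
    prom[i] <- window_density(track, pw, mapability, "sense", map_floor)
    body[i] <- window_density(track, bw, mapability, "sense", map_floor)
    if (!is.na(prom[i]) && !is.na(body[i]) && body[i] > 0)
      idx[i] <- prom[i] / body[i]
  }
  data.frame(accession = transcripts$accession, promoter_density = prom,
             body_density = body, index = idx, stringsAsFactors = FALSE)
}
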