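# The core density statistic: reads per kilobase per mapability over
# arbitrary windows and strands.  A read contributes to exactly one window
# (by its anchor position), so counts are exactly additive over partitions.

count_anchors <- function(track, chrom, starts, ends, strand) {
  pos <- if (strand == "+") track$plus[[chrom]] else track$minus[[chrom]]
  if (is.null(pos) || length(pos) == 0) return(rep(0L, length(starts)))
  findInterval(ends - 0.5, pos) - findInterval(starts - 0.5, pos)
}

resolve_strand <- function(window_strand, strand_mode) {
  switch(strand_mode,
         plus = rep("+", length(window_strand)),
         minus = rep("-", length(window_strand)),
         sense = {
           if (any(window_strand == "*"))
             stop("sense/antisense density requires a stranded window")
           window_strand
         },
         antisense = {
           if (any(window_strand == "*"))
             stop("sense/antisense density requires a stranded window")
           ifelse(window_strand == "+", "-", "+")
         },
         stop("strand_mode must be sense, antisense, plus or minus"))
}

#' Read density over windows
#'
#' Computes the read density `count / (length/1000) / mean-mapability`
#' (reads/kb/mapability) for each window.  `strand_mode` `"sense"` resolves
#' to the reads on the window's own strand (so sense on a `-` window counts
#' minus-strand reads), `"antisense"` to the opposite strand, `"plus"` /
#' `"minus"` to an absolute strand regardless of the window.
#'
#' Windows whose mean mapability is at or below `map_floor` get `NA`
#' (density undefined) rather than an arbitrarily inflated value.
#'
#' @param track a `read_track`.
#' @param windows interval data frame (chrom, start, end, strand).
#' @param mapability a `mapability_track`.
#' @param strand_mode one of `"sense"`, `"antisense"`, `"plus"`, `"minus"`.
#' @param map_floor mean-mapability floor below which density is undefined.
#' @return numeric vector of densities (reads/kb/mapability), `NA` where
#'   undefined.
#' @export
window_density <- function(track, windows, mapability, strand_mode = "sense",
                           map_floor = 0.05) {
  stopifnot(nrow(windows) >= 1, all(windows$end > windows$start))
  strands <- resolve_strand(windows$strand, strand_mode)
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    sel <- which(windows$chrom == ch)
    mm <- mapability_mean(mapability, ch, windows$start[sel],
                          windows$end[sel])
    for (s in c("+", "-")) {
      ss <- sel[strands[sel] == s]
      if (!length(ss)) next
      cnt <- count_anchors(track, ch, windows$start[ss], windows$end[ss], s)
      len_kb <- (windows$end[ss] - windows$start[ss]) / 1000
      d <- cnt / len_kb / mm[match(ss, sel)]
      d[mm[match(ss, sel)] <= map_floor] <- NA_real_
      out[ss] <- d
    }
  }
  out
}

#' Binned density profile over a region
#'
#' Tiles `[start, end)` left-to-right (genome coordinates) with contiguous
#' non-overlapping bins of `bin_bp`; a last partial bin is kept and
#' normalised by its own length.
#'
#' @param track a `read_track`.
#' @param region one-row interval data frame.
#' @param bin_bp bin width in bp.
#' @param mapability a `mapability_track`.
#' @inheritParams window_density
#' @return data frame with columns start, end, density (`NA` where the bin's
#'   mapability is at or below the floor).
#' @export
binned_density_profile <- function(track, region, bin_bp,
                                   mapability, strand_mode = "sense",
                                   map_floor = 0.05) {
  stopifnot(nrow(region) == 1, bin_bp > 0,
            region$end - region$start >= bin_bp)
  edges <- seq(region$start, region$end, by = bin_bp)
  if (edges[length(edges)] < region$end) edges <- c(edges, region$end)
  bins <- genomic_intervals(region$chrom, edges[-length(edges)], edges[-1],
                            region$strand)
  bins$density <- window_density(track, bins, mapability, strand_mode,
                                 map_floor)
  bins[c("start", "end", "density")]
}
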