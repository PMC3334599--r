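# Interval plumbing shared by every module.  All coordinates in the package
# are 0-based, half-open [start, end); strand is "+", "-" or "*" (unstranded).

#' Construct a table of genomic intervals
#'
#' The package represents sets of genomic intervals as plain data frames with
#' columns `chrom`, `start`, `end` and `strand`, using 0-based half-open
#' coordinates throughout.  This constructor validates the invariants every
#' interval must satisfy: `start >= 0`, `end > start`, and strand one of
#' `"+"`, `"-"`, `"*"`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand per interval; recycled. `"*"` means unstranded.
#' @return data frame with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must not be NA")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start (0-based half-open)")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Merge overlapping or adjacent intervals
#'
#' Collapses an interval table into a minimal sorted set of disjoint
#' intervals per chromosome (strand is ignored and dropped).
#'
#' @param x interval data frame (chrom, start, end).
#' @return merged data frame sorted by (chrom, start) with strand `"*"`.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- lapply(split(x, x$chrom), function(d) {
    s <- d$start; e <- d$end
    keep_s <- numeric(0); keep_e <- numeric(0)
    cs <- s[1]; ce <- e[1]
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (s[i] <= ce) {
          ce <- max(ce, e[i])
        } else {
          keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
          cs <- s[i]; ce <- e[i]
        }
      }
    }
    keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
    data.frame(chrom = d$chrom[1], start = keep_s, end = keep_e,
               strand = "*", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Internal mask representation: named list chrom -> two-column matrix of
# merged disjoint [start, end) rows, used for O(log n) membership queries.
as_mask <- function(x) {
  m <- merge_intervals(x)
  lapply(split(m, m$chrom), function(d) cbind(start = d$start, end = d$end))
}

mask_to_intervals <- function(mask) {
  if (length(mask) == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  out <- do.call(rbind, lapply(names(mask), function(ch) {
    data.frame(chrom = ch, start = mask[[ch]][, "start"],
               end = mask[[ch]][, "end"], strand = "*",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# TRUE for each query window [start_i, end_i) on `chrom` that intersects the
# mask by >= 1 bp.  starts/ends vectorised.
mask_hits <- function(mask, chrom, starts, ends) {
  m <- mask[[chrom]]
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(starts)))
  # window overlaps some [s,e) iff the last mask start < end also has e > start
  idx <- findInterval(ends - 0.5, m[, "start"])
  hit <- idx >= 1
  hit[hit] <- m[idx[hit], "end"] > starts[hit]
  hit
}

#' Which intervals overlap a peak set
#'
#' @param windows interval data frame.
#' @param peaks a `peak_set` (see [read_peaks()]) or interval data frame.
#' @param min_overlap_bp minimum intersection, in bp, to count as overlap.
#' @return logical vector, one element per row of `windows`.
#' @export
overlaps_peaks <- function(windows, peaks, min_overlap_bp = 1) {
  stopifnot(min_overlap_bp >= 1)
  if (nrow(windows) == 0) return(logical(0))
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(windows)))
  by_chr <- split(peaks, peaks$chrom)
  out <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    p <- by_chr[[windows$chrom[i]]]
    if (is.null(p)) next
    ov <- pmin(p$end, windows$end[i]) - pmax(p$start, windows$start[i])
    out[i] <- any(ov >= min_overlap_bp)
  }
  out
}

#' Fraction of windows overlapping a peak set
#'
#' @inheritParams overlaps_peaks
#' @return fraction in `[0, 1]` of windows with at least `min_overlap_bp`
#'   intersection with any peak.
#' @export
overlap_fraction <- function(windows, peaks, min_overlap_bp = 1) {
  if (nrow(windows) == 0) stop("overlap_fraction: empty window set")
  mean(overlaps_peaks(windows, peaks, min_overlap_bp))
}
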