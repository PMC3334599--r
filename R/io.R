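# Readers and writers for the plain-text genomics formats the tool touches:
# refFlat/BED12 gene tables, BED6/bedGraph stranded reads, wiggle/BED4
# mapability, BED3/BED5 peak sets, and the BED6+3 prediction output.
# Everything is tab-separated UTF-8; coordinates are normalised to 0-based
# half-open on input.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop(sprintf("malformed %s at line %d: '%s' is not numeric",
                 what, lineno[which(is.na(v))[1]], x[which(is.na(v))[1]]))
  v
}

#' Read a transcript annotation table
#'
#' Parses a refFlat-like TSV (`accession  gene_symbol  chrom  strand  txStart
#' txEnd`, extra columns ignored) or a BED6/BED12 file (`chrom start end name
#' score strand`, name used as accession).  Coordinates are interpreted as
#' 0-based half-open in both formats.  The transcription start site (TSS) is
#' the interval start on `+` transcripts and `end - 1` on `-` transcripts;
#' `gene_end` is the opposite terminus.
#'
#' @param path path to the annotation file.
#' @param validated_prefix accession prefix marking curated mRNA models
#'   (default `"NM_"`); transcripts whose accession starts with it get
#'   `is_validated_mrna = TRUE`.
#' @param format `"auto"` (default), `"refflat"` or `"bed"`.
#' @return data frame of class `transcript_table` with columns accession,
#'   gene_symbol, chrom, strand, start, end, tss, gene_end, length,
#'   is_validated_mrna.
#' @export
read_transcripts <- function(path, validated_prefix = "NM_",
                             format = c("auto", "refflat", "bed")) {
  format <- match.arg(format)
  if (!nzchar(validated_prefix)) stop("validated_prefix must be non-empty")
  lines <- read_tsv_lines(path)
  if (length(lines) == 0) {
    tt <- data.frame(accession = character(), gene_symbol = character(),
                     chrom = character(), strand = character(),
                     start = numeric(), end = numeric(), tss = numeric(),
                     gene_end = numeric(), length = numeric(),
                     is_validated_mrna = logical(), stringsAsFactors = FALSE)
    class(tt) <- c("transcript_table", class(tt))
    return(tt)
  }
  f <- split_fields(lines)
  lineno <- seq_along(lines)
  ncols <- lengths(f)
  if (format == "auto") {
    # BED has numeric columns 2 and 3; refFlat has them at 5 and 6
    c23 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
    format <- if (!any(is.na(c23))) "bed" else "refflat"
  }
  if (format == "bed") {
    bad <- which(ncols < 6)
    if (length(bad))
      stop(sprintf("malformed BED transcript line %d: expected >= 6 fields",
                   bad[1]))
    chrom <- vapply(f, `[`, "", 1)
    start <- num_or_stop(vapply(f, `[`, "", 2), "BED start", lineno)
    end <- num_or_stop(vapply(f, `[`, "", 3), "BED end", lineno)
    acc <- vapply(f, `[`, "", 4)
    strand <- vapply(f, `[`, "", 6)
    sym <- acc
  } else {
    bad <- which(ncols < 6)
    if (length(bad))
      stop(sprintf("malformed refFlat line %d: expected >= 6 fields", bad[1]))
    acc <- vapply(f, `[`, "", 1)
    sym <- vapply(f, `[`, "", 2)
    chrom <- vapply(f, `[`, "", 3)
    strand <- vapply(f, `[`, "", 4)
    start <- num_or_stop(vapply(f, `[`, "", 5), "txStart", lineno)
    end <- num_or_stop(vapply(f, `[`, "", 6), "txEnd", lineno)
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("unknown strand symbol '%s' at line %d", strand[bad[1]],
                 bad[1]))
  if (any(end <= start))
    stop(sprintf("transcript with non-positive length at line %d",
                 which(end <= start)[1]))
  tss <- ifelse(strand == "+", start, end - 1)
  gene_end <- ifelse(strand == "+", end - 1, start)
  tt <- data.frame(accession = acc, gene_symbol = sym, chrom = chrom,
                   strand = strand, start = start, end = end, tss = tss,
                   gene_end = gene_end, length = end - start,
                   is_validated_mrna = startsWith(acc, validated_prefix),
                   stringsAsFactors = FALSE)
  class(tt) <- c("transcript_table", class(tt))
  tt
}

# ---- stranded read tracks ---------------------------------------------------

new_read_track <- function(plus, minus, anchor) {
  plus <- lapply(plus, function(p) sort(as.numeric(p)))
  minus <- lapply(minus, function(p) sort(as.numeric(p)))
  structure(list(plus = plus, minus = minus,
                 n_plus = sum(lengths(plus)), n_minus = sum(lengths(minus)),
                 anchor = anchor),
            class = "read_track")
}

#' @export
print.read_track <- function(x, ...) {
  cat(sprintf("Stranded read track: %d plus / %d minus anchors on %d chromosome(s) (anchor = %s)\n",
              x$n_plus, x$n_minus,
              length(union(names(x$plus), names(x$minus))), x$anchor))
  invisible(x)
}

parse_read_file <- function(path, designated, anchor) {
  lines <- read_tsv_lines(path)
  res <- list(plus = list(), minus = list())
  if (length(lines) == 0) return(res)
  f <- split_fields(lines)
  ncols <- lengths(f)
  chrom <- vapply(f, `[`, "", 1)
  start <- num_or_stop(vapply(f, `[`, "", 2), "read start", seq_along(lines))
  end <- num_or_stop(vapply(f, `[`, "", 3), "read end", seq_along(lines))
  if (any(start < 0)) stop("negative read coordinate")
  is_bedgraph <- all(ncols == 4)
  if (is_bedgraph) {
    # per-base read counts: value v over [s, e) places v anchors at each base
    val <- num_or_stop(vapply(f, `[`, "", 4), "bedGraph value",
                       seq_along(lines))
    if (any(val < 0) || any(val != round(val)))
      stop("bedGraph read counts must be non-negative integers")
    pos <- chromv <- vector("list", length(val))
    for (i in seq_along(val)) {
      if (val[i] == 0) next
      pos[[i]] <- rep(seq(start[i], end[i] - 1), each = val[i])
      chromv[[i]] <- rep(chrom[i], val[i] * (end[i] - start[i]))
    }
    pos <- unlist(pos); chromv <- unlist(chromv)
    res[[designated]] <- split(pos, chromv)
    return(res)
  }
  if (any(ncols < 6)) stop("read file must be BED6 or 4-column bedGraph")
  strand <- vapply(f, `[`, "", 6)
  if (!all(strand %in% c("+", "-"))) stop("unknown strand in read file")
  other <- if (designated == "plus") "-" else "+"
  desig_sym <- if (designated == "plus") "+" else "-"
  if (any(strand == other))
    warning(sprintf("%d read(s) in the %s-strand file carry strand '%s'; reassigned per their strand column",
                    sum(strand == other), designated, other))
  pos <- ifelse(strand == "+", start, end - 1)  # 5' end on own strand
  if (anchor == "midpoint") pos <- floor((start + end) / 2)
  res$plus <- split(pos[strand == "+"], chrom[strand == "+"])
  res$minus <- split(pos[strand == "-"], chrom[strand == "-"])
  res
}

#' Read stranded read anchors from per-strand BED6 or bedGraph files
#'
#' Each read is reduced to a single anchor position.  The default anchor is
#' the read's 5' end on its own strand (interval start for `+` reads,
#' `end - 1` for `-` reads), the natural convention for polymerase-position
#' signals; `"midpoint"` is available as an alternative.  bedGraph input is
#' interpreted as per-base read counts.  BED6 reads whose strand column
#' disagrees with the file's designated strand are reassigned (with a
#' warning) according to their strand column.
#'
#' @param path_plus,path_minus per-strand input files.
#' @param anchor `"five_prime"` (default) or `"midpoint"`.
#' @return a `read_track`: per-chromosome sorted anchor vectors per strand.
#' @export
read_stranded_reads <- function(path_plus, path_minus,
                                anchor = c("five_prime", "midpoint")) {
  anchor <- match.arg(anchor)
  p <- parse_read_file(path_plus, "plus", anchor)
  m <- parse_read_file(path_minus, "minus", anchor)
  cat_lists <- function(a, b) {
    chroms <- union(names(a), names(b))
    stats::setNames(lapply(chroms, function(ch)
      c(a[[ch]], b[[ch]])), chroms)
  }
  new_read_track(cat_lists(p$plus, m$plus), cat_lists(p$minus, m$minus),
                 anchor)
}

# build a read_track directly from anchor data frames (chrom, pos, strand)
track_from_anchors <- function(chrom, pos, strand, anchor = "five_prime") {
  new_read_track(split(pos[strand == "+"], chrom[strand == "+"]),
                 split(pos[strand == "-"], chrom[strand == "-"]),
                 anchor)
}

# ---- peak sets --------------------------------------------------------------

#' Read a BED3/BED5 peak set
#'
#' @param path BED file (first three columns used).
#' @param name label for the peak set (defaults to the file name).
#' @return a `peak_set`: interval data frame sorted by (chrom, start) with a
#'   `name` attribute.
#' @export
read_peaks <- function(path, name = basename(path)) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0) {
    ps <- genomic_intervals(character(), numeric(), numeric())[0, ]
  } else {
    f <- split_fields(lines)
    if (any(lengths(f) < 3)) stop("peak BED needs >= 3 columns")
    ps <- genomic_intervals(vapply(f, `[`, "", 1),
                            num_or_stop(vapply(f, `[`, "", 2), "peak start",
                                        seq_along(lines)),
                            num_or_stop(vapply(f, `[`, "", 3), "peak end",
                                        seq_along(lines)))
    ps <- ps[order(ps$chrom, ps$start), , drop = FALSE]
    rownames(ps) <- NULL
  }
  attr(ps, "name") <- name
  class(ps) <- c("peak_set", class(ps))
  ps
}

write_bed3 <- function(x, path) {
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# ---- mapability -------------------------------------------------------------

# A mapability track stores, per chromosome, knot positions and a cumulative
# integral of the piecewise-constant value, so the mean over any window is
# two O(log n) lookups.  Bases not covered by any segment take default_value.
new_mapability <- function(segs, default_value) {
  per <- lapply(segs, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$value < 0 | d$value > 1)) stop("mapability values must be in [0,1]")
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("mapability segments must be non-overlapping")
    # knots: 0, then every segment boundary; rate on [k_i, k_{i+1})
    k <- unique(c(0, d$start, d$end))
    k <- sort(k)
    rate <- rep(default_value, length(k))
    idx <- findInterval(k, d$start)
    cov <- idx >= 1 & k < d$end[pmax(idx, 1)]
    rate[cov] <- d$value[idx[cov]]
    # cumulative integral at each knot
    cum <- c(0, cumsum(rate[-length(k)] * diff(k)))
    list(knots = k, rate = rate, cum = cum)
  })
  structure(list(per_chrom = per, default = default_value),
            class = "mapability_track")
}

#' Constant mapability track
#'
#' @param value mapability everywhere, in `[0, 1]`.
#' @export
flat_mapability <- function(value = 1) {
  stopifnot(value >= 0, value <= 1)
  structure(list(per_chrom = list(), default = value, flat = TRUE),
            class = "mapability_track")
}

#' Read a mapability track
#'
#' Supported formats: UCSC wiggle (`fixedStep` / `variableStep`, 1-based,
#' converted to 0-based half-open) and BED4 (`chrom start end value`,
#' already 0-based).  Values must lie in `[0, 1]`.  Bases outside every
#' segment take `default_value` (0 by default: unannotated sequence is
#' treated as unmappable, the conservative choice).
#'
#' @param path input file.
#' @param default_value value for uncovered bases.
#' @return a `mapability_track`.
#' @export
read_mapability <- function(path, default_value = 0) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) return(new_mapability(list(), default_value))
  is_wig <- any(grepl("^(fixedStep|variableStep)", lines))
  segs <- list()
  if (!is_wig) {
    f <- split_fields(lines)
    if (any(lengths(f) < 4)) stop("BED mapability needs 4 columns")
    df <- data.frame(chrom = vapply(f, `[`, "", 1),
                     start = as.numeric(vapply(f, `[`, "", 2)),
                     end = as.numeric(vapply(f, `[`, "", 3)),
                     value = as.numeric(vapply(f, `[`, "", 4)),
                     stringsAsFactors = FALSE)
    segs <- split(df[c("start", "end", "value")], df$chrom)
  } else {
    recs <- list()
    mode <- NULL; chrom <- NULL; pos <- NULL; step <- NULL; span <- 1
    for (ln in lines) {
      if (startsWith(ln, "fixedStep") || startsWith(ln, "variableStep")) {
        kv <- strsplit(strsplit(ln, "\\s+")[[1]][-1], "=")
        kv <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
        mode <- if (startsWith(ln, "fixedStep")) "fixed" else "variable"
        chrom <- kv[["chrom"]]
        span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
        if (mode == "fixed") {
          pos <- as.numeric(kv[["start"]]) - 1  # wiggle is 1-based
          step <- as.numeric(kv[["step"]])
        }
      } else if (mode == "fixed") {
        recs[[length(recs) + 1]] <- data.frame(chrom = chrom, start = pos,
                                               end = pos + span,
                                               value = as.numeric(ln))
        pos <- pos + step
      } else if (mode == "variable") {
        p <- strsplit(ln, "\\s+")[[1]]
        s <- as.numeric(p[1]) - 1
        recs[[length(recs) + 1]] <- data.frame(chrom = chrom, start = s,
                                               end = s + span,
                                               value = as.numeric(p[2]))
      } else stop("wiggle data before any step declaration")
    }
    df <- do.call(rbind, recs)
    segs <- split(df[c("start", "end", "value")], df$chrom)
  }
  new_mapability(segs, default_value)
}

#' Mean mapability over windows
#'
#' Length-weighted mean of the piecewise-constant mapability value over each
#' `[start, end)` window; uncovered bases contribute the track's default.
#'
#' @param map a `mapability_track`.
#' @param chrom chromosome name (scalar).
#' @param starts,ends window coordinates (vectorised).
#' @return numeric vector of means in `[0, 1]`.
#' @export
mapability_mean <- function(map, chrom, starts, ends) {
  stopifnot(all(ends > starts))
  pc <- map$per_chrom[[chrom]]
  if (is.null(pc)) return(rep(map$default, length(starts)))
  Fx <- function(x) {
    i <- findInterval(x, pc$knots)
    out <- numeric(length(x))
    inside <- i >= 1
    out[inside] <- pc$cum[i[inside]] +
      pc$rate[i[inside]] * (x[inside] - pc$knots[i[inside]])
    out[!inside] <- map$default * x[!inside]  # before first knot (knot0 = 0)
    # beyond the last knot the rate vector's final entry is the default
    out
  }
  (Fx(ends) - Fx(starts)) / (ends - starts)
}

# ---- predictions ------------------------------------------------------------

#' Write window predictions as BED6+3
#'
#' Columns: chrom, start, end, class label, LOD (score, rounded), strand,
#' then posterior probabilities for B, E and N.  Rows are ordered by
#' (chrom, start, strand) for deterministic output.
#'
#' @param predictions prediction data frame from [scan_genome()].
#' @param path output path.
#' @param precision digits kept for LOD and posteriors.
#' @export
write_predictions <- function(predictions, path, precision = 4) {
  p <- predictions[order(predictions$chrom, predictions$start,
                         predictions$strand), , drop = FALSE]
  if (any(!is.finite(p$lod))) stop("non-finite LOD in predictions")
  df <- data.frame(p$chrom,
                   format(p$start, scientific = FALSE, trim = TRUE),
                   format(p$end, scientific = FALSE, trim = TRUE),
                   p$class, round(p$lod, precision), p$strand,
                   round(p$post_B, precision), round(p$post_E, precision),
                   round(p$post_N, precision))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read back a BED6+3 prediction file
#'
#' @param path file written by [write_predictions()].
#' @return prediction data frame (high_confidence column not restored; it is
#'   a function of LOD and the caller's threshold).
#' @export
read_predictions <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(), lod = numeric(),
                      strand = character(), post_B = numeric(),
                      post_E = numeric(), post_N = numeric(),
                      stringsAsFactors = FALSE))
  f <- split_fields(lines)
  if (any(lengths(f) < 9)) stop("prediction BED needs 9 columns")
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.numeric(vapply(f, `[`, "", 2)),
             end = as.numeric(vapply(f, `[`, "", 3)),
             class = vapply(f, `[`, "", 4),
             lod = as.numeric(vapply(f, `[`, "", 5)),
             strand = vapply(f, `[`, "", 6),
             post_B = as.numeric(vapply(f, `[`, "", 7)),
             post_E = as.numeric(vapply(f, `[`, "", 8)),
             post_N = as.numeric(vapply(f, `[`, "", 9)),
             stringsAsFactors = FALSE)
}
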