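# The BEST classifier: a three-class Naive Bayes model over six read-density
# features of stranded 2-kb windows.
#
# Classes: B (BEST: bidirectional expression of short transcripts, the
# signature of paused polymerase), E (transcriptional elongation), N
# (non-transcribed).  Features, all strand-relative to the window under
# evaluation:
#   f1  sense read density (reads/kb/mapability)
#   f2  antisense read density
#   f3  f1 / sense density in the 2-kb window immediately 3'
#   f4  f2 / antisense density in the 2-kb window immediately 3'
#   f5  f1 / sense density in the 2-kb window immediately 5'
#   f6  f2 / antisense density in the 2-kb window immediately 5'
# Ratios are regularised with a symmetric pseudocount in numerator and
# denominator.  Class-conditional feature distributions are quantile-binned
# histograms of log1p-transformed values with Laplace smoothing, which keeps
# every log-likelihood finite; priors are uniform.

CLASSES <- c("B", "E", "N")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Build labelled training windows for the classifier
#'
#' B windows are centred on the TSS of every active transcript (window
#' strand = transcript strand); E windows on active-transcript midpoints; N
#' windows on midpoints of randomly placed intergenic regions whose lengths
#' are drawn from the active-transcript length distribution and which
#' overlap no annotated transcript.  N windows get a random strand (the
#' background is strand-symmetric).
#'
#' @param active `transcript_table` of active transcripts.
#' @param transcripts full `transcript_table` (intergenic regions must avoid
#'   all of these, not just the active subset).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_intergenic number of intergenic N regions to place.
#' @param seed RNG seed for the intergenic placement.
#' @param window_bp window width.
#' @param max_tries placement attempts per region before giving up.
#' @return named list (B, E, N) of stranded interval data frames.
#' @export
build_training_windows <- function(active, transcripts, chrom_sizes,
                                   n_intergenic = nrow(active), seed = 1,
                                   window_bp = 2000, max_tries = 1000) {
  stopifnot(nrow(active) > 0, n_intergenic > 0)
  h <- window_bp / 2
  centered <- function(center, strand, chrom) {
    ok <- center - h >= 0 & center + h <= chrom_sizes[chrom]
    genomic_intervals(chrom[ok], center[ok] - h, center[ok] + h, strand[ok])
  }
  B <- centered(active$tss, active$strand, active$chrom)
  mid <- floor((active$start + active$end) / 2)
  E <- centered(mid, active$strand, active$chrom)
  gene_mask <- as_mask(genomic_intervals(transcripts$chrom,
                                         transcripts$start, transcripts$end))
  lens <- active$length
  N <- with_seed(seed, {
    chroms <- names(chrom_sizes)
    picked <- vector("list", n_intergenic)
    for (i in seq_len(n_intergenic)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len <- sample(lens, 1)
        ch <- sample(chroms, 1, prob = chrom_sizes)
        if (chrom_sizes[ch] <= len) next
        s <- floor(stats::runif(1, 0, chrom_sizes[ch] - len))
        if (mask_hits(gene_mask, ch, s, s + len)) next
        m <- floor(s + len / 2)
        if (m - h < 0 || m + h > chrom_sizes[ch]) next
        picked[[i]] <- data.frame(chrom = ch, start = m - h, end = m + h,
                                  strand = sample(c("+", "-"), 1),
                                  stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place intergenic region %d of %d after %d tries",
                     i, n_intergenic, max_tries))
    }
    do.call(rbind, picked)
  })
  rownames(N) <- NULL
  list(B = B, E = E, N = N)
}

#' Extract the six classifier features for stranded windows
#'
#' Vectorised over windows.  For a `+` window the 3' neighbour is the 2-kb
#' window immediately downstream in genome coordinates and the 5' neighbour
#' immediately upstream; for a `-` window the directions flip.  Any window
#' whose own or neighbouring densities are undefined (mapability at or below
#' the floor), or whose neighbours would fall off the chromosome, is refused
#' (`NA` row, `ok = FALSE`).
#'
#' @param track a `read_track`.
#' @param windows stranded interval data frame (equal widths).
#' @param mapability a `mapability_track`.
#' @param ratio_pseudocount symmetric pseudocount (reads/kb/mapability)
#'   added to numerator and denominator of the ratio features f3-f6.
#' @param map_floor mapability floor below which densities are undefined.
#' @param chrom_sizes optional named vector; windows whose neighbours exceed
#'   a chromosome end are refused.
#' @return list with `features` (n x 6 matrix, columns f1..f6) and `ok`
#'   (logical vector; rows with `ok = FALSE` are all-`NA`).
#' @export
extract_features <- function(track, windows, mapability,
                             ratio_pseudocount = 0.1, map_floor = 0.05,
                             chrom_sizes = NULL) {
  n <- nrow(windows)
  w <- windows$end - windows$start
  stopifnot(all(windows$strand %in% c("+", "-")))
  upstream <- genomic_intervals_unsafe(windows$chrom, windows$start - w,
                                       windows$end - w, windows$strand)
  downstream <- genomic_intervals_unsafe(windows$chrom, windows$start + w,
                                         windows$end + w, windows$strand)
  in_bounds <- upstream$start >= 0
  if (!is.null(chrom_sizes))
    in_bounds <- in_bounds & downstream$end <= chrom_sizes[windows$chrom]
  dens <- function(win, mode) {
    d <- rep(NA_real_, n)
    if (any(in_bounds))
      d[in_bounds] <- window_density(track, win[in_bounds, , drop = FALSE],
                                     mapability, mode, map_floor)
    d
  }
  f1 <- dens(windows, "sense")
  f2 <- dens(windows, "antisense")
  up_s <- dens(upstream, "sense");   up_a <- dens(upstream, "antisense")
  dn_s <- dens(downstream, "sense"); dn_a <- dens(downstream, "antisense")
  plus <- windows$strand == "+"
  s3 <- ifelse(plus, dn_s, up_s); a3 <- ifelse(plus, dn_a, up_a)
  s5 <- ifelse(plus, up_s, dn_s); a5 <- ifelse(plus, up_a, dn_a)
  pc <- ratio_pseudocount
  fm <- cbind(f1 = f1, f2 = f2,
              f3 = (f1 + pc) / (s3 + pc), f4 = (f2 + pc) / (a3 + pc),
              f5 = (f1 + pc) / (s5 + pc), f6 = (f2 + pc) / (a5 + pc))
  ok <- in_bounds & !apply(is.na(fm), 1, any)
  fm[!ok, ] <- NA_real_
  list(features = fm, ok = ok)
}

# interval constructor without start >= 0 validation (neighbour windows may
# provisionally fall off the chromosome; they are refused downstream)
genomic_intervals_unsafe <- function(chrom, start, end, strand) {
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Fit the three-class Naive Bayes BEST model
#'
#' For each feature, values from all three classes are pooled, log1p
#' transformed, and cut into `n_bins` quantile bins; each class's
#' class-conditional distribution is the Laplace-smoothed histogram
#' `(count + pseudocount) / (n + n_bins * pseudocount)` over those shared
#' bins.  Priors are uniform over B, E, N.
#'
#' @param training named list (B, E, N) of feature matrices as returned by
#'   [extract_features()] (`ok` rows only).
#' @param n_bins number of quantile bins per feature.
#' @param pseudocount Laplace smoothing constant.
#' @param min_class_size minimum training windows per class.
#' @param ratio_pseudocount recorded so that scanning uses the same ratio
#'   regularisation as training.
#' @return object of class `best_nbc`.
#' @export
fit_best_nbc <- function(training, n_bins = 20, pseudocount = 1.0,
                         min_class_size = 50, ratio_pseudocount = 0.1) {
  stopifnot(setequal(names(training), CLASSES), n_bins >= 2, pseudocount > 0)
  training <- training[CLASSES]
  sizes <- vapply(training, nrow, 0L)
  if (any(sizes < min_class_size))
    stop(sprintf("class %s has %d training windows (< %d)",
                 CLASSES[which(sizes < min_class_size)[1]],
                 min(sizes), min_class_size))
  feats <- lapply(CLASSES, function(cl) {
    m <- log1p(as.matrix(training[[cl]]))
    if (ncol(m) != 6 || any(!is.finite(m))) stop("features must be a finite n x 6 matrix")
    m
  })
  names(feats) <- CLASSES
  features <- vector("list", 6)
  for (j in 1:6) {
    pooled <- unlist(lapply(feats, function(m) m[, j]), use.names = FALSE)
    cuts <- unique(stats::quantile(pooled, probs = seq(0, 1,
                                                       length.out = n_bins + 1),
                                   names = FALSE, type = 7))
    cuts <- cuts[-c(1, length(cuts))]  # inner cut points only; edge bins open
    n_eff <- length(cuts) + 1
    masses <- matrix(NA_real_, 3, n_eff, dimnames = list(CLASSES, NULL))
    for (cl in CLASSES) {
      x <- feats[[cl]][, j]
      counts <- tabulate(findInterval(x, cuts) + 1L, nbins = n_eff)
      masses[cl, ] <- (counts + pseudocount) /
        (length(x) + n_eff * pseudocount)
    }
    features[[j]] <- list(cuts = cuts, masses = masses)
  }
  structure(list(priors = stats::setNames(rep(1 / 3, 3), CLASSES),
                 features = features, transform = "log1p",
                 n_bins = n_bins, pseudocount = pseudocount,
                 ratio_pseudocount = ratio_pseudocount,
                 n_train = sizes, version = 1L),
            class = "best_nbc")
}

# per-class log likelihood (including log prior) for an n x 6 feature matrix
nbc_loglik <- function(object, fm) {
  fm <- log1p(as.matrix(fm))
  n <- nrow(fm)
  ll <- matrix(rep(log(object$priors), each = n), n, 3,
               dimnames = list(NULL, CLASSES))
  for (j in 1:6) {
    bins <- findInterval(fm[, j], object$features[[j]]$cuts) + 1L
    # out-of-range values land in the open edge bins by construction
    ll <- ll + log(t(object$features[[j]]$masses[, bins, drop = FALSE]))
  }
  ll
}

#' Posteriors, class calls and LOD scores for feature vectors
#'
#' Likelihoods are evaluated in log space and normalised with log-sum-exp.
#' The class is the posterior argmax; exact ties are broken in the fixed
#' order N, then E, then B (biasing against false BEST calls).  The LOD is
#' `ln[ Pr(B) prod_j Pr(f_j|B) / max_{c in {E,N}} Pr(c) prod_j Pr(f_j|c) ]`,
#' so with equal priors a window is called B exactly when LOD > 0.
#'
#' @param object a fitted `best_nbc`.
#' @param newdata n x 6 feature matrix or data frame (columns f1..f6).
#' @param ... unused.
#' @return data frame with post_B, post_E, post_N, class, lod.
#' @export
predict.best_nbc <- function(object, newdata, ...) {
  ll <- nbc_loglik(object, newdata)
  lod <- unname(ll[, "B"] - pmax(ll[, "E"], ll[, "N"]))
  m <- apply(ll, 1, max)
  post <- exp(ll - m)
  post <- post / rowSums(post)
  tie_order <- c("N", "E", "B")
  cls <- tie_order[apply(ll[, tie_order, drop = FALSE], 1, which.max)]
  data.frame(post_B = post[, "B"], post_E = post[, "E"], post_N = post[, "N"],
             class = cls, lod = lod, stringsAsFactors = FALSE)
}

#' LOD score of the BEST class for feature vectors
#'
#' @inheritParams predict.best_nbc
#' @param fm n x 6 feature matrix.
#' @return numeric vector of natural-log odds of B against the better of E
#'   and N (priors included).
#' @export
lod_score <- function(object, fm) {
  ll <- nbc_loglik(object, fm)
  unname(ll[, "B"] - pmax(ll[, "E"], ll[, "N"]))
}

#' @export
print.best_nbc <- function(x, ...) {
  cat("Three-class Naive Bayes BEST classifier\n")
  cat(sprintf("  classes B/E/N, training windows: %s\n",
              paste(sprintf("%s=%d", CLASSES, x$n_train), collapse = ", ")))
  cat(sprintf("  %d quantile bins per feature (log1p scale), pseudocount %.3g, ratio pseudocount %.3g\n",
              x$n_bins, x$pseudocount, x$ratio_pseudocount))
  invisible(x)
}

#' @export
summary.best_nbc <- function(object, ...) {
  print(object)
  for (j in 1:6) {
    cat(sprintf("  f%d: %d bins; per-class mass range ", j,
                ncol(object$features[[j]]$masses)))
    rng <- range(object$features[[j]]$masses)
    cat(sprintf("[%.4g, %.4g]\n", rng[1], rng[2]))
  }
  invisible(object)
}

#' Plot class-conditional feature distributions
#'
#' One panel per feature showing the smoothed bin masses for B, E and N.
#'
#' @param x a fitted `best_nbc`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.best_nbc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (j in 1:6) {
    m <- x$features[[j]]$masses
    graphics::matplot(t(m), type = "s", lty = 1, col = c(2, 3, 4),
                      xlab = "bin", ylab = "mass",
                      main = sprintf("f%d", j), ...)
    graphics::legend("topright", legend = CLASSES, col = c(2, 3, 4),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Serialise / restore a fitted model as versioned JSON
#'
#' @param model a `best_nbc`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  out <- list(version = model$version, priors = as.list(model$priors),
              transform = model$transform, n_bins = model$n_bins,
              pseudocount = model$pseudocount,
              ratio_pseudocount = model$ratio_pseudocount,
              n_train = as.list(model$n_train),
              features = lapply(model$features, function(f)
                list(cuts = f$cuts, masses = apply(f$masses, 1, identity,
                                                   simplify = FALSE))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_model
#' @param path JSON file path.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- lapply(x$features, function(f) {
    masses <- do.call(rbind, lapply(f$masses[CLASSES],
                                    function(m) as.numeric(unlist(m))))
    rownames(masses) <- CLASSES
    list(cuts = as.numeric(unlist(f$cuts)), masses = masses)
  })
  structure(list(priors = unlist(x$priors)[CLASSES], features = features,
                 transform = x$transform, n_bins = x$n_bins,
                 pseudocount = x$pseudocount,
                 ratio_pseudocount = x$ratio_pseudocount,
                 n_train = unlist(x$n_train)[CLASSES],
                 version = x$version),
            class = "best_nbc")
}

#' Promoter/gene-end exclusion mask
#'
#' Union of `[x - radius, x + radius)` around every TSS and annotated gene
#' end, and `[start - radius, end + radius)` around every H3K4me3 peak,
#' merged and clipped at 0.  Windows intersecting this mask are outside the
#' non-promoter search space.
#'
#' @param transcripts a `transcript_table` (all known transcripts).
#' @param h3k4me3 optional `peak_set` of promoter-mark peaks.
#' @param radius_bp exclusion radius.
#' @return an `exclusion_mask` (merged interval list, one matrix per
#'   chromosome); convert with [mask_intervals()].
#' @export
exclusion_mask <- function(transcripts, h3k4me3 = NULL, radius_bp = 7000) {
  stopifnot(radius_bp >= 0)
  parts <- list()
  if (nrow(transcripts) > 0) {
    pts <- c(transcripts$tss, transcripts$gene_end)
    chs <- c(transcripts$chrom, transcripts$chrom)
    parts$points <- genomic_intervals(chs, pmax(0, pts - radius_bp),
                                      pts + radius_bp)
  }
  if (!is.null(h3k4me3) && nrow(h3k4me3) > 0)
    parts$peaks <- genomic_intervals(h3k4me3$chrom,
                                     pmax(0, h3k4me3$start - radius_bp),
                                     h3k4me3$end + radius_bp)
  if (length(parts) == 0)
    return(structure(list(), class = "exclusion_mask"))
  m <- as_mask(do.call(rbind, parts))
  structure(m, class = "exclusion_mask")
}

#' Intervals covered by an exclusion mask
#'
#' @param mask an `exclusion_mask`.
#' @return interval data frame of the merged mask.
#' @export
mask_intervals <- function(mask) mask_to_intervals(unclass(mask))

#' Scan the genome for high-confidence BEST windows
#'
#' Tiles every chromosome with non-overlapping `window_bp` windows starting
#' at coordinate 0, drops windows that (or whose two flanking windows)
#' intersect the exclusion mask or have undefined densities, evaluates each
#' survivor on both strands with strand-relative features, and reports one
#' prediction per genomic window carrying the max-LOD strand.  A window is a
#' high-confidence BEST locus when its LOD is strictly greater than
#' `lod_threshold` on one or both strands.
#'
#' @param model a fitted `best_nbc`.
#' @param track a `read_track`.
#' @param mapability a `mapability_track`.
#' @param mask an `exclusion_mask` from [exclusion_mask()].
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param window_bp window width (default 2000).
#' @param lod_threshold high-confidence threshold (strict `>`; default 2.5).
#' @param map_floor mapability floor for defined densities.
#' @return data frame of class `best_predictions` with columns chrom, start,
#'   end, strand, class, lod, post_B, post_E, post_N, high_confidence, and a
#'   `counts` attribute (windows scored / masked / undefined per
#'   chromosome).
#' @export
scan_genome <- function(model, track, mapability, mask, chrom_sizes,
                        window_bp = 2000, lod_threshold = 2.5,
                        map_floor = 0.05) {
  if (lod_threshold < 0)
    warning("negative LOD threshold: every B call will be high-confidence")
  pc <- model$ratio_pseudocount
  res <- list()
  counts <- list()
  for (ch in names(chrom_sizes)) {
    nt <- floor(chrom_sizes[[ch]] / window_bp)
    if (nt < 3) next
    edges <- (0:nt) * window_bp
    starts <- edges[-(nt + 1)]; ends <- edges[-1]
    cp <- count_anchors(track, ch, starts, ends, "+")
    cm <- count_anchors(track, ch, starts, ends, "-")
    mm <- mapability_mean(mapability, ch, starts, ends)
    kb <- window_bp / 1000
    dp <- ifelse(mm > map_floor, cp / kb / mm, NA_real_)
    dm <- ifelse(mm > map_floor, cm / kb / mm, NA_real_)
    masked <- mask_hits(unclass(mask), ch, starts, ends)
    i <- 2:(nt - 1)
    ok_mask <- !masked[i] & !masked[i - 1] & !masked[i + 1]
    ok_def <- !is.na(dp[i]) & !is.na(dp[i - 1]) & !is.na(dp[i + 1]) &
      !is.na(dm[i]) & !is.na(dm[i - 1]) & !is.na(dm[i + 1])
    keep <- i[ok_mask & ok_def]
    counts[[ch]] <- c(tiles = nt, scored = length(keep),
                      masked = sum(!ok_mask),
                      undefined = sum(ok_mask & !ok_def))
    if (!length(keep)) next
    fm_plus <- cbind(f1 = dp[keep], f2 = dm[keep],
                     f3 = (dp[keep] + pc) / (dp[keep + 1] + pc),
                     f4 = (dm[keep] + pc) / (dm[keep + 1] + pc),
                     f5 = (dp[keep] + pc) / (dp[keep - 1] + pc),
                     f6 = (dm[keep] + pc) / (dm[keep - 1] + pc))
    fm_minus <- cbind(f1 = dm[keep], f2 = dp[keep],
                      f3 = (dm[keep] + pc) / (dm[keep - 1] + pc),
                      f4 = (dp[keep] + pc) / (dp[keep - 1] + pc),
                      f5 = (dm[keep] + pc) / (dm[keep + 1] + pc),
                      f6 = (dp[keep] + pc) / (dp[keep + 1] + pc))
    pr_p <- predict(model, fm_plus)
    pr_m <- predict(model, fm_minus)
    take_plus <- pr_p$lod >= pr_m$lod
    pr <- pr_p
    pr[!take_plus, ] <- pr_m[!take_plus, ]
    res[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep],
                            strand = ifelse(take_plus, "+", "-"),
                            class = pr$class, lod = pr$lod,
                            post_B = pr$post_B, post_E = pr$post_E,
                            post_N = pr$post_N,
                            high_confidence = pmax(pr_p$lod, pr_m$lod) >
                              lod_threshold,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), class = character(), lod = numeric(),
               post_B = numeric(), post_E = numeric(), post_N = numeric(),
               high_confidence = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("best_predictions", class(out))
  out
}
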