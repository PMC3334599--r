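# Seeded synthetic datasets: genome, gene annotation, stranded reads,
# mapability, peak sets, expression labels, and ground-truth planted BEST
# loci, written in the package's text formats so every module is testable
# end-to-end without external data.
#
# The read model is a Poisson process with the structure of nascent
# transcription: a promoter-proximal sense spike with a divergent antisense
# spike immediately upstream at every expressed promoter (the BEST
# signature), uniform lower-density sense elongation over gene bodies,
# sparse strand-symmetric background noise, and the same bidirectional
# spike shape at planted intergenic loci.  Each read is thinned by the
# local mapability, so the reads/kb/mapability estimator is unbiased for
# the simulated rates.

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the package's reference simulation: a 10-Mb genome
#' (2 x 5 Mb), 200 non-overlapping genes of 3.5-12 kb (60% expressed),
#' promoter pause spikes of Poisson mean 50 sense reads in
#' `[TSS, TSS+150)` and 35 antisense reads in `[TSS-200, TSS)`, gene-body
#' elongation around 18 reads/kb for expressed genes versus under 1 for
#' non-expressed, background noise of 0.2 reads/kb per strand, and 50
#' planted intergenic BEST loci carrying the same spike shape.  Planted
#' loci are kept at least 7 kb from every gene TSS/end, mutually
#' separated, and within mappable sequence.
#'
#' @param seed integer RNG seed; the entire dataset is a deterministic
#'   function of the config.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_genes number of genes.
#' @param gene_len_min,gene_len_max gene length bounds (bp).
#' @param expressed_fraction fraction of genes drawn as expressed.
#' @param elongation_base,elongation_spread expressed gene-body rates are
#'   `elongation_base + Exp(mean = elongation_spread)` reads/kb.
#' @param nonexpressed_max non-expressed body rates are
#'   `Unif(0, nonexpressed_max)` reads/kb.
#' @param expression_split rate (reads/kb) separating the expressed /
#'   non-expressed truth labels.
#' @param spike_sense,spike_antisense Poisson mean read counts of the
#'   promoter-proximal sense spike and the divergent antisense spike.
#' @param spike_sense_len,spike_antisense_len spike extents (bp).
#' @param spike_scale global amplitude multiplier applied to both spike
#'   means (1 = reference conditions).
#' @param n_planted_best number of planted intergenic BEST loci.
#' @param planted_clearance_bp minimum distance of a planted locus centre
#'   from any gene TSS or gene end.
#' @param background_rate background noise (reads/kb per strand).
#' @param map_seg_bp,map_low_fraction,map_low_value,map_mid_fraction,map_mid_value
#'   mapability model: the genome is tiled in `map_seg_bp` segments; each
#'   is unmappable (`map_low_value`) with probability `map_low_fraction`,
#'   partially mappable (`map_mid_value`) with probability
#'   `map_mid_fraction`, else 1.0.
#' @param marks list of synthetic peak sets, each
#'   `list(q = , r = , peak_len = , n_background = )`: a peak is planted
#'   over each truth locus with probability `q` and over each of
#'   `n_background` random control windows with probability `r`.
#' @param promoter_mark_rate probability that an expressed promoter gets an
#'   H3K4me3-like peak.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             chrom_sizes = c(chrS1 = 5e6, chrS2 = 5e6),
                             n_genes = 200, gene_len_min = 3500,
                             gene_len_max = 12000,
                             expressed_fraction = 0.6,
                             elongation_base = 8, elongation_spread = 10,
                             nonexpressed_max = 0.8, expression_split = 5,
                             spike_sense = 50, spike_antisense = 35,
                             spike_sense_len = 150, spike_antisense_len = 200,
                             spike_scale = 1, n_planted_best = 50,
                             planted_clearance_bp = 7000,
                             background_rate = 0.2,
                             map_seg_bp = 50000, map_low_fraction = 0.02,
                             map_low_value = 0.02, map_mid_fraction = 0.05,
                             map_mid_value = 0.8,
                             marks = list(DHS = list(q = 0.8, r = 0.1,
                                                     peak_len = 400,
                                                     n_background = 2000)),
                             promoter_mark_rate = 0.9) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == round(cfg$seed), all(cfg$chrom_sizes > 0),
            n_genes > 0, gene_len_min > 0, gene_len_max >= gene_len_min,
            expressed_fraction >= 0, expressed_fraction <= 1,
            spike_scale >= 0, n_planted_best >= 0, background_rate >= 0)
  class(cfg) <- "synthetic_config"
  cfg
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Generate a synthetic dataset
#'
#' Writes all files under `outdir` in the package's input formats (refFlat
#' genes, per-strand BED6 reads, BED4 mapability, BED3 peak and control
#' files, BED6 truth loci, two-column expression labels, resolved config
#' JSON) and returns their paths plus the in-memory truth.  Regenerating
#' with the same config is byte-identical.
#'
#' @param config a `synthetic_config`.
#' @param outdir output directory (created if needed).
#' @return list of class `synthetic_dataset`: `paths` (named file paths),
#'   `truth` (stranded interval data frame of planted loci), `genes`
#'   (transcript table), `labels` (accession/label data frame), `config`.
#' @export
generate_synthetic_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, generate_impl(config, outdir))
}

generate_impl <- function(cfg, outdir) {
  chroms <- names(cfg$chrom_sizes)

  ## mapability: piecewise-constant segments
  map_rows <- list()
  for (ch in chroms) {
    n_seg <- ceiling(cfg$chrom_sizes[[ch]] / cfg$map_seg_bp)
    s <- (seq_len(n_seg) - 1) * cfg$map_seg_bp
    e <- pmin(s + cfg$map_seg_bp, cfg$chrom_sizes[[ch]])
    u <- stats::runif(n_seg)
    v <- ifelse(u < cfg$map_low_fraction, cfg$map_low_value,
                ifelse(u < cfg$map_low_fraction + cfg$map_mid_fraction,
                       cfg$map_mid_value, 1.0))
    map_rows[[ch]] <- data.frame(chrom = ch, start = s, end = e, value = v)
  }
  map_df <- do.call(rbind, map_rows)
  map <- new_mapability(split(map_df[c("start", "end", "value")],
                              map_df$chrom), 0)

  ## genes: non-overlapping placement by rejection
  gene_mask_rows <- list()
  genes <- vector("list", cfg$n_genes)
  occupied <- structure(vector("list", length(chroms)), names = chroms)
  for (i in seq_len(cfg$n_genes)) {
    placed <- FALSE
    for (try in 1:2000) {
      len <- floor(stats::runif(1, cfg$gene_len_min, cfg$gene_len_max + 1))
      ch <- sample(chroms, 1, prob = cfg$chrom_sizes)
      if (cfg$chrom_sizes[[ch]] <= len + 2000) next
      s <- floor(stats::runif(1, 1000, cfg$chrom_sizes[[ch]] - len - 1000))
      occ <- occupied[[ch]]
      if (!is.null(occ) &&
          any(pmin(occ[, 2], s + len) - pmax(occ[, 1], s) > -500)) next
      occupied[[ch]] <- rbind(occ, c(s, s + len))
      genes[[i]] <- data.frame(
        accession = sprintf("NM_SYN%04d", i),
        gene_symbol = sprintf("SYNG%04d", i), chrom = ch,
        strand = sample(c("+", "-"), 1), start = s, end = s + len,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("gene placement infeasible for this genome size")
  }
  genes <- do.call(rbind, genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$gene_end <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  genes$length <- genes$end - genes$start

  ## expression classes and rates
  expressed <- stats::runif(cfg$n_genes) < cfg$expressed_fraction
  rate <- ifelse(expressed,
                 cfg$elongation_base +
                   stats::rexp(cfg$n_genes, 1 / cfg$elongation_spread),
                 stats::runif(cfg$n_genes, 0, cfg$nonexpressed_max))
  label <- ifelse(rate >= cfg$expression_split, "expressed", "non-expressed")

  ## planted intergenic BEST loci: clear of gene TSS/ends, mutually
  ## separated, and within the scannable search space.  A scanned 2-kb
  ## window needs its two flanking windows as context, so the locus plus
  ## a +/- 5 kb context must stay clear of the exclusion zone and of
  ## unmappable sequence: truth planted where the classifier cannot look
  ## would measure placement, not recovery.
  clearance <- cfg$planted_clearance_bp
  pts <- c(genes$tss, genes$gene_end)
  pchs <- c(genes$chrom, genes$chrom)
  forbid <- as_mask(genomic_intervals(pchs, pmax(0, pts - clearance),
                                      pts + clearance))
  truth <- list()
  centers <- structure(vector("list", length(chroms)), names = chroms)
  if (cfg$n_planted_best > 0) {
    for (i in seq_len(cfg$n_planted_best)) {
      placed <- FALSE
      for (try in 1:5000) {
        ch <- sample(chroms, 1, prob = cfg$chrom_sizes)
        c0 <- floor(stats::runif(1, 5000, cfg$chrom_sizes[[ch]] - 5000))
        if (mask_hits(forbid, ch, c0 - 5000, c0 + 5000)) next
        if (length(centers[[ch]]) && any(abs(centers[[ch]] - c0) < 6000)) next
        sub <- seq(c0 - 5000, c0 + 4000, by = 1000)
        if (min(mapability_mean(map, ch, sub, sub + 1000)) < 0.3) next
        centers[[ch]] <- c(centers[[ch]], c0)
        truth[[i]] <- data.frame(chrom = ch, start = c0 - 1000,
                                 end = c0 + 1000,
                                 strand = sample(c("+", "-"), 1),
                                 center = c0, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("planted locus placement infeasible")
    }
    truth <- do.call(rbind, truth)
  } else {
    truth <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        center = numeric(), stringsAsFactors = FALSE)
  }

  ## reads --------------------------------------------------------------
  rch <- rpos <- rstr <- list()
  emit <- function(ch, pos, strand) {
    k <- length(rch) + 1
    rch[[k]] <<- rep(ch, length(pos)); rpos[[k]] <<- pos
    rstr[[k]] <<- rep(strand, length(pos))
  }
  unif_reads <- function(n, lo, hi) floor(stats::runif(n, lo, hi))
  # background noise, both strands
  for (ch in chroms) for (st in c("+", "-")) {
    n <- stats::rpois(1, cfg$background_rate * cfg$chrom_sizes[[ch]] / 1000)
    emit(ch, unif_reads(n, 0, cfg$chrom_sizes[[ch]]), st)
  }
  # gene-body elongation (sense strand, TSS to gene end)
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i, ]
    n <- stats::rpois(1, rate[i] * g$length / 1000)
    emit(g$chrom, unif_reads(n, g$start, g$end), g$strand)
  }
  # bidirectional pause spikes: expressed promoters and planted loci
  spike <- function(ch, tss, strand) {
    sl <- cfg$spike_sense_len; al <- cfg$spike_antisense_len
    ns <- stats::rpois(1, cfg$spike_sense * cfg$spike_scale)
    na <- stats::rpois(1, cfg$spike_antisense * cfg$spike_scale)
    if (strand == "+") {
      emit(ch, unif_reads(ns, tss, tss + sl), "+")
      emit(ch, unif_reads(na, max(0, tss - al), tss), "-")
    } else {
      emit(ch, unif_reads(ns, tss - sl + 1, tss + 1), "-")
      emit(ch, unif_reads(na, tss + 1, tss + 1 + al), "+")
    }
  }
  for (i in which(label == "expressed"))
    spike(genes$chrom[i], genes$tss[i], genes$strand[i])
  if (nrow(truth) > 0)
    for (i in seq_len(nrow(truth)))
      spike(truth$chrom[i], truth$center[i], truth$strand[i])

  reads <- data.frame(chrom = unlist(rch), pos = unlist(rpos),
                      strand = unlist(rstr), stringsAsFactors = FALSE)
  # thin by local mapability so densities recover the simulated rates
  keepp <- rep(TRUE, nrow(reads))
  for (ch in chroms) {
    sel <- which(reads$chrom == ch)
    mv <- mapability_mean(map, ch, reads$pos[sel], reads$pos[sel] + 1)
    keepp[sel] <- stats::runif(length(sel)) < mv
  }
  reads <- reads[keepp & reads$pos >= 0, , drop = FALSE]
  reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]

  ## peak sets over truth loci and control windows -----------------------
  truth_mask <- if (nrow(truth) > 0)
    as_mask(genomic_intervals(truth$chrom, pmax(0, truth$start - 2000),
                              truth$end + 2000))
  else list()
  mark_files <- list()
  for (mk in names(cfg$marks)) {
    m <- cfg$marks[[mk]]
    rows <- list()
    if (nrow(truth) > 0) {
      hit <- stats::runif(nrow(truth)) < m$q
      for (i in which(hit)) {
        cc <- truth$center[i] + floor(stats::runif(1, -100, 100))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = truth$chrom[i], start = cc - floor(m$peak_len / 2),
          end = cc + ceiling(m$peak_len / 2))
      }
    }
    # control windows: 2-kb tiles sampled without replacement, so each
    # window can only overlap its own planted peak and the Bernoulli(r)
    # overlap indicators stay independent across windows
    tiles <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(chrom = ch,
                 start = 2000 * (seq_len(floor(cfg$chrom_sizes[[ch]] / 2000))
                                 - 1), stringsAsFactors = FALSE)))
    tiles$end <- tiles$start + 2000
    free <- !logical(nrow(tiles))
    for (ch in chroms) {
      sel <- tiles$chrom == ch
      free[sel] <- !mask_hits(truth_mask, ch, tiles$start[sel],
                              tiles$end[sel])
    }
    tiles <- tiles[free, , drop = FALSE]
    if (nrow(tiles) < m$n_background)
      stop("control window placement infeasible")
    ctrl <- tiles[sample.int(nrow(tiles), m$n_background), , drop = FALSE]
    rownames(ctrl) <- NULL
    chit <- stats::runif(nrow(ctrl)) < m$r
    for (i in which(chit)) {
      cc <- floor((ctrl$start[i] + ctrl$end[i]) / 2)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ctrl$chrom[i], start = cc - floor(m$peak_len / 2),
        end = cc + ceiling(m$peak_len / 2))
    }
    pk <- do.call(rbind, rows)
    pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    pk$start <- pmax(0, pk$start)
    mark_files[[mk]] <- list(peaks = pk, controls = ctrl)
  }
  # H3K4me3-like promoter mark for the exclusion machinery
  prom_idx <- which(label == "expressed" &
                      stats::runif(cfg$n_genes) < cfg$promoter_mark_rate)
  h3k4me3 <- data.frame(chrom = genes$chrom[prom_idx],
                        start = pmax(0, genes$tss[prom_idx] - 500),
                        end = genes$tss[prom_idx] + 500)
  h3k4me3 <- h3k4me3[order(h3k4me3$chrom, h3k4me3$start), , drop = FALSE]

  ## write everything -----------------------------------------------------
  paths <- list(
    genes = file.path(outdir, "genes.refflat.tsv"),
    reads_plus = file.path(outdir, "reads_plus.bed"),
    reads_minus = file.path(outdir, "reads_minus.bed"),
    mapability = file.path(outdir, "mapability.bed4"),
    labels = file.path(outdir, "expression_labels.tsv"),
    truth = file.path(outdir, "truth_best_loci.bed"),
    h3k4me3 = file.path(outdir, "h3k4me3_peaks.bed"),
    config = file.path(outdir, "config.json"))
  write_tsv_raw(data.frame(genes$accession, genes$gene_symbol, genes$chrom,
                           genes$strand, fmt_int(genes$start),
                           fmt_int(genes$end)), paths$genes)
  for (st in c("+", "-")) {
    r <- reads[reads$strand == st, , drop = FALSE]
    write_tsv_raw(data.frame(r$chrom, fmt_int(r$pos), fmt_int(r$pos + 1),
                             paste0("read", seq_len(nrow(r))), 0, r$strand),
                  if (st == "+") paths$reads_plus else paths$reads_minus)
  }
  write_tsv_raw(data.frame(map_df$chrom, fmt_int(map_df$start),
                           fmt_int(map_df$end), map_df$value),
                paths$mapability)
  write_tsv_raw(data.frame(genes$accession, label), paths$labels)
  write_tsv_raw(data.frame(truth$chrom, fmt_int(truth$start),
                           fmt_int(truth$end),
                           sprintf("best%03d", seq_len(nrow(truth))),
                           rep(0, nrow(truth)), truth$strand), paths$truth)
  write_bed3(h3k4me3, paths$h3k4me3)
  for (mk in names(mark_files)) {
    paths[[paste0("peaks_", mk)]] <- file.path(outdir,
                                               paste0("peaks_", mk, ".bed"))
    paths[[paste0("controls_", mk)]] <-
      file.path(outdir, paste0("controls_", mk, ".bed"))
    write_bed3(mark_files[[mk]]$peaks, paths[[paste0("peaks_", mk)]])
    write_bed3(mark_files[[mk]]$controls, paths[[paste0("controls_", mk)]])
  }
  cfg_json <- cfg
  cfg_json$chrom_sizes <- as.list(cfg_json$chrom_sizes)
  jsonlite::write_json(unclass(cfg_json), paths$config, auto_unbox = TRUE,
                       digits = NA)

  genes$label <- label
  genes$body_rate <- rate
  structure(list(paths = paths, truth = truth, genes = genes,
                 labels = data.frame(accession = genes$accession,
                                     label = label,
                                     stringsAsFactors = FALSE),
                 config = cfg),
            class = "synthetic_dataset")
}

#' Sensitivity and precision of predictions against planted truth
#'
#' Sensitivity is the fraction of truth loci intersected by at least one
#' high-confidence prediction; precision the fraction of high-confidence
#' predictions intersecting at least one truth locus.
#'
#' @param predictions `best_predictions` from [scan_genome()].
#' @param truth interval data frame of planted loci.
#' @return list with `sensitivity`, `precision`, `n_truth`, `n_predicted`;
#'   `sensitivity` is `NA` (flagged) for empty truth, `precision` `NA` for
#'   no high-confidence predictions.
#' @export
truth_overlap_report <- function(predictions, truth) {
  hc <- predictions[predictions$high_confidence, , drop = FALSE]
  sens <- if (nrow(truth) == 0) NA_real_ else
    if (nrow(hc) == 0) 0 else mean(overlaps_peaks(truth, hc))
  prec <- if (nrow(hc) == 0) NA_real_ else mean(overlaps_peaks(hc, truth))
  list(sensitivity = sens, precision = prec, n_truth = nrow(truth),
       n_predicted = nrow(hc))
}
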