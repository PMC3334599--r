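# End-to-end orchestration: read inputs, calibrate the activity cutoff,
# train the classifier, scan the genome, and write predictions with the
# resolved parameters and per-stage counts.

#' Default pipeline parameters
#'
#' All tunables with their reference values: 2-kb windows, 7-kb exclusion
#' radius, LOD threshold 2.5 (strict), 3-kb minimum transcript length,
#' 1-kb body offset, 150-bp profile bins with 5-kb flanks and 2-kb
#' promoter-proximity discard radius, 20 quantile bins, Laplace
#' pseudocount 1, ratio pseudocount 0.1, mapability floor 0.05.
#'
#' @param ... overrides for any default.
#' @return named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(window_bp = 2000, exclusion_bp = 7000, lod_threshold = 2.5,
            min_len_bp = 3000, body_offset_bp = 1000,
            profile_bin_bp = 150, profile_flank_bp = 5000,
            profile_exclusion_bp = 2000, n_bins = 20, pseudocount = 1,
            ratio_pseudocount = 0.1, map_floor = 0.05, seed = 1)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm)
    p[[nm]] <- over[[nm]]
  }
  bad <- vapply(p, function(v) is.numeric(v) && v < 0, FALSE)
  bad["lod_threshold"] <- FALSE  # negative threshold is legal, just warned
  if (any(bad)) stop("negative value for: ", names(p)[bad][1])
  p
}

#' Run the training + scanning pipeline on files
#'
#' Reads the annotation, stranded reads, mapability and H3K4me3 peaks,
#' calibrates the activity cutoff against the expression labels (maximal
#' accuracy), calls active transcripts, builds training windows, fits the
#' classifier, scans the genome outside the exclusion mask, and writes
#' `predictions.bed`, `model.json`, `roc_curve.tsv`, `active.tsv`,
#' `params.json` and `log.txt` under `outdir`.
#'
#' @param genes,reads_plus,reads_minus,mapability,h3k4me3,labels input file
#'   paths (`h3k4me3`, `labels` optional; without labels the activity
#'   `cutoff` parameter must be supplied).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param outdir output directory.
#' @param params parameter list from [default_params()].
#' @param cutoff optional fixed activity cutoff (reads/kb/mapability),
#'   bypassing ROC calibration.
#' @return list with `model`, `predictions`, `roc`, `active`, `paths`.
#' @export
run_pipeline <- function(genes, reads_plus, reads_minus, mapability,
                         chrom_sizes, outdir, h3k4me3 = NULL, labels = NULL,
                         params = default_params(), cutoff = NULL) {
  for (f in c(genes, reads_plus, reads_minus, mapability, h3k4me3, labels))
    if (!file.exists(f)) stop("missing input: ", f)
  if (is.null(labels) && is.null(cutoff))
    stop("either labels or a fixed cutoff is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  tt <- read_transcripts(genes)
  tt <- tt[tt$is_validated_mrna, , drop = FALSE]
  track <- read_stranded_reads(reads_plus, reads_minus)
  map <- read_mapability(mapability)
  k4 <- if (!is.null(h3k4me3)) read_peaks(h3k4me3, "H3K4me3") else NULL
  say("inputs: %d validated transcripts, %d/%d reads", nrow(tt),
      track$n_plus, track$n_minus)

  bd <- transcript_body_density(tt, track, map, params$body_offset_bp,
                                params$min_len_bp, params$map_floor)
  roc <- NULL
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, sep = "\t", stringsAsFactors = FALSE)
    lv <- stats::setNames(lab[[2]], lab[[1]])
    ok <- !is.na(bd$density) & bd$accession %in% names(lv)
    roc <- maximal_accuracy_cutoff(
      stats::setNames(bd$density[ok], bd$accession[ok]),
      lv[bd$accession[ok]])
    cutoff <- roc$cutoff
    say("calibrated activity cutoff %.4g (accuracy %.4f)", cutoff,
        roc$accuracy)
    utils::write.table(roc$curve, file.path(outdir, "roc_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  act <- call_active_transcripts(bd, cutoff)
  active_tt <- tt[tt$accession %in% act$active, , drop = FALSE]
  say("%d active transcripts (%d unique symbols) at cutoff %.4g",
      nrow(active_tt), nrow(act$unique_symbols), cutoff)
  utils::write.table(
    data.frame(bd, active = bd$accession %in% act$active),
    file.path(outdir, "active.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  tw <- build_training_windows(active_tt, tt, chrom_sizes,
                               seed = params$seed,
                               window_bp = params$window_bp)
  feats <- lapply(tw, function(w) {
    fx <- extract_features(track, w, map, params$ratio_pseudocount,
                           params$map_floor, chrom_sizes)
    fx$features[fx$ok, , drop = FALSE]
  })
  say("training windows kept: B=%d E=%d N=%d", nrow(feats$B),
      nrow(feats$E), nrow(feats$N))
  model <- fit_best_nbc(feats, params$n_bins, params$pseudocount,
                        ratio_pseudocount = params$ratio_pseudocount)
  write_model(model, file.path(outdir, "model.json"))

  mask <- exclusion_mask(tt, k4, params$exclusion_bp)
  pred <- scan_genome(model, track, map, mask, chrom_sizes,
                      params$window_bp, params$lod_threshold,
                      params$map_floor)
  cnt <- attr(pred, "counts")
  for (ch in names(cnt))
    say("scan %s: %d tiles, %d scored, %d masked, %d undefined", ch,
        cnt[[ch]]["tiles"], cnt[[ch]]["scored"], cnt[[ch]]["masked"],
        cnt[[ch]]["undefined"])
  say("%d high-confidence BEST windows (LOD > %.3g)",
      sum(pred$high_confidence), params$lod_threshold)
  write_predictions(pred, file.path(outdir, "predictions.bed"))
  jsonlite::write_json(c(params, list(cutoff = cutoff,
                                      tool = "bestscan",
                                      version = "0.1.0")),
                       file.path(outdir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(outdir, "log.txt"))
  list(model = model, predictions = pred, roc = roc, active = act,
       paths = list(predictions = file.path(outdir, "predictions.bed"),
                    model = file.path(outdir, "model.json")))
}
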