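# Shared in-code fixtures.  Heavy objects (the reference synthetic dataset
# and its trained scan) are built once per test run and memoised here.

mk_track <- function(chrom, plus = numeric(0), minus = numeric(0)) {
  bestscan:::track_from_anchors(
    c(rep(chrom, length(plus)), rep(chrom, length(minus))),
    c(plus, minus),
    c(rep("+", length(plus)), rep("-", length(minus))))
}

mk_transcripts <- function(chrom, start, end, strand,
                           accession = sprintf("NM_T%03d", seq_along(start)),
                           symbol = accession) {
  tt <- data.frame(accession = accession, gene_symbol = symbol,
                   chrom = chrom, strand = strand, start = start, end = end,
                   tss = ifelse(strand == "+", start, end - 1),
                   gene_end = ifelse(strand == "+", end - 1, start),
                   length = end - start,
                   is_validated_mrna = TRUE, stringsAsFactors = FALSE)
  class(tt) <- c("transcript_table", class(tt))
  tt
}

# random small NBC model with arbitrary (non-degenerate) bin masses
random_model <- function(n_bins = 8) {
  features <- lapply(1:6, function(j) {
    cuts <- sort(stats::runif(n_bins - 1, 0, 4))
    masses <- t(vapply(1:3, function(i) {
      w <- stats::rgamma(n_bins, 1) + 0.05
      w / sum(w)
    }, numeric(n_bins)))
    rownames(masses) <- c("B", "E", "N")
    list(cuts = cuts, masses = masses)
  })
  structure(list(priors = c(B = 1, E = 1, N = 1) / 3, features = features,
                 transform = "log1p", n_bins = n_bins, pseudocount = 1,
                 ratio_pseudocount = 0.1, n_train = c(B = 0, E = 0, N = 0),
                 version = 1L),
            class = "best_nbc")
}

# independent direct-product posterior/LOD oracle (no log space, no
# findInterval): bin index by counting exceeded cut points
oracle_predict <- function(model, fv) {
  x <- log1p(fv)
  lik <- vapply(c("B", "E", "N"), function(cl) {
    p <- model$priors[[cl]]
    for (j in 1:6) {
      bin <- sum(x[j] > model$features[[j]]$cuts) + 1
      p <- p * model$features[[j]]$masses[cl, bin]
    }
    p
  }, 0)
  list(post = lik / sum(lik),
       lod = log(lik[["B"]] / max(lik[["E"]], lik[["N"]])))
}

# write lines to a throw-away file and return its path
textConnection_file <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

.fixture_cache <- new.env(parent = emptyenv())

reference_dataset <- function(seed = 1, spike_scale = 1) {
  key <- sprintf("ds_%d_%g", seed, spike_scale)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(seed = seed, spike_scale = spike_scale)
    .fixture_cache[[key]] <- generate_synthetic_dataset(
      cfg, file.path(tempdir(), key))
  }
  .fixture_cache[[key]]
}

reference_run <- function(seed = 1, spike_scale = 1) {
  key <- sprintf("run_%d_%g", seed, spike_scale)
  if (is.null(.fixture_cache[[key]])) {
    ds <- reference_dataset(seed, spike_scale)
    .fixture_cache[[key]] <- suppressWarnings(run_pipeline(
      ds$paths$genes, ds$paths$reads_plus, ds$paths$reads_minus,
      ds$paths$mapability, ds$config$chrom_sizes,
      file.path(tempdir(), key), h3k4me3 = ds$paths$h3k4me3,
      labels = ds$paths$labels))
  }
  .fixture_cache[[key]]
}
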