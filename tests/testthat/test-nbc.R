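flat1 <- flat_mapability(1)

test_that("training windows are centred on TSS and transcript midpoints", {
  act <- mk_transcripts("chr1", 10000, 20000, "+")
  tw <- build_training_windows(act, act, c(chr1 = 1e6), n_intergenic = 5,
                               seed = 1)
  expect_equal(c(tw$B$start, tw$B$end), c(9000, 11000))
  expect_equal(tw$B$strand, "+")
  expect_equal(c(tw$E$start, tw$E$end), c(14000, 16000))
  expect_equal(nrow(tw$N), 5)
  # N regions avoid all transcripts and are seed-reproducible
  expect_false(any(overlaps_peaks(
    tw$N, genomic_intervals("chr1", 10000, 20000))))
  tw2 <- build_training_windows(act, act, c(chr1 = 1e6), n_intergenic = 5,
                                seed = 1)
  expect_identical(tw, tw2)
  tw3 <- build_training_windows(act, act, c(chr1 = 1e6), n_intergenic = 5,
                                seed = 2)
  expect_false(identical(tw$N, tw3$N))
})

test_that("intergenic placement fails loudly on a fully covered genome", {
  act <- mk_transcripts("chr1", 0, 99000, "+")
  expect_error(build_training_windows(act, act, c(chr1 = 1e5),
                                      n_intergenic = 3, seed = 1,
                                      max_tries = 50),
               "could not place")
})

test_that("feature extraction produces the six densities and ratios", {
  # window [2000,4000)+ : 10 plus anchors (5/kb); 3' neighbour [4000,6000):
  # 2 plus anchors (1/kb); 5' neighbour empty
  tr <- mk_track("chr1", plus = c(seq(2100, 3900, length.out = 10),
                                  c(4500, 5500)),
                 minus = seq(2050, 3950, length.out = 6))
  w <- genomic_intervals("chr1", 2000, 4000, "+")
  fx <- extract_features(tr, w, flat1, ratio_pseudocount = 0)
  expect_true(fx$ok)
  f <- fx$features[1, ]
  expect_equal(unname(f["f1"]), 5)
  expect_equal(unname(f["f2"]), 3)
  expect_equal(unname(f["f3"]), 5 / 1)
  expect_equal(unname(f["f6"]), Inf)  # zero upstream antisense, pc = 0
  # symmetric pseudocount: zero reads everywhere -> ratios exactly 1
  tr0 <- mk_track("chr1", plus = numeric(0))
  fx0 <- extract_features(tr0, w, flat1, ratio_pseudocount = 0.1)
  expect_equal(unname(fx0$features[1, ]), c(0, 0, 1, 1, 1, 1))
  # all densities equal and nonzero -> all ratios 1
  tru <- mk_track("chr1", plus = seq(25, 99975, by = 50),
                  minus = seq(10, 99960, by = 50))
  fxu <- extract_features(tru, w, flat1, ratio_pseudocount = 0)
  expect_equal(unname(fxu$features[1, 3:6]), rep(1, 4))
})

test_that("strand-relative 3'/5' directions flip on the minus strand", {
  # plus anchors only downstream (genomically right) of the window
  tr <- mk_track("chr1", plus = seq(4100, 5900, length.out = 8),
                 minus = seq(4100, 5900, length.out = 4))
  wp <- genomic_intervals("chr1", 2000, 4000, "+")
  wm <- genomic_intervals("chr1", 2000, 4000, "-")
  fp <- extract_features(tr, wp, flat1, 0.1)$features[1, ]
  fm <- extract_features(tr, wm, flat1, 0.1)$features[1, ]
  # for the + window the right neighbour is 3'; for the - window it is 5'
  expect_lt(unname(fp["f3"]), 1)
  expect_equal(unname(fp["f5"]), 1)
  expect_lt(unname(fm["f5"]), 1)
  expect_equal(unname(fm["f3"]), 1)
  # sense/antisense swap between the two strands of the same window
  tr2 <- mk_track("chr1", plus = seq(2100, 3900, length.out = 10))
  f2p <- extract_features(tr2, wp, flat1, 0.1)$features[1, ]
  f2m <- extract_features(tr2, wm, flat1, 0.1)$features[1, ]
  expect_equal(unname(f2p["f1"]), 5)
  expect_equal(unname(f2m["f2"]), 5)
  expect_equal(unname(f2m["f1"]), 0)
})

test_that("windows with undefined densities or missing flanks are refused", {
  tr <- mk_track("chr1", plus = c(100, 2100))
  w_edge <- genomic_intervals("chr1", 0, 2000, "+")  # no 5' flank possible
  expect_false(extract_features(tr, w_edge, flat1)$ok)
  w <- genomic_intervals("chr1", 2000, 4000, "+")
  expect_false(extract_features(tr, w, flat_mapability(0.01))$ok)
  expect_false(extract_features(tr, w, flat1,
                                chrom_sizes = c(chr1 = 5000))$ok)
})

test_that("Laplace smoothing gives the hand-computed bin masses", {
  # pooled quantile bins stay distinct (B and N spread over 810 of 900
  # pooled values); the 90 E values all land in the top bin, so its
  # Laplace-smoothed mass is (90 + 1) / (90 + 10)
  spread <- matrix(rep(seq(0.01, 20, length.out = 405), 6), ncol = 6)
  concentrated <- matrix(rep(seq(29.9, 30.1, length.out = 90), 6), ncol = 6)
  colnames(spread) <- colnames(concentrated) <- paste0("f", 1:6)
  m <- fit_best_nbc(list(B = spread, E = concentrated, N = spread),
                    n_bins = 10, pseudocount = 1, min_class_size = 10)
  masses_E <- m$features[[1]]$masses["E", ]
  expect_equal(length(masses_E), 10)
  expect_equal(max(masses_E), 91 / 100)
  expect_equal(sort(unique(round(masses_E, 10))),
               c(round(1 / 100, 10), round(91 / 100, 10)))
  # identical training values -> identical distributions
  expect_equal(m$features[[1]]$masses["B", ], m$features[[1]]$masses["N", ])
  # masses sum to one per (class, feature)
  for (j in 1:6)
    expect_equal(unname(rowSums(m$features[[j]]$masses)), rep(1, 3),
                 tolerance = 1e-9)
  expect_equal(unname(sum(m$priors)), 1)
})

test_that("classes below the minimum training size are rejected", {
  small <- matrix(stats::runif(20 * 6), ncol = 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  expect_error(fit_best_nbc(list(B = small, E = small, N = small),
                            min_class_size = 50), "training windows")
})

test_that("posterior and LOD match the direct-product oracle", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_model()
    fv <- stats::rexp(6, 1 / 3)
    names(fv) <- paste0("f", 1:6)
    o <- oracle_predict(m, fv)
    p <- predict(m, matrix(fv, 1, dimnames = list(NULL, names(fv))))
    expect_equal(unname(unlist(p[1, c("post_B", "post_E", "post_N")])),
                 unname(o$post), tolerance = 1e-9)
    expect_equal(p$lod, unname(o$lod), tolerance = 1e-9)
    expect_equal(lod_score(m, matrix(fv, 1)), unname(o$lod),
                 tolerance = 1e-9)
  }
})

test_that("exact likelihood ties resolve to N and LOD boundaries behave", {
  m <- random_model()
  # force all classes identical for every feature -> posterior 1/3 each
  for (j in 1:6) {
    m$features[[j]]$masses["E", ] <- m$features[[j]]$masses["B", ]
    m$features[[j]]$masses["N", ] <- m$features[[j]]$masses["B", ]
  }
  p <- predict(m, matrix(rep(1, 6), 1))
  expect_equal(unname(unlist(p[1, 1:3])), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(p$class, "N")
  expect_equal(p$lod, 0)
  # B likelihood e^2.5 times the best alternative -> LOD exactly 2.5,
  # which is NOT high-confidence under the strict rule
  m2 <- m
  for (j in 1:6)
    m2$features[[j]]$masses["B", ] <-
      m$features[[j]]$masses["B", ] * exp(2.5 / 6)
  p2 <- predict(m2, matrix(rep(1, 6), 1))
  expect_equal(p2$lod, 2.5, tolerance = 1e-12)
  expect_false(p2$lod > 2.5)
  expect_equal(p2$class, "B")
})

test_that("with equal priors the B call is equivalent to LOD > 0", {
  set.seed(8)
  for (i in 1:20) {
    m <- random_model()
    fm <- matrix(stats::rexp(6 * 50, 1 / 3), ncol = 6)
    p <- predict(m, fm)
    expect_equal(p$class == "B", p$lod > 0)
  }
})

test_that("ratio features are invariant to scaling all counts (pc = 0)", {
  tr1 <- mk_track("chr1", plus = seq(2010, 7990, by = 20),
                  minus = seq(2015, 7995, by = 40))
  tr3 <- mk_track("chr1", plus = rep(seq(2010, 7990, by = 20), 3),
                  minus = rep(seq(2015, 7995, by = 40), 3))
  w <- genomic_intervals("chr1", 4000, 6000, "+")
  f1 <- extract_features(tr1, w, flat1, ratio_pseudocount = 0)$features
  f3 <- extract_features(tr3, w, flat1, ratio_pseudocount = 0)$features
  expect_equal(f3[, 3:6], f1[, 3:6])
  expect_equal(f3[, 1:2], 3 * f1[, 1:2])
})

test_that("exclusion mask covers TSS, gene ends and peaks and merges", {
  tt <- mk_transcripts("chr1", 100000, 120000, "+")
  mk <- exclusion_mask(tt, radius_bp = 7000)
  iv <- mask_intervals(mk)
  expect_equal(iv$start, c(93000, 112999))
  expect_equal(iv$end, c(107000, 126999))
  # overlapping zones merge into one
  tt2 <- mk_transcripts("chr1", 100000, 110000, "+")
  iv2 <- mask_intervals(exclusion_mask(tt2, radius_bp = 7000))
  expect_equal(nrow(iv2), 1)
  expect_equal(c(iv2$start, iv2$end), c(93000, 116999))
  # peaks contribute [start - r, end + r)
  pk <- genomic_intervals("chr2", 50000, 50400)
  iv3 <- mask_intervals(exclusion_mask(tt[0, ], pk, radius_bp = 7000))
  expect_equal(c(iv3$start, iv3$end), c(43000, 57400))
  expect_equal(nrow(mask_intervals(exclusion_mask(tt[0, ]))), 0)
})

test_that("a zero-read genome yields no high-confidence BEST windows", {
  run <- reference_run()
  tr0 <- mk_track("chrS1")
  ds <- reference_dataset()
  map <- read_mapability(ds$paths$mapability)
  tt <- read_transcripts(ds$paths$genes)
  mask <- exclusion_mask(tt, read_peaks(ds$paths$h3k4me3), 7000)
  pred <- scan_genome(run$model, tr0, map, mask, c(chrS1 = 5e6))
  expect_equal(sum(pred$high_confidence), 0)
})

test_that("masked windows and their flanks never appear in scan output", {
  run <- reference_run()
  ds <- reference_dataset()
  tt <- read_transcripts(ds$paths$genes)
  mask <- exclusion_mask(tt, read_peaks(ds$paths$h3k4me3), 7000)
  pred <- run$predictions
  miv <- mask_intervals(mask)
  expect_false(any(overlaps_peaks(pred, miv)))
  # every scanned window satisfies the B <=> LOD > 0 equivalence
  expect_equal(pred$class == "B", pred$lod > 0)
})

test_that("model serialisation round-trips predictions exactly", {
  run <- reference_run()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(run$model, f)
  m2 <- read_model(f)
  set.seed(3)
  fm <- matrix(stats::rexp(6 * 40, 1 / 3), ncol = 6)
  expect_equal(predict(m2, fm), predict(run$model, fm))
  expect_equal(m2$ratio_pseudocount, run$model$ratio_pseudocount)
})
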