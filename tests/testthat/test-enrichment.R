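# closed-form Pearson chi-squared for a 2x2 table, the independent oracle
chi2_closed_form <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  (a * d - b * c_)^2 * N / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

test_that("background sampling is seeded, mask-avoiding and reproducible", {
  mask <- exclusion_mask(mk_transcripts("chr1", 40000, 60000, "+"),
                         radius_bp = 7000)
  gs <- c(chr1 = 2e5)
  bg1 <- sample_background_windows(200, 2000, mask, gs, seed = 9)
  bg2 <- sample_background_windows(200, 2000, mask, gs, seed = 9)
  expect_identical(bg1, bg2)
  expect_false(identical(bg1,
                         sample_background_windows(200, 2000, mask, gs,
                                                   seed = 10)))
  # every window disjoint from the mask, checked exhaustively
  miv <- mask_intervals(mask)
  expect_false(any(overlaps_peaks(bg1, miv)))
  # extra exclusions honoured too
  extra <- genomic_intervals("chr1", 100000, 150000)
  bg3 <- sample_background_windows(100, 2000, mask, gs, seed = 1,
                                   extra_exclusions = extra)
  expect_false(any(overlaps_peaks(bg3, extra)))
})

test_that("a mask leaving a single slot forces placement into it", {
  # free space only [100000, 102000) on a 2e5 chromosome
  mask <- structure(list(chr1 = cbind(start = c(0, 102000),
                                      end = c(100000, 2e5))),
                    class = "exclusion_mask")
  bg <- sample_background_windows(1, 2000, mask, c(chr1 = 2e5), seed = 4,
                                  max_tries = 10000)
  expect_equal(bg$start, 100000)
  # infeasible space errors with the shortfall
  mask_all <- structure(list(chr1 = cbind(start = 0, end = 2e5)),
                        class = "exclusion_mask")
  expect_error(sample_background_windows(1, 2000, mask_all, c(chr1 = 2e5),
                                         seed = 4, max_tries = 50),
               "could not place")
})

test_that("chi-squared matches the hand-derived example and closed form", {
  r <- chi_squared_2x2(matrix(c(30, 70, 10, 90), 2, 2, byrow = TRUE))
  expect_equal(r$chi2, 12.5)
  # equal rows: no association
  r0 <- chi_squared_2x2(matrix(c(25, 75, 25, 75), 2, 2, byrow = TRUE))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  set.seed(13)
  for (i in 1:100) {
    t <- matrix(stats::rpois(4, 40) + 1, 2, 2)
    r <- chi_squared_2x2(t)
    expect_equal(r$chi2, chi2_closed_form(t[1, 1], t[1, 2], t[2, 1],
                                          t[2, 2]),
                 tolerance = 1e-9)
    expect_equal(r$p, stats::pchisq(r$chi2, df = 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_squared_2x2(matrix(c(0, 0, 5, 5), 2, 2)),
               "zero marginal")
})

test_that("overlap fraction counts windows touching any peak", {
  wins <- genomic_intervals("chr1", c(0, 1000, 2000, 3000),
                            c(500, 1500, 2500, 3500))
  peaks <- genomic_intervals("chr1", c(100, 1100, 2100), c(150, 1150, 2150))
  expect_equal(overlap_fraction(wins, peaks), 0.75)
  expect_equal(overlap_fraction(wins, peaks[0, ]), 0)
  # abutting intervals do not overlap under half-open coordinates
  expect_equal(overlap_fraction(genomic_intervals("chr1", 0, 500),
                                genomic_intervals("chr1", 500, 600)), 0)
  # invariant to peak order and to splitting one peak in two
  shuffled <- peaks[c(3, 1, 2), ]
  expect_equal(overlap_fraction(wins, shuffled), 0.75)
  split_pk <- genomic_intervals("chr1", c(100, 125, 1100, 2100),
                                c(125, 150, 1150, 2150))
  expect_equal(overlap_fraction(wins, split_pk), 0.75)
})

test_that("overlap enrichment recovers planted peak rates q/r", {
  ds <- reference_dataset()
  peaks <- read_peaks(ds$paths$peaks_DHS, "DHS")
  controls <- read_peaks(ds$paths$controls_DHS, "controls")
  truth <- genomic_intervals(ds$truth$chrom, ds$truth$start, ds$truth$end)
  er <- overlap_enrichment(truth, controls, peaks)
  q <- 0.8; r <- 0.1
  se_fold <- (q / r) * sqrt(q * (1 - q) / q^2 / nrow(truth) +
                              r * (1 - r) / r^2 / nrow(controls))
  expect_lt(abs(er$fold - q / r), 3 * se_fold)
  expect_lt(er$p, 1e-5)
})

test_that("mark representation is an input-normalised log ratio", {
  loci <- genomic_intervals("chr1", c(10000, 30000), c(12000, 32000))
  bg <- genomic_intervals("chr1", c(50000, 70000), c(52000, 72000))
  mk_cov <- function(regions, per_bp) {
    pos <- unlist(mapply(function(s, e, n) seq(s, e - 1, length.out = n),
                         regions$start, regions$end,
                         round(per_bp * (regions$end - regions$start)),
                         SIMPLIFY = FALSE))
    mk_track("chr1", plus = pos)
  }
  # treatment twice as dense at loci as background, input flat
  treat <- mk_track("chr1",
                    plus = c(mk_cov(loci, 0.2)$plus$chr1,
                             mk_cov(bg, 0.1)$plus$chr1))
  input <- mk_track("chr1", plus = c(mk_cov(loci, 0.05)$plus$chr1,
                                     mk_cov(bg, 0.05)$plus$chr1))
  mr <- mark_representation(treat, input, loci, bg)
  expect_equal(mr$ln_fold, log(2), tolerance = 1e-9)
  # treatment identical to input: exact self-normalisation to zero
  mr0 <- mark_representation(input, input, loci, bg)
  expect_identical(mr0$ln_fold, 0)
  # swapping loci and background negates the log fold
  mr_sw <- mark_representation(treat, input, bg, loci)
  expect_equal(mr_sw$ln_fold, -mr$ln_fold, tolerance = 1e-9)
  # zero pooled density in any term flags the result undefined
  empty <- mk_track("chr1")
  expect_true(is.na(mark_representation(empty, input, loci, bg)$ln_fold))
  # replicates: per-replicate values and their spread are reported
  mr2 <- mark_representation(list(treat, input), input, loci, bg)
  expect_equal(length(mr2$replicates), 2)
  expect_equal(mr2$replicates[2], 0)
  expect_equal(mr2$sd, stats::sd(mr2$replicates))
})
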