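flat1 <- flat_mapability(1)

test_that("peaks are categorised with active-transcript precedence", {
  tt <- mk_transcripts("chr1", c(10000, 50000), c(20000, 60000),
                       c("+", "-"))
  active <- tt$accession[1]
  pk <- genomic_intervals("chr1", c(12000, 52000, 80000, 19500),
                          c(12400, 52400, 80400, 50200))
  cats <- categorize_peaks(pk, tt, active)
  expect_equal(cats, c("transcribed_intragenic", "nontranscribed_intragenic",
                       "intergenic", "transcribed_intragenic"))
})

test_that("promoter-proximal peaks are discarded with their flanks", {
  tt <- mk_transcripts("chr1", 100000, 120000, "+")
  pk <- read_peaks(textConnection_file(c(
    "chr1\t140000\t140400",   # flank ends 15.6 kb from gene end: kept
    "chr1\t127500\t127900",   # 5-kb flank reaches 122500, 2.5 kb clear: kept
    "chr1\t126000\t126400"))) # flank reaches 121000, 1 kb from gene end: out
  kept <- filter_promoter_proximal(pk, tt, flank_bp = 5000,
                                   radius_bp = 2000)
  expect_equal(kept$start, c(127500, 140000))
  # empty exclusion inputs retain everything
  expect_equal(nrow(filter_promoter_proximal(pk, tt[0, ])), 3)
})

test_that("proportional bins reproduce the 300-bp worked example", {
  b <- proportional_bins(10000, 10300, flank_bp = 5000, bin_bp = 150)
  up1 <- b[b$zone == "upstream", ][sum(b$zone == "upstream"), ]
  expect_equal(c(up1$prop_lo, up1$prop_hi), c(-0.5, 0))
  inside <- b[b$zone == "peak", ]
  expect_equal(inside$prop_lo, c(0, 0.5))
  expect_equal(inside$prop_hi, c(0.5, 1))
  down1 <- b[b$zone == "downstream", ][1, ]
  expect_equal(c(down1$prop_lo, down1$prop_hi), c(1, 1.5))
  # bins are the affine map x -> (x - peak_start) / L applied to 150-bp tiles
  expect_equal(b$prop_hi - b$prop_lo,
               (b$end - b$start) / 300, tolerance = 1e-12)
  # flanks cover 5 kb with a truncated outermost bin
  expect_equal(min(b$start), 5000)
  expect_equal(max(b$end), 15300)
})

test_that("uniform read density gives relative density one everywhere", {
  tr <- mk_track("chr1", plus = seq(2, 99998, by = 4),
                 minus = seq(1, 99997, by = 4))
  pk <- genomic_intervals("chr1", c(30000, 60000), c(30300, 60900))
  prof <- proportional_profile(pk, tr, flat1, flank_bp = 3000, bin_bp = 150)
  got <- prof[prof$n_regions > 0, ]
  expect_true(all(abs(got$mean_sense - 1) < 0.35))
  expect_equal(mean(got$mean_sense), 1, tolerance = 0.05)
})

test_that("per-region length-weighted mean of relative density is one", {
  set.seed(21)
  for (i in 1:10) {
    L <- sample(200:2000, 1)
    s <- 50000
    tr <- mk_track("chr1",
                   plus = sample((s - 6000):(s + L + 6000), 400,
                                 replace = TRUE),
                   minus = sample((s - 6000):(s + L + 6000), 300,
                                  replace = TRUE))
    b <- proportional_bins(s, s + L, 5000, 150)
    win <- genomic_intervals("chr1", b$start, b$end, "*")
    d <- window_density(tr, win, flat1, "plus")
    rel <- d / (sum(d * (b$end - b$start)) / sum(b$end - b$start))
    lw <- sum(rel * (b$end - b$start)) / sum(b$end - b$start)
    expect_equal(lw, 1, tolerance = 0.01)
  }
})

test_that("aggregating N identical regions equals the single-region profile", {
  tr_pos <- c(seq(29000, 29990, by = 40), seq(30000, 30290, by = 10),
              seq(30300, 31300, by = 25))
  tr <- mk_track("chr1", plus = tr_pos, minus = tr_pos - 7)
  one <- genomic_intervals("chr1", 30000, 30300)
  prof1 <- proportional_profile(one, tr, flat1, flank_bp = 1000,
                                bin_bp = 150)
  # identical copies of the same region (same coordinates repeated)
  many <- one[rep(1, 5), ]
  prof5 <- proportional_profile(many, tr, flat1, flank_bp = 1000,
                                bin_bp = 150)
  expect_equal(prof5$mean_sense, prof1$mean_sense, tolerance = 1e-12)
  expect_equal(prof5$mean_antisense, prof1$mean_antisense,
               tolerance = 1e-12)
  # and the profile is invariant to peak ordering
  two <- genomic_intervals("chr1", c(30000, 60000), c(30300, 60500))
  tr2 <- mk_track("chr1", plus = c(tr_pos, seq(59000, 61500, by = 20)))
  pa <- proportional_profile(two, tr2, flat1, 1000, 150)
  pb <- proportional_profile(two[2:1, ], tr2, flat1, 1000, 150)
  expect_equal(pa, pb)
})

test_that("gene metaprofile recovers a planted TSS spike, strand-aware", {
  set.seed(31)
  n <- 30
  starts <- seq(20000, by = 30000, length.out = n)
  tt <- mk_transcripts("chr1", starts, starts + 8000,
                       rep(c("+", "-"), length.out = n))
  plus_pos <- minus_pos <- list()
  for (i in seq_len(n)) {
    t <- tt[i, ]
    body <- sample(t$start:(t$end - 1), 60, replace = TRUE)
    if (t$strand == "+") {
      sp <- sample(t$tss:(t$tss + 149), 150, replace = TRUE)
      as <- sample((t$tss - 200):(t$tss - 1), 100, replace = TRUE)
      plus_pos <- c(plus_pos, list(body), list(sp))
      minus_pos <- c(minus_pos, list(as))
    } else {
      sp <- sample((t$tss - 149):t$tss, 150, replace = TRUE)
      as <- sample((t$tss + 1):(t$tss + 200), 100, replace = TRUE)
      minus_pos <- c(minus_pos, list(body), list(sp))
      plus_pos <- c(plus_pos, list(as))
    }
  }
  tr <- mk_track("chr1", plus = unlist(plus_pos), minus = unlist(minus_pos))
  prof <- gene_metaprofile(tt, tr, flat1, n_bins = 40)
  mids <- (prof$bin_lo + prof$bin_hi) / 2
  expect_lt(abs(mids[which.max(prof$mean_sense)]), 0.05)
  peak_anti <- mids[which.max(prof$mean_antisense)]
  expect_lt(peak_anti, 0)
  expect_gt(peak_anti, -0.15)
  # a minus-strand gene with mirrored reads contributes symmetrically
  tp <- mk_transcripts("chr1", 10000, 18000, "+")
  trp <- mk_track("chr1", plus = seq(10000, 10400, by = 2))
  tm <- mk_transcripts("chr1", 10000, 18000, "-")
  trm <- mk_track("chr1", minus = 27999 - seq(10000, 10400, by = 2))
  pp <- gene_metaprofile(tp, trp, flat1, n_bins = 20)
  pm <- gene_metaprofile(tm, trm, flat1, n_bins = 20)
  expect_equal(pm$mean_sense, pp$mean_sense, tolerance = 1e-9)
})

test_that("a read-free track yields an all-zero metaprofile", {
  tt <- mk_transcripts("chr1", 10000, 18000, "+")
  prof <- gene_metaprofile(tt, mk_track("chr1"), flat1, n_bins = 10)
  expect_true(all(prof$mean_sense == 0))
  expect_true(all(prof$mean_antisense == 0))
})

test_that("pausing index is the promoter-to-body density ratio", {
  # 50 reads in the 1-kb promoter window, 20 over the 4-kb body
  tt <- mk_transcripts("chr1", 10000, 15000, "+")
  tr <- mk_track("chr1", plus = c(sample(10000:10999, 50, replace = TRUE),
                                  sample(11000:14999, 20, replace = TRUE)))
  pi <- pausing_index(tt, tr, flat1)
  expect_equal(pi$promoter_density, 50)
  expect_equal(pi$body_density, 5)
  expect_equal(pi$index, 10)
  # uniform density: index 1 (exact with aligned counts)
  tru <- mk_track("chr1", plus = seq(10000, 14999, by = 10))
  piu <- pausing_index(tt, tru, flat1)
  expect_equal(piu$index, 1)
  # zero body density: undefined, flagged as NA
  trp <- mk_track("chr1", plus = sample(10000:10999, 30, replace = TRUE))
  expect_true(is.na(pausing_index(tt, trp, flat1)$index))
  # too-short transcripts are refused
  short <- mk_transcripts("chr1", 10000, 11500, "+")
  expect_true(is.na(pausing_index(short, tru, flat1)$index))
})

test_that("pausing index anti-correlates with expression when spikes are capped", {
  set.seed(41)
  n <- 40
  starts <- seq(20000, by = 20000, length.out = n)
  tt <- mk_transcripts("chr1", starts, starts + 6000, "+")
  body_rate <- stats::rlnorm(n, log(10), 0.8)   # reads/kb
  spike_reads <- 60                             # constant pause occupancy
  pos <- list()
  for (i in seq_len(n)) {
    t <- tt[i, ]
    nb <- stats::rpois(1, body_rate[i] * 6)
    pos <- c(pos, list(sample(t$start:(t$end - 1), nb, replace = TRUE)),
             list(sample(t$tss:(t$tss + 149), spike_reads, replace = TRUE)))
  }
  tr <- mk_track("chr1", plus = unlist(pos))
  pi <- pausing_index(tt, tr, flat1)
  ok <- !is.na(pi$index)
  rho <- stats::cor(pi$index[ok], pi$body_density[ok], method = "spearman")
  expect_lt(rho, -0.5)
})
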