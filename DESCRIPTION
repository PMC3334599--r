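Package: bestscan
Title: Prediction of Bidirectional Expression of Short Transcripts from
    Nascent Transcription Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate active regulatory elements from stranded
    nascent-transcription (GRO-seq-like) read data by modelling the
    signature of promoter-proximal RNA polymerase pausing: bidirectional
    expression of short transcripts (BEST).  A three-class Naive Bayes
    classifier is trained on 2-kb windows at active promoters, active
    gene bodies, and random intergenic regions, then scanned genome-wide
    over non-promoter windows on both strands, scoring each window with a
    natural-log odds (LOD) score.  Supporting tools compute
    mapability-normalised read densities, call actively transcribed genes
    by a maximal-accuracy ROC cutoff, quantify overlap enrichment of
    predictions with chromatin peak sets, build proportional-distance
    sense/antisense metaprofiles at peaks and genes, compute
    promoter-proximal pausing indices, and generate fully synthetic
    seeded datasets with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
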