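Package: frygan
Title: Adversarial Regression for Frying-Oil Deterioration Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts four frying-oil quality indices (acid value, total
    polar compounds, triacylglycerol polymers, trans fatty acids) from
    frying time and temperature with a GAN-based regression model: a
    feed-forward generator maps (time, temperature) to the four indices
    and a discriminator scores index vectors as real or generated, trained
    adversarially together with a mean-squared-error term. Includes a
    calibrated synthetic-data generator for the frying experiment design,
    moving-average and vector-autoregression baselines, MAE/MSE/MASE
    forecast metrics, threshold-based deterioration verdicts, and an
    end-to-end benchmarking pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
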