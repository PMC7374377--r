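Package: saliseg
Title: Noise-Robust Feature-Saliency Fuzzy Clustering for Greyscale Image
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised segmentation of noisy 8-bit greyscale images by a
    feature-saliency fuzzy Gaussian mixture model with embedded neighbourhood
    information constraints.  Per-pixel class memberships are regularised by a
    Kullback-Leibler divergence penalty towards a Markov spatial prior built
    from windowed class likelihoods, and a noise smoothing factor inflates the
    prior of locally dominant classes to suppress impulse and Gaussian noise.
    Includes phantom-image and noise simulators (Gaussian, salt-and-pepper,
    multiplicative, mixed), a fuzzy C-means baseline and initialiser, and
    PSNR / misclassification-rate evaluation with optimal label alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
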