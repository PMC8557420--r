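Package: admixpulse
Title: Dating Gene Flow with an Extended Admixture Pulse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of the mean time and duration of admixture
    from introgressed-segment lengths and ancestry linkage disequilibrium
    (ALD) decay curves. Implements the extended admixture pulse model, in
    which the per-generation migration rate follows a Gamma density, so
    that segment lengths are Lomax (Pareto type II) distributed and the
    ALD decay has a closed form. Provides closed-form densities and
    moments, the segment/ALD duality transforms, synthetic-data
    generation, maximum-likelihood and nonlinear least-squares inference,
    a parametric-bootstrap likelihood-ratio test against the simple
    single-generation pulse, power analysis, recombination-map utilities,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
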