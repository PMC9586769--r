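Package: hawkespd
Title: Drug-Effect Modelling of Monitored Physiological Series via a
    Self-Exciting Point-Process Kernel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the long-term effect of repeated drug administrations on a
    regularly sampled monitored physiological variable (e.g. one-minute heart
    rate) as a sinusoidal baseline plus a Hawkes-type self-exciting term whose
    excitation kernel is a dose sigmoid multiplied by a Gamma-shaped lag
    profile.  Provides a Haar maximal-overlap discrete wavelet transform
    (MODWT) for multiresolution trend extraction, Granger-causality F-tests to
    select the wavelet component most predictable from the dosing record,
    bounded multi-start quasi-Newton least-squares fitting of the
    eleven-parameter model with R-squared and Pearson-correlation evaluation,
    a simulation engine for study replication, and an end-to-end pipeline with
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
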