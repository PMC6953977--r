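Package: hsrm
Title: Robust Hankel Structured Rank Minimization for Dynamic Time-Series Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-order linear time-invariant (LTI) dynamics from
    multichannel trajectories corrupted by gross but sparse noise and missing
    entries, by minimizing an lq-regularized Schatten-p norm of a block-Hankel
    matrix with an ADMM solver and a scalable orthonormal-factorization
    variant. Includes deterministic subspace realization of the identified
    system, continuous output prediction, structured trajectory completion,
    tracklet stitching by generalized linear assignment, a synthetic benchmark
    generator for sparsely corrupted LTI outputs, and evaluation metrics
    (relative reconstruction error, Pearson correlation, ICC(3,1), MOTA, MMR).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
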