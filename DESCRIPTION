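Package: dwispan
Title: Question-Conditioned Span Extraction of DWI High-Signal Regions from
    Head-MRI Report Text
Version: 0.1.0
Authors@R:
    person("dwispan", "maintainers", email = "dwispan@example.org",
           role = c("aut", "cre"))
Description: Identifies body-part mentions reported as high-signal on
    diffusion-weighted imaging (DWI) in the free-text description section of
    head-MRI reports. Frames the task as machine reading comprehension: a
    fixed natural-language question is prepended to the report, a
    character-level encoder produces contextual representations, and learned
    start/end projections predict span boundaries that are paired by
    sequential matching. Also provides the classical two-step pipeline
    (BIOES sequence labeling with a linear-chain CRF, then mention-type
    classification) as a comparison system, BRAT standoff corpus I/O with
    offset-preserving text normalization, a synthetic annotated-report
    generator reproducing the statistical profile of such corpora, strict
    span-triple evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
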