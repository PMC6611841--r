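Package: aqueflow
Title: Cardiac and Respiratory Drivers of Pulsatile CSF Flow in the Cerebral Aqueduct
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-sensor intracranial pressure (ICP)
    recordings as drivers of cerebrospinal fluid (CSF) flow in the cerebral
    aqueduct. Forms differential pressure gradients from co-registered ICP
    channels, extracts and vets 6-minute windows, estimates cardiac and
    respiratory gradient amplitudes by spectral analysis, and maps them
    through the analytical Womersley solution for oscillatory flow in a
    rigid cylinder to peak volumetric flow rates, aqueductal stroke volumes
    and respiratory flow volumes. Includes a seeded synthetic-recording
    generator with known ground truth, an independent radial
    finite-difference solver used as a numerical oracle, a peak/valley
    flow-decomposition procedure, and cohort-level summaries with
    sleep-versus-awake comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
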