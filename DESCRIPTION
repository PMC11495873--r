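Package: nanodrach
Title: m6A Site Calling from Nanopore Direct RNA Sequencing Signal and Trace Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) at DRACH motifs from Oxford
    Nanopore direct RNA sequencing data. Raw per-read current intensity
    (signal) and basecaller base-probability (trace) streams are normalized,
    realigned to the reference transcriptome by a trace-based dynamic
    programming resquiggler, and cut into fixed-length five-channel read
    features at each DRACH site. A dilated causal convolution (WaveNet-style)
    encoder converts read features into embeddings, and a dual-stream
    multiple-instance learning aggregator converts 20-1000 read embeddings
    per site into a site-level modification probability; a separate
    pseudo-labelling head estimates per-site modification stoichiometry.
    Includes a full synthetic nanopore data generator (pore model, dwell
    times, trace sharpness, site-level mixing ratios) so the whole pipeline
    is trainable and testable without external data, plus evaluation
    utilities (silhouette analysis, ROC/PR metrics, motif tables) and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    optparse
Config/testthat/edition: 3
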