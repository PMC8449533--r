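Package: npmine
Title: Neuropeptide Precursor Annotation and GPCR Triage for Transcriptome Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining neuropeptidomes from decapod central-nervous-system
    transcriptomes: six-frame translation and ORF extraction, heuristic signal-peptide
    prediction with external overrides, prohormone convertase cleavage-site scanning
    (mono-, di- and tribasic), excision of precursor fragments, post-translational
    processing rules (C-terminal glycine amidation, N-terminal pyroglutamate),
    disulfide-pairing bookkeeping, motif-based neuropeptide family classification,
    hydropathy-based seven-transmembrane receptor vetting with neighbor-joining
    receptor trees, tissue presence/absence summaries, and a ground-truthed
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
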