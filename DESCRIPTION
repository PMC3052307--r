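Package: ubilys
Title: Window-Based Prediction of Protein Ubiquitylation Sites with
    Radial Basis Function Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification of ubiquitin-conjugated lysines from protein
    sequence and sequence-derived profiles.  Candidate lysines are encoded
    over a sliding window (default 41-mer, -20..+20) using amino-acid and
    amino-acid-pair composition, min-max-normalized BLOSUM62 rows, a 400-D
    summed position-specific scoring matrix transform, scaled solvent
    accessibility and one-hot secondary structure.  Discriminative features
    and window positions are ranked with the between-class/within-class
    F-score statistic, and classification uses a Gaussian radial basis
    function network with all training instances as centers and an
    output-weight matrix solved in closed form.  Includes homology-aware
    fragment redundancy reduction, stratified k-fold cross-validation with
    window-length and feature-combination sweeps, readers for FASTA,
    PSI-BLAST ASCII PSSM, ASA and secondary-structure profiles, and a
    synthetic-proteome generator that plants class signal at chosen window
    offsets so the whole pipeline is exercisable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
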