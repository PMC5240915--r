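Package: episcan
Title: Linear B-Cell Epitope Mapping from Peptide-Microarray Substitution Data
Version: 0.1.0
Authors@R:
    person("Array", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of high-density peptide-microarray single-amino-acid
    substitution experiments for mapping linear antibody (B-cell) epitopes. Maps measured
    peptides (native overlapping windows and their single-substitution derivatives) onto
    target protein sequences, rescales intensities to substitution values relative to the
    native-peptide median, and calls epitope positions per peptide with a one-tailed
    many-to-one Dunnett least-significant-difference test built on an equicorrelated
    multivariate-t quadrature engine. Substitution values of overlapping peptides are then
    pooled per protein residue to test the selectivity of every replacing amino acid
    against the global mean, yielding signed log10(p) sequence-logo scores and gap-tolerant
    epitope regions. Includes a seeded synthetic-data generator emulating full substitution
    and alanine-scan array designs with planted ground-truth epitopes, and a command-line
    interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
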