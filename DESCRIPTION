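Package: snvphylo
Title: Somatic SNV Lineage Trees from Multi-Sample Targeted Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs per-patient cell lineage trees from variant allele
    frequencies (VAFs) of somatic single nucleotide variants assayed by
    targeted deep sequencing across many tissue samples of the same
    individual. Implements presence/absence calling at a VAF cutoff with
    curated overrides, grouping of variants into phylogenetic classes with
    robustness assessment, perfect-phylogeny treebuilding with parsimonious
    resolution of mixed-lineage (two-component) samples, VAF-sum validation
    of inferred lineage mixtures, and inference of the minimum number of
    independent origins of recurrent hotspot mutations on the fixed tree.
    A ground-truthed simulator generates allele-count tables with realistic
    depth, sequencing error, normal-cell contamination, lineage mixing, and
    recurrent mutations, so every stage of the pipeline can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
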