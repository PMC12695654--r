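Package: cloneTrace
Title: Clonal Lineage Tracing of Hematopoietic Stem Cell Clones from
    Droplet Digital PCR and Somatic Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mutational lineage tracing of individual hematopoietic
    stem cell (HSC) clones in human bone marrow. Implements Bayesian estimation
    of mutant cell fractions (MCF) from duplex droplet digital PCR quadrant
    counts via a Poisson droplet-occupancy likelihood with a beta prior on the
    MCF and an exponential prior on extraction efficiency; posterior-overlap
    positivity calling; classification of clonal output across the platelet,
    erythroid, myeloid, B and T lineages into balanced, lineage-restricted and
    lineage-biased patterns using nearest-neighbour fold-change rules;
    conversion of mutation-count phylogenies of single-cell-derived colonies to
    an age scale from conception with Poisson confidence intervals on the
    timing of mutation acquisition; and clade-level lineage-concordance
    permutation tests and Moran's I with phylogenetic weights. A synthetic
    cohort generator produces donors, clones, droplet assays, colony read
    counts and phylogenies with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
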