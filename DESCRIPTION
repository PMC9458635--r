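Package: weedhyb
Title: Crop-Weed Hybrid Genome Analysis for Selfing Weeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genomes of crop-weed hybrid derivatives
    in predominantly self-fertilizing weeds, motivated by herbicide-resistant
    weedy rice. Provides ancestry-informative-marker (AIM) discovery between
    diverged inbred panels, supervised ancestry coefficients and admixture
    classification, a heterozygosity-decay estimator of generations since
    hybridization, a hidden Markov model for local ancestry along chromosomes
    with genome-wide weed-bias summaries, Weir-Cockerham FST and nucleotide
    diversity in sliding windows with dual weed-vs-crop / weed-vs-weed-ancestor
    comparisons at focal adaptive loci, median-joining haplotype networks with
    amino-acid-replacement annotation for a resistance gene, herbicide-injury
    phenotype binning, and a forward-in-time simulator of hybridization,
    selfing, recombination and selection that supplies ground truth for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
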