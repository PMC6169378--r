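Package: inrelate
Title: Maximum-Likelihood Pairwise Relatedness in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates pairwise genetic relatedness between diploid individuals
    sampled from structured or admixed populations, using multi-allelic
    (microsatellite-style) genotype panels. Population structure is modeled by
    the admixture model: per-individual ancestry proportions and subpopulation
    allele frequencies are estimated by an EM algorithm, and the resulting
    per-individual allele probabilities parametrize the conditional
    probabilities of observed identity-by-state modes given each of the nine
    condensed (Jacquard) identity-by-descent states. The nine IBD-state
    probabilities for a dyad are then estimated by constrained maximum
    likelihood on the unit simplex, in a full nine-state variant and a
    restricted outbred three-state variant, and converted to coancestry and
    relatedness coefficients. Also included: Fst-parametrized baseline
    estimators with a multi-allelic Weir-Cockerham theta estimator, a
    bootstrap-over-loci / Wald-test procedure that assigns dyads to pedigree
    categories, and a Mendelian gene-dropping simulator with labeled founder
    alleles that provides ground-truth IBD states for benchmarking.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
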