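Package: episwitch
Title: Heritable Epigenetic Switching of Digital NF-kB Responses in
    Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models all-or-nothing (digital) TLR2/NF-kB signaling in
    epithelial cell populations as a heritable two-state epigenetic switch
    with stochastic per-generation transitions on expanding cell lineages.
    Provides lineage-tree simulation, an exact pruning likelihood,
    maximum-likelihood estimation of the switching probabilities with
    profile-likelihood or bootstrap confidence intervals, Fitch parsimony
    reconstruction of ancestral responder states, prediction of
    responder-fraction relaxation toward the stationary fraction, and
    lineage relatedness concordance.  Companion modules featurize
    single-cell NF-kB nuclear/cytoplasmic translocation traces and call
    responders against media controls, test spatial clustering of
    responders with a label-permutation k-nearest-responder statistic,
    and quantify per-read promoter CpG methylation bimodality from
    nanopolish-style call tables with a two-component binomial mixture
    fitted by EM.  Seeded synthetic-data generators reproduce the
    statistical structure of each data type so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
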