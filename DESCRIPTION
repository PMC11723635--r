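Package: nbsim
Title: Multicellular Agent-Based Simulation of Neuroblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale multicellular model of neuroblastoma comprising a
    continuous-automaton microenvironment (voxel grid with oxygen, matrix and
    angiogenesis bookkeeping), stochastic neuroblastoma and Schwann cell
    agents with a 20-gene-product Bernoulli regulatory layer and a 24-subclone
    population structure, and a centre-based soft-sphere mechanical model
    relaxed by overdamped Euler iteration. Ships the four in-silico experiment
    designs built on the model (clonal competition, gene-expression
    sensitivity, composition/microenvironment sensitivity, and combination
    drug trials) together with their analysis procedures: outcome
    classification, clonal enrichment, drug-combination effectiveness
    labelling, bootstrap confidence intervals, principal component analysis,
    and Ward clustering with silhouette validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
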