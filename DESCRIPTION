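Package: metakin
Title: Toy Metadynamics and Binding Kinetics for Pseudoirreversible
    Receptor Antagonism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale models of slow-dissociating ("pseudoirreversible")
    GPCR antagonism. Provides a coarse-grained two-pocket ligand-receptor
    landscape with overdamped Langevin dynamics and well-tempered
    metadynamics on a distance collective variable; trajectory
    post-processing (ligand RMSD, a threshold dissociation rule, gatekeeper
    distance pairs, metastable-pose gate classification, pose clustering);
    a comparative protein-ligand interaction-fingerprint statistic (Qb)
    ranking residues by differential contact between two ligands; and the
    pharmacology kinetics toolchain: one-phase exponential decay half-life
    fits, log-linear pharmacokinetic fits, four-parameter logistic
    concentration-response fits, a two-step induced-fit ODE model of
    insurmountable antagonism, and a residence-time receptor-occupancy
    PK-PD model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
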