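Package: chemoflow
Title: Chemotaxis and Collective Motion in Dense Bacterial Suspensions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of dense suspensions of chemotactic,
    self-propelled rod-shaped bacteria confined to quasi two dimensions,
    with Hertzian steric contacts and screened (Hele-Shaw) pusher
    force-dipole hydrodynamics, coupled to an intracellular
    receptor-methylation chemotaxis pathway.  Companion Fourier image
    analysis tools quantify motility and collective flows: differential
    dynamic microscopy (DDM) with Schulz swimmer intermediate scattering
    function fits, global and local phase-differential velocimetry,
    kinetic-energy structure factors of coarse-grained velocity fields,
    velocity autocorrelation/decorrelation times, and chemotactic drift
    statistics, together with generators for the synthetic trajectories,
    image stacks, reference flow fields and attractant gradients that the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
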