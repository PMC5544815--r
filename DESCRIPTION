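Package: ecgi
Title: Electrocardiographic Imaging with Physiology-Based Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the potential-based inverse problem of electrocardiography:
    reconstruction of epicardial surface potentials from body-surface potential
    recordings through a volume-conductor transfer matrix. Provides classical
    Tikhonov regularization (orders 0-2, L-curve parameter selection) and
    physiology-based regularization (PBR), in which epicardial potentials are
    reconstructed as sparse (L1-constrained) combinations of spatial basis
    vectors obtained by singular value decomposition of simulated propagating
    action potentials. Includes synthetic torso-heart phantoms with a
    boundary-element forward solver and an analytic concentric-spheres oracle,
    simplified action-potential propagation on triangulated surfaces
    (FitzHugh-Nagumo and Luo-Rudy 1991 cell models), activation/recovery-time
    mapping with temporal and spatiotemporal criteria, pacing-site
    localization, and an end-to-end synthetic benchmark comparing PBR with
    Tikhonov reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, stats, utils, graphics
Suggests: testthat (>= 3.0.0), deSolve, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
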