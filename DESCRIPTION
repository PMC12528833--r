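Package: kelscape
Title: Kinetic-Energy Landscapes for Planar Reaching Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trajectory selection in planar sequential
    reaching tasks performed with a two-link exoskeleton. The package
    simulates straight and parabolically curved reaching trajectories with
    bell-shaped speed profiles, maps them between hand (Cartesian) and joint
    (shoulder-elbow angle) space through the exoskeleton's kinematics,
    computes kinetic-energy (KE) landscapes over trajectory-deviation levels,
    and predicts the deviation range ("safe KE range") within which KE is
    insensitive to deviation. It also provides behavioural metrics (movement
    onset detection, signed normalised trajectory deviation, spatial
    variability, deviation ellipses, cosine k-means submovement classes),
    session-trend summaries, resampled RMSE model comparison, and a
    synthetic multi-session study generator with recorded ground truth for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
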