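Package: amphisurf
Title: Acid-Base Interfacial Tension of Phospholipid Bilayers and
    Water-Bridge Trajectory Analysis
Version: 1.0.0
Authors@R:
    person("amphisurf", "developers", email = "amphisurf@example.org",
           role = c("aut", "cre"))
Description: Models the pH dependence of the interfacial tension of
    amphoteric phospholipid bilayers (DPPC, DPPE) through acid-base
    equilibria of the phosphate and amine headgroups: forward tension
    curves, speciation fractions, isoelectric points, buffer capacity, and
    Young-Laplace conversion of pressure/radius measurements. Includes a
    charge-balance pH solver for the Britton-Robinson universal buffer
    (with optional Davies activity correction), weighted least-squares
    fitting of tension curves with parameter-recovery benchmarking, and a
    molecular-trajectory toolkit that detects hydrogen bonds, water
    bridges and lipid-lipid contacts, builds normalized bridge/contact
    maps and event-duration distributions, and generates synthetic tension
    data and toy bilayer trajectories with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
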