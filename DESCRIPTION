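Package: polfid
Title: Nucleotide Selection Energetics and Transcription Fidelity for T7 RNA Polymerase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs potentials of mean force from umbrella-sampling
    window data by the weighted histogram analysis method (WHAM) with
    bootstrap uncertainties, estimates relative nucleotide binding free
    energies by the Bennett acceptance ratio through a thermodynamic cycle,
    assembles composite selection landscapes for cognate and non-cognate
    nucleotides, and solves a branched five-state nucleotide-addition-cycle
    master equation to obtain steady-state transcription-elongation error
    rates and kinetic-checkpoint selection energetics.  A synthetic-data
    generator draws Boltzmann-distributed biased samples from reference
    free-energy profiles and Crooks-consistent alchemical perturbation
    energies, so the full estimator chain can be exercised and validated
    without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
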