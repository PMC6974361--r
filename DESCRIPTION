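Package: splitdrive
Title: Stochastic Simulation of CRISPR Split Gene Drive Dynamics in Mosquito
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of CRISPR-based gene drive releases in
    Aedes aegypti metapopulations. Implements offspring-genotype probability
    tensors (inheritance cubes) for split drives, linked homing drives and
    inert disease-refractory alleles with sex-specific cleavage and
    homology-directed repair, resistant-allele formation and optional
    maternal Cas9 deposition; a daily-step, stage-structured (egg, larva,
    pupa, adult) stochastic mosquito life cycle with density-dependent
    larval mortality calibrated to an equilibrium adult population; a
    multi-patch landscape with adult migration and scheduled releases of
    transgenic males; seeded ensemble runs with carrier-frequency,
    allele-frequency and window-of-protection summaries; and a breeding
    cross module that forward-simulates G1/G2 cross count tables and
    estimates transmission and cleavage rates back from them.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
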