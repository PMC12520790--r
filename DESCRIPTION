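Package: androsim
Title: Forward-Time Simulation of Drug-Resistance Evolution Under Selfing,
    Outcrossing and Androdioecy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental, polygenic, forward-time population-genetic
    simulator of anthelmintic-resistance evolution in diploid nematode
    populations with selfing, outcrossing or mixed (androdioecious)
    reproduction. Genotypes over k unlinked biallelic loci are mapped to
    fitness through an additive cost/benefit model and a Hill-type
    pharmacodynamic dose-response curve; populations evolve through a
    serial-passage protocol in which the drug concentration climbs a
    ladder whenever mean egg output exceeds an escalation threshold.
    Includes Mendelian inheritance kernels, single-step Poisson mutation,
    multinomial census regulation, trajectory observables (allele
    frequencies, homozygous-locus counts, Shannon diversity, fixation
    times, concentration reached), scenario presets, and tab-separated
    output writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
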