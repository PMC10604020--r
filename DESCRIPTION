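Package: quinscreen
Title: Combinatorial Design and Multi-Stage Screening of Quinoline
    Antioxidant Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enumerates mono- to tri-substituted derivatives of a labeled
    heteroaromatic scaffold (quinoline by default) from a functional-group
    library, computes physicochemical descriptors and the Lipinski, Ghose,
    Veber, Egan and Muegge drug-likeness rule sets, screens out compounds
    with missing toxicity endpoints, and prioritizes the survivors with
    selection and elimination scores relative to a reference set of
    neuroprotectors. Downstream stages compute multiprotic acid-base
    microspecies fractions at physiological pH, build the electron and
    hydrogen-atom donation map (ionization potential versus minimum bond
    dissociation energy) against reference antioxidants, and aggregate
    per-species docking scores into fraction-weighted binding scores,
    per-enzyme log-ratio affinities versus natural substrates and a
    polygenic neuroprotection score. A synthetic-data generator emulates
    the external toxicity, pKa, reactivity and docking tables so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ChemmineOB
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
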