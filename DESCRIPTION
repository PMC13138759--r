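Package: vasodyn
Title: Simulation of Cerebral Arteriolar Vasodynamics and Vasomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A systems-level simulator of mouse cerebral arteriolar
    vasodynamics. Builds a segmented cerebrovascular network (pial tree,
    penetrating arterioles, downstream microvessels), solves steady-state
    Poiseuille hemodynamics at every vasodynamic time step, and couples it
    to two wall models: a macro-scale delayed-myogenic-response model that
    generates synchronized ~0.1 Hz vasomotion in the coupled network, and a
    phenomenological cellular model of a penetrating-arteriole segment
    (smooth-muscle and endothelial electrophysiology, mechanotransduction
    lags, four-state crossbridge mechanics) with virtual pressure-myography
    and voltage-clamp protocols. Neural and astrocytic drives (nitric-oxide
    impulses and steps, gamma-band envelopes, constriction-triggered
    potassium release) modulate the myogenic response for functional
    hyperemia experiments. Results are tidy tibbles with broom-style
    tidiers, summary metrics, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
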