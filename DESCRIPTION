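Package: ietolf
Title: Inelastic Electron Tunnelling Model of Olfactory Receptor Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculator and simulator for the "swipe card" model of odorant
    recognition, in which an olfactory receptor discriminates odorants by
    inelastic electron tunnelling: electron transfer from a donor to an
    acceptor site is gated by whether the odorant's vibrational quantum can
    absorb the donor-acceptor energy gap. Provides vibronically weighted
    Marcus-type transfer rates for the discriminating (one-quantum) and
    non-discriminating (elastic) channels, reorganization-energy sweeps and
    the channel-crossover solver, closed-form oscillator, electrostatic and
    charge-transport estimates, kinetic race models of receptor signalling
    with a seedable stochastic receptor-cycle simulator, and a spectral
    discrimination layer that decides which odorant vibrational spectra
    activate which tuned receptors, including isotope-substitution
    transforms and a synthetic-spectrum generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
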