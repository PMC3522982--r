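# Shared fixtures, built in code.

# Default tuned-receptor parameter set (quantum 200 meV, S 0.1, lambda 30 meV,
# |t| 1 meV, kBT 0.027 eV)
default_params <- function(...) receptor_params(...)

# Hydrogen sulphide reduced to its detected symmetric S-H stretch
h2s_spectrum <- function() {
  odorant_spectrum("H2S", data.frame(
    label = "SH-sym-stretch", freq_cm1 = 2600, huang_rhys = 0.1, has_H = TRUE
  ))
}

# Decaborane's strongest B-H stretch sits ~25 cm^-1 from the H2S stretch
decaborane_spectrum <- function(offset = 25) {
  odorant_spectrum("decaborane", data.frame(
    label = "BH-stretch", freq_cm1 = 2600 + offset, huang_rhys = 0.12,
    has_H = TRUE
  ))
}

sulphuraceous_receptor <- function() {
  receptor_definition("sulphuraceous", tuned_frequency = 2600,
                      resolution_window = 25)
}

# Acetophenone-like spectrum: a high-frequency hydrogen-stretch cluster plus
# a hydrogen-free carbonyl band
acetophenone_like <- function() {
  odorant_spectrum("acetophenone-like", data.frame(
    label = c("CH-stretch-a", "CH-stretch-b", "CO-stretch"),
    freq_cm1 = c(2730, 3050, 1690),
    huang_rhys = c(0.10, 0.08, 0.15),
    has_H = c(TRUE, TRUE, FALSE)
  ))
}
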