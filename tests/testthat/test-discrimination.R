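test_that("spectrum files round-trip through TSV", {
  sp <- acetophenone_like()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f, name = sp$name)
  expect_equal(back$name, sp$name)
  expect_equal(back$modes, sp$modes)
})

test_that("spectrum reading validates rows and reports positions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tfreq_cm1\thuang_rhys",
               "good\t2600\t0.1",
               "bad\t-100\t0.1"), f)
  expect_error(read_spectrum(f), "row\\(s\\): 2")
  writeLines(c("label\tfreq_cm1", "m\t2600"), f)
  expect_error(read_spectrum(f), "huang_rhys")
  writeLines("label\tfreq_cm1\thuang_rhys", f)
  expect_warning(sp <- read_spectrum(f), "no modes")
  expect_equal(nrow(sp$modes), 0)
})

test_that("spectrum construction enforces its invariants", {
  expect_error(odorant_spectrum("", data.frame()), "non-empty")
  expect_error(odorant_spectrum("x", data.frame(
    label = c("a", "a"), freq_cm1 = c(1, 2), huang_rhys = c(0.1, 0.1))),
    "duplicate")
  expect_error(odorant_spectrum("x", data.frame(
    label = "a", freq_cm1 = 100, huang_rhys = -0.1)), "Huang-Rhys")
})

test_that("the sulphuraceous receptor fires on H2S and on decaborane", {
  rec <- sulphuraceous_receptor()
  rep_h2s <- receptor_activation(h2s_spectrum(), rec)
  expect_true(rep_h2s$activated)
  expect_equal(rep_h2s$matching_modes$detuning, 0)
  # the B-H stretch sits exactly at the 25 cm^-1 edge: inclusive boundary
  rep_dec <- receptor_activation(decaborane_spectrum(offset = 25), rec)
  expect_true(rep_dec$activated)
  # a mode just outside the window is missed
  expect_false(receptor_activation(decaborane_spectrum(offset = 25.5),
                                   rec)$activated)
  # both odorants share the receptor: same combinatorial column
  m <- activation_matrix(list(h2s_spectrum(), decaborane_spectrum()),
                         list(rec))
  expect_true(all(m[, "sulphuraceous"]))
})

test_that("coupling range gates activation, boundaries inclusive", {
  rec <- receptor_definition("r", 2600, 25, coupling_range = c(0.01, 0.3))
  mk <- function(S) odorant_spectrum("x", data.frame(
    label = "m", freq_cm1 = 2600, huang_rhys = S))
  expect_true(receptor_activation(mk(0.01), rec)$activated)
  expect_true(receptor_activation(mk(0.3), rec)$activated)
  expect_false(receptor_activation(mk(0.005), rec)$activated)
  expect_false(receptor_activation(mk(0.5), rec)$activated)
  # the narrower efficient-detection preset
  expect_equal(coupling_range_preset("useful"), c(0.05, 0.3))
  rec_u <- receptor_definition("r", 2600, 25,
                               coupling_range = coupling_range_preset("useful"))
  expect_false(receptor_activation(mk(0.02), rec_u)$activated)
})

test_that("empty spectra never activate and empty panels give empty rows", {
  empty <- odorant_spectrum("nothing")
  expect_false(receptor_activation(empty, sulphuraceous_receptor())$activated)
  m <- activation_matrix(list(h2s_spectrum()), list())
  expect_equal(dim(m), c(1L, 0L))
  expect_error(activation_matrix(list(), list()), "at least one odorant")
})

test_that("activation depends only on the (frequency, S) multiset", {
  set.seed(41)
  receptors <- list(
    receptor_definition("a", 1000, 25), receptor_definition("b", 1650, 40),
    receptor_definition("c", 2600, 25), receptor_definition("d", 3050, 25)
  )
  for (i in 1:10) {
    sp <- generate_synthetic_spectrum(8, seed = 100 + i, name = "orig")
    m <- sp$modes
    # permute mode order and relabel: an enantiomer-like twin with the same
    # (frequency, S) multiset
    perm <- sample(nrow(m))
    m2 <- m[perm, ]
    m2$label <- sprintf("renamed_%d", seq_len(nrow(m2)))
    twin <- odorant_spectrum("twin", m2)
    row_orig <- activation_matrix(list(sp), receptors)[1, ]
    row_twin <- activation_matrix(list(twin), receptors)[1, ]
    expect_equal(unname(row_orig), unname(row_twin))
  }
})

test_that("identical spectra give identical matrix rows; a single covered
           mode difference flips exactly one column", {
  rec_low <- receptor_definition("low", 1000, 25)
  rec_high <- receptor_definition("high", 2600, 25)
  base <- data.frame(label = c("m1", "m2"), freq_cm1 = c(1000, 2600),
                     huang_rhys = c(0.1, 0.1))
  a <- odorant_spectrum("a", base)
  b <- odorant_spectrum("b", base)
  m <- activation_matrix(list(a, b), list(rec_low, rec_high))
  expect_equal(unname(m["a", ]), unname(m["b", ]))
  # move the high mode out of the only receptor window that covers it
  shifted <- base
  shifted$freq_cm1[2] <- 2700
  c_sp <- odorant_spectrum("c", shifted)
  m2 <- activation_matrix(list(a, c_sp), list(rec_low, rec_high))
  expect_equal(sum(m2["a", ] != m2["c", ]), 1L)
  expect_true(m2["a", "high"] && !m2["c", "high"])
})

test_that("widening the resolution window never deactivates a pair", {
  set.seed(77)
  for (i in 1:8) {
    sp <- generate_synthetic_spectrum(6, seed = 500 + i)
    tuned <- runif(1, 600, 3000)
    narrow <- receptor_activation(
      sp, receptor_definition("r", tuned, resolution_window = 15))$activated
    wide <- receptor_activation(
      sp, receptor_definition("r", tuned, resolution_window = 60))$activated
    expect_true(!narrow || wide)
  }
})

test_that("H -> D substitution shifts a 2730 cm^-1 stretch by ~800 cm^-1", {
  ace <- acetophenone_like()
  deut <- apply_isotope_substitution(ace)
  shift <- ace$modes$freq_cm1[1] - deut$modes$freq_cm1[1]
  expect_equal(shift, 2730 * (1 - 1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(shift, 800, tolerance = 0.01)
  # hydrogen-free modes and all couplings untouched; input not modified
  expect_equal(deut$modes$freq_cm1[3], ace$modes$freq_cm1[3])
  expect_equal(deut$modes$huang_rhys, ace$modes$huang_rhys)
  expect_equal(ace$modes$freq_cm1[1], 2730)
})

test_that("isotope substitution is monotone-lowering and compounds", {
  sp <- generate_synthetic_spectrum(10, h_fraction = 1, seed = 9)
  deut <- apply_isotope_substitution(sp)
  expect_true(all(deut$modes$freq_cm1 < sp$modes$freq_cm1))
  # twice is the factor squared, not idempotent
  twice <- apply_isotope_substitution(deut)
  expect_equal(twice$modes$freq_cm1, sp$modes$freq_cm1 / 2, tolerance = 1e-12)
  # no hydrogen: identity
  dry <- generate_synthetic_spectrum(5, h_fraction = 0, seed = 10)
  expect_equal(apply_isotope_substitution(dry)$modes, dry$modes)
  expect_error(apply_isotope_substitution(sp, rule = "labelled"), "labels")
})

test_that("labelled-subset substitution touches only the named modes", {
  ace <- acetophenone_like()
  deut <- apply_isotope_substitution(ace, rule = "labelled",
                                     labels = "CH-stretch-a")
  expect_equal(deut$modes$freq_cm1[2:3], ace$modes$freq_cm1[2:3])
  expect_lt(deut$modes$freq_cm1[1], ace$modes$freq_cm1[1])
  expect_error(apply_isotope_substitution(ace, rule = "labelled",
                                          labels = "CO-stretch"),
               "has_H")
  expect_error(apply_isotope_substitution(ace, rule = "labelled",
                                          labels = "nope"), "not in spectrum")
})

test_that("isotope discrimination: a receptor on the H band disengages", {
  ace <- acetophenone_like()
  panel <- list(receptor_definition("CH-band", 2730),
                receptor_definition("carbonyl", 1690))
  res <- isotope_discrimination(ace, panel)
  expect_true(res$discriminated)
  expect_equal(res$first_receptor, "CH-band")
  expect_true(res$original["CH-band"] && !res$substituted["CH-band"])
  # the hydrogen-free receptor keeps firing
  expect_true(res$original["carbonyl"] && res$substituted["carbonyl"])
  # panel tuned far from any H mode: nothing changes
  far <- list(receptor_definition("far", 500))
  expect_false(isotope_discrimination(ace, far)$discriminated)
  expect_false(isotope_discrimination(ace, list())$discriminated)
})

test_that("synthetic spectra are reproducible and respect their bands", {
  s1 <- generate_synthetic_spectrum(8, seed = 42)
  s2 <- generate_synthetic_spectrum(8, seed = 42)
  expect_identical(s1$modes, s2$modes)
  expect_false(identical(
    s1$modes, generate_synthetic_spectrum(8, seed = 43)$modes))
  expect_equal(nrow(generate_synthetic_spectrum(0, seed = 1)$modes), 0)
  expect_error(generate_synthetic_spectrum(3, bands = list(), seed = 1),
               "non-empty")
  bands <- list(c(500, 1700), c(2200, 3100))
  big <- generate_synthetic_spectrum(10000, bands = bands,
                                     S_range = c(0.01, 0.3), seed = 314)
  in_band <- (big$modes$freq_cm1 >= 500 & big$modes$freq_cm1 <= 1700) |
    (big$modes$freq_cm1 >= 2200 & big$modes$freq_cm1 <= 3100)
  expect_true(all(in_band))
  expect_true(all(big$modes$huang_rhys >= 0.01 & big$modes$huang_rhys <= 0.3))
})
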