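# Spectral discrimination layer: odorant vibrational spectra as mode tables,
# receptors as a tuned frequency plus a resolution window and an acceptable
# coupling range, and the binary activation decisions built on them. The
# contract is deliberately spectroscopic — a receptor sees only the
# (frequency, Huang-Rhys) pairs, never labels, ordering or geometry.

.mode_required_cols <- c("label", "freq_cm1", "huang_rhys")
.mode_optional_cols <- c("reduced_mass_amu", "has_H")

.validate_modes <- function(modes, where = "modes") {
  if (!is.data.frame(modes)) stop(where, " must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.mode_required_cols, names(modes))
  if (length(missing_cols) > 0) {
    stop(where, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"reduced_mass_amu" %in% names(modes)) {
    modes$reduced_mass_amu <- rep(NA_real_, nrow(modes))
  }
  if (!"has_H" %in% names(modes)) modes$has_H <- rep(FALSE, nrow(modes))
  modes$label <- as.character(modes$label)
  modes$reduced_mass_amu <- as.numeric(modes$reduced_mass_amu)
  modes$has_H <- as.logical(modes$has_H)
  if (nrow(modes) > 0) {
    bad <- which(!is.finite(modes$freq_cm1) | modes$freq_cm1 <= 0)
    if (length(bad) > 0) {
      stop("non-positive or non-finite frequency in ", where, " row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- which(!is.finite(modes$huang_rhys) | modes$huang_rhys < 0)
    if (length(bad) > 0) {
      stop("negative or non-finite Huang-Rhys factor in ", where, " row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(modes$label)) {
      stop("duplicate mode label(s) in ", where, ": ",
           paste(unique(modes$label[duplicated(modes$label)]), collapse = ", "),
           call. = FALSE)
    }
  }
  modes[c(.mode_required_cols, .mode_optional_cols)]
}

#' Construct an odorant vibrational spectrum
#'
#' An odorant, for discrimination purposes, is its table of normal modes:
#' label, frequency in cm^-1, Huang-Rhys coupling factor, and optionally a
#' reduced mass and a flag marking modes that involve hydrogen motion (the
#' ones an H -> D substitution shifts).
#'
#' @param name Odorant name (non-empty).
#' @param modes Data frame with columns `label`, `freq_cm1`, `huang_rhys`
#'   and optionally `reduced_mass_amu`, `has_H`. Labels must be unique,
#'   frequencies > 0, couplings >= 0. May have zero rows.
#' @param metadata Free-form named list.
#' @return An object of class `odorant_spectrum`.
#' @examples
#' odorant_spectrum("H2S", data.frame(
#'   label = "SH-sym-stretch", freq_cm1 = 2600, huang_rhys = 0.1, has_H = TRUE))
#' @export
odorant_spectrum <- function(name, modes = data.frame(), metadata = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("odorant name must be a non-empty string", call. = FALSE)
  }
  if (nrow(modes) == 0 && ncol(modes) == 0) {
    modes <- data.frame(label = character(), freq_cm1 = numeric(),
                        huang_rhys = numeric(), reduced_mass_amu = numeric(),
                        has_H = logical())
  }
  structure(
    list(name = name, modes = .validate_modes(modes), metadata = metadata),
    class = "odorant_spectrum"
  )
}

#' @export
print.odorant_spectrum <- function(x, ...) {
  cat(sprintf("odorant spectrum '%s': %d mode(s)\n", x$name, nrow(x$modes)))
  if (nrow(x$modes) > 0) print(x$modes, row.names = FALSE)
  invisible(x)
}

#' Read / write an odorant spectrum as tab-separated text
#'
#' The on-disk format is UTF-8 TSV with a header row
#' `label  freq_cm1  huang_rhys` and optional `reduced_mass_amu`, `has_H`
#' columns. Malformed rows are reported with their row numbers; a file with
#' a header but no rows yields an empty spectrum with a warning.
#'
#' @param path File path.
#' @param name Odorant name; defaults to the file name without extension.
#' @return [read_spectrum()]: an [odorant_spectrum()];
#'   [write_spectrum()]: the path, invisibly. Writing then reading returns
#'   an identical spectrum.
#' @examples
#' sp <- odorant_spectrum("demo", data.frame(
#'   label = "m1", freq_cm1 = 2600, huang_rhys = 0.1, has_H = TRUE))
#' f <- tempfile(fileext = ".tsv")
#' write_spectrum(sp, f)
#' read_spectrum(f, name = "demo")
#' @export
read_spectrum <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(tab) == 0) {
    warning("spectrum file '", path, "' has a header but no modes",
            call. = FALSE)
  }
  odorant_spectrum(name, tab)
}

#' @rdname read_spectrum
#' @param spectrum An [odorant_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "odorant_spectrum"))
  out <- spectrum$modes
  # full double precision so that write -> read is the identity
  for (col in c("freq_cm1", "huang_rhys", "reduced_mass_amu")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Named presets for the acceptable coupling range
#'
#' `"broad"` is the full plausible range of Huang-Rhys factors for detected
#' modes, 0.01-0.3; `"useful"` is the narrower 0.05-0.3 band over which
#' detection is comfortably efficient.
#'
#' @param preset `"broad"` (default) or `"useful"`.
#' @return Numeric length-2 vector `c(S_min, S_max)`.
#' @examples
#' coupling_range_preset("useful")
#' @export
coupling_range_preset <- function(preset = c("broad", "useful")) {
  switch(match.arg(preset), broad = c(0.01, 0.3), useful = c(0.05, 0.3))
}

#' Construct a tuned-receptor definition
#'
#' A receptor is characterised by the vibrational frequency its
#' donor-acceptor gap is tuned to, a spectral resolution window (modes
#' within it are indistinguishable from the tuned frequency; differences
#' under ~25 cm^-1 go undetected), and the range of Huang-Rhys couplings it
#' can usefully detect.
#'
#' @param name Receptor name (non-empty).
#' @param tuned_frequency Tuned frequency, cm^-1; > 0.
#' @param resolution_window Half-width of the detection window, cm^-1
#'   (default 25); > 0. Boundaries are inclusive: a mode exactly at the edge
#'   counts as detected.
#' @param coupling_range `c(S_min, S_max)` acceptance band (default the
#'   `"broad"` preset, 0.01-0.3); `0 <= S_min < S_max`, inclusive at both
#'   ends.
#' @return An object of class `receptor_definition`.
#' @examples
#' receptor_definition("sulphuraceous", 2600)
#' @export
receptor_definition <- function(name, tuned_frequency, resolution_window = 25,
                                coupling_range = coupling_range_preset("broad")) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("receptor name must be a non-empty string", call. = FALSE)
  }
  if (tuned_frequency <= 0) stop("tuned_frequency must be > 0 cm^-1",
                                 call. = FALSE)
  if (resolution_window <= 0) stop("resolution_window must be > 0 cm^-1",
                                   call. = FALSE)
  if (length(coupling_range) != 2L || coupling_range[1] < 0 ||
      coupling_range[1] >= coupling_range[2]) {
    stop("coupling_range must be c(S_min, S_max) with 0 <= S_min < S_max",
         call. = FALSE)
  }
  structure(
    list(name = name, tuned_frequency = tuned_frequency,
         resolution_window = resolution_window,
         coupling_range = as.numeric(coupling_range)),
    class = "receptor_definition"
  )
}

#' @export
print.receptor_definition <- function(x, ...) {
  cat(sprintf("receptor '%s': tuned %s +/- %s cm^-1, S in [%s, %s]\n",
              x$name, format(x$tuned_frequency), format(x$resolution_window),
              format(x$coupling_range[1]), format(x$coupling_range[2])))
  invisible(x)
}

#' Does an odorant activate a receptor?
#'
#' A receptor activates when the odorant has at least one mode whose
#' frequency lies within the receptor's resolution window of the tuned
#' frequency and whose Huang-Rhys factor lies within the acceptable
#' coupling range (all boundaries inclusive). The decision depends only on
#' the (frequency, S) pairs: labels and mode order are irrelevant, so two
#' spectra with identical (frequency, S) multisets — e.g. enantiomers —
#' always activate the same receptors.
#'
#' @param spectrum An [odorant_spectrum()].
#' @param receptor A [receptor_definition()].
#' @return An object of class `activation_report`: `odorant`, `receptor`,
#'   `activated`, and `matching_modes` (data frame of qualifying modes with
#'   their detuning from the tuned frequency; activation holds exactly when
#'   it is non-empty).
#' @examples
#' h2s <- odorant_spectrum("H2S", data.frame(
#'   label = "SH", freq_cm1 = 2600, huang_rhys = 0.1, has_H = TRUE))
#' receptor_activation(h2s, receptor_definition("sulphuraceous", 2600))
#' @export
receptor_activation <- function(spectrum, receptor) {
  stopifnot(inherits(spectrum, "odorant_spectrum"),
            inherits(receptor, "receptor_definition"))
  m <- spectrum$modes
  detuning <- m$freq_cm1 - receptor$tuned_frequency
  hit <- abs(detuning) <= receptor$resolution_window &
    m$huang_rhys >= receptor$coupling_range[1] &
    m$huang_rhys <= receptor$coupling_range[2]
  matching <- data.frame(
    label = m$label[hit], freq_cm1 = m$freq_cm1[hit],
    huang_rhys = m$huang_rhys[hit], detuning = detuning[hit],
    stringsAsFactors = FALSE
  )
  structure(
    list(odorant = spectrum$name, receptor = receptor$name,
         activated = nrow(matching) > 0, matching_modes = matching),
    class = "activation_report"
  )
}

#' @export
print.activation_report <- function(x, ...) {
  cat(sprintf("'%s' on receptor '%s': %s\n", x$odorant, x$receptor,
              if (x$activated) "ACTIVATED" else "not activated"))
  if (x$activated) print(x$matching_modes, row.names = FALSE)
  invisible(x)
}

#' Activation matrix for a panel of odorants and receptors
#'
#' Logical matrix with one row per odorant and one column per receptor.
#' Under the combinatorial-coding reading, two odorants smell different at
#' the receptor level exactly when their rows differ.
#'
#' @param odorants Non-empty list of [odorant_spectrum()] objects.
#' @param receptors List of [receptor_definition()] objects (may be empty,
#'   giving zero-column rows).
#' @return Logical matrix, dimnames = odorant and receptor names.
#' @examples
#' h2s <- odorant_spectrum("H2S", data.frame(
#'   label = "SH", freq_cm1 = 2600, huang_rhys = 0.1, has_H = TRUE))
#' activation_matrix(list(h2s), list(receptor_definition("sulph", 2600)))
#' @export
activation_matrix <- function(odorants, receptors) {
  if (length(odorants) == 0) stop("need at least one odorant", call. = FALSE)
  mat <- matrix(
    FALSE, nrow = length(odorants), ncol = length(receptors),
    dimnames = list(
      vapply(odorants, function(o) o$name, character(1)),
      if (length(receptors) > 0)
        vapply(receptors, function(r) r$name, character(1)) else NULL
    )
  )
  for (i in seq_along(odorants)) {
    for (j in seq_along(receptors)) {
      mat[i, j] <- receptor_activation(odorants[[i]], receptors[[j]])$activated
    }
  }
  mat
}

#' Apply an isotope substitution to a spectrum
#'
#' Scales the frequencies of hydrogen-bearing modes by the isotope factor
#' from [isotope_frequency_factor()] — by default the proton-only H -> D
#' factor `1/sqrt(2)`, which lowers a ~2700 cm^-1 hydrogen stretch by about
#' 800 cm^-1. Couplings, reduced masses and unflagged modes are untouched;
#' a new spectrum is returned and the input is never modified. Applying the
#' substitution twice compounds the factor (the operation is not
#' idempotent).
#'
#' @param spectrum An [odorant_spectrum()].
#' @param rule `"all_H_to_D"` (default: every mode flagged `has_H`) or
#'   `"labelled"` (only the modes named in `labels`, each of which must be
#'   flagged `has_H`).
#' @param labels Mode labels for `rule = "labelled"`.
#' @param model,mass_original,mass_substituted,partner_mass Passed to
#'   [isotope_frequency_factor()].
#' @return A new [odorant_spectrum()] with scaled frequencies and the
#'   substitution recorded in its metadata.
#' @examples
#' ace <- odorant_spectrum("acetophenone-like", data.frame(
#'   label = "CH-stretch", freq_cm1 = 2730, huang_rhys = 0.1, has_H = TRUE))
#' apply_isotope_substitution(ace)
#' @export
apply_isotope_substitution <- function(spectrum,
                                       rule = c("all_H_to_D", "labelled"),
                                       labels = NULL,
                                       model = c("proton_only", "reduced_mass"),
                                       mass_original = 1, mass_substituted = 2,
                                       partner_mass = NULL) {
  stopifnot(inherits(spectrum, "odorant_spectrum"))
  rule <- match.arg(rule)
  model <- match.arg(model)
  fac <- isotope_frequency_factor(model, mass_original, mass_substituted,
                                  partner_mass)$ratio
  m <- spectrum$modes
  which_modes <- if (rule == "all_H_to_D") {
    isTRUE_vec <- !is.na(m$has_H) & m$has_H
    isTRUE_vec
  } else {
    if (is.null(labels)) stop("rule 'labelled' needs mode labels", call. = FALSE)
    unknown <- setdiff(labels, m$label)
    if (length(unknown) > 0) {
      stop("label(s) not in spectrum: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sel <- m$label %in% labels
    if (any(sel & !(!is.na(m$has_H) & m$has_H))) {
      stop("labelled mode(s) not flagged has_H cannot be H -> D substituted",
           call. = FALSE)
    }
    sel
  }
  m$freq_cm1[which_modes] <- m$freq_cm1[which_modes] * fac
  meta <- spectrum$metadata
  meta$isotope_substitution <- list(rule = rule, model = model, factor = fac)
  odorant_spectrum(spectrum$name, m, meta)
}

#' Can isotope substitution be smelt?
#'
#' Compares the activation pattern of a spectrum against that of its
#' deuterated counterpart over a receptor panel: discrimination holds when
#' the two patterns differ in at least one receptor. An H -> D shift of
#' ~800 cm^-1 on a hydrogen stretch easily exceeds the ~25 cm^-1 resolution
#' window, disengaging any receptor tuned to the original band.
#'
#' @param spectrum An [odorant_spectrum()].
#' @param receptors List of [receptor_definition()] objects.
#' @param ... Passed to [apply_isotope_substitution()].
#' @return List with `discriminated` (flag), `first_receptor` (name of the
#'   first receptor whose response differs, or NA), and the two activation
#'   rows.
#' @examples
#' ace <- odorant_spectrum("acetophenone-like", data.frame(
#'   label = "CH", freq_cm1 = 2730, huang_rhys = 0.1, has_H = TRUE))
#' isotope_discrimination(ace, list(receptor_definition("CH-band", 2730)))
#' @export
isotope_discrimination <- function(spectrum, receptors, ...) {
  stopifnot(inherits(spectrum, "odorant_spectrum"))
  if (length(receptors) == 0) {
    return(list(discriminated = FALSE, first_receptor = NA_character_,
                original = logical(0), substituted = logical(0)))
  }
  deut <- apply_isotope_substitution(spectrum, ...)
  row_orig <- vapply(receptors, function(r)
    receptor_activation(spectrum, r)$activated, logical(1))
  row_deut <- vapply(receptors, function(r)
    receptor_activation(deut, r)$activated, logical(1))
  names(row_orig) <- names(row_deut) <-
    vapply(receptors, function(r) r$name, character(1))
  differs <- row_orig != row_deut
  list(
    discriminated = any(differs),
    first_receptor = if (any(differs)) names(row_orig)[which(differs)[1]]
                     else NA_character_,
    original = row_orig,
    substituted = row_deut
  )
}

#' Generate a reproducible synthetic odorant spectrum
#'
#' Fixture generator: draws `n_modes` modes with frequencies uniform inside
#' the given bands (a band is picked uniformly at random for each mode,
#' then the frequency uniformly within it), Huang-Rhys factors uniform in
#' `S_range`, and hydrogen flags Bernoulli(`h_fraction`). Identical seeds
#' give identical spectra; the caller's RNG state is untouched.
#'
#' @param n_modes Number of modes; >= 0.
#' @param bands List of `c(low, high)` frequency bands in cm^-1; non-empty,
#'   each with `0 < low < high`. Default: a fingerprint band (500-1700) and
#'   a stretch band (2200-3100).
#' @param S_range `c(min, max)` for the coupling draw (default 0.01-0.3).
#' @param h_fraction Probability a mode is flagged `has_H` (default 0.5).
#' @param seed Integer RNG seed (required).
#' @param name Spectrum name.
#' @return An [odorant_spectrum()] with modes labelled `mode_001`, ...
#' @examples
#' generate_synthetic_spectrum(5, seed = 42)
#' @export
generate_synthetic_spectrum <- function(n_modes,
                                        bands = list(c(500, 1700),
                                                     c(2200, 3100)),
                                        S_range = c(0.01, 0.3),
                                        h_fraction = 0.5, seed,
                                        name = "synthetic") {
  if (length(bands) == 0) stop("bands must be non-empty", call. = FALSE)
  for (b in bands) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1]) {
      stop("each band must be c(low, high) with 0 < low < high", call. = FALSE)
    }
  }
  if (n_modes < 0 || n_modes != round(n_modes)) {
    stop("n_modes must be a non-negative integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required", call. = FALSE)
  }
  if (n_modes == 0) {
    return(odorant_spectrum(name, metadata = list(seed = seed)))
  }
  modes <- .with_seed(seed, function() {
    band_idx <- sample.int(length(bands), n_modes, replace = TRUE)
    freq <- vapply(band_idx, function(i)
      stats::runif(1, bands[[i]][1], bands[[i]][2]), numeric(1))
    data.frame(
      label = sprintf("mode_%03d", seq_len(n_modes)),
      freq_cm1 = freq,
      huang_rhys = stats::runif(n_modes, S_range[1], S_range[2]),
      reduced_mass_amu = NA_real_,
      has_H = stats::runif(n_modes) < h_fraction,
      stringsAsFactors = FALSE
    )
  })
  odorant_spectrum(name, modes, metadata = list(seed = seed))
}
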