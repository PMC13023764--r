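# Filtered tungsten-anode kVp spectrum model: Kramers continuum, effective
# anode self-filtration, Be inherent filtration, W characteristic L/K lines.

# W characteristic lines (keV) with relative in-series intensities.
# L series gated on the L3 edge, K series on the K edge.
.w_lines <- list(
  L = data.frame(energy = c(8.398, 9.672), rel = c(1.0, 0.8), edge = 10.207),
  K = data.frame(energy = c(59.318, 57.982, 67.244), rel = c(1.0, 0.57, 0.33),
                 edge = 69.525)
)
.w_density <- 19.30
.be_density <- 1.848

#' Tube configuration for spectrum generation
#'
#' Semi-empirical model of a tungsten reflection anode: Kramers
#' bremsstrahlung shaped by an effective tungsten self-filtration path plus
#' inherent beryllium filtration, with characteristic L/K lines whose
#' strength follows an overvoltage power law. The line-to-continuum scale
#' factors are fixed model constants calibrated once for the default tube
#' (0.2 mm target, 20 degree takeoff, 0.8 mm Be).
#'
#' @param kvp Tube potential, kV (10--200).
#' @param anode Anode element; only `"W"` is supported.
#' @param anode_angle Target angle, degrees (geometry documentation only;
#'   its effect is folded into `target_selffilter_mm`).
#' @param target_selffilter_mm Effective tungsten path for anode
#'   self-filtration, mm.
#' @param filters List of `list(material=, thickness_mm=)` external filters.
#' @param bin_width Spectrum bin width, keV.
#' @param min_energy Lowest tabulated energy, keV.
#' @param line_scale_L,line_scale_K Characteristic line amplitude constants
#'   (documented model parameters; do not refit per run).
#' @param line_exponent_L,line_exponent_K Overvoltage exponents of the
#'   line-intensity law `(E0/edge - 1)^p`.
#' @return An object of class `tube_config`.
#' @export
tube_config <- function(kvp, anode = "W", anode_angle = 20,
                        target_selffilter_mm = 0.02,
                        filters = list(list(material = "Be",
                                            thickness_mm = 0.8)),
                        bin_width = 0.5, min_energy = 1.0,
                        line_scale_L = 3e4, line_scale_K = 2,
                        line_exponent_L = -2.5, line_exponent_K = 2) {
  stopifnot(identical(anode, "W"), kvp >= 10, kvp <= 200, bin_width > 0,
            min_energy >= 1, target_selffilter_mm >= 0)
  for (f in filters) stopifnot(f$thickness_mm >= 0)
  structure(list(kvp = kvp, anode = anode, anode_angle = anode_angle,
                 target_selffilter_mm = target_selffilter_mm,
                 filters = filters, bin_width = bin_width,
                 min_energy = min_energy, line_scale_L = line_scale_L,
                 line_scale_K = line_scale_K,
                 line_exponent_L = line_exponent_L,
                 line_exponent_K = line_exponent_K),
            class = "tube_config")
}

new_spectrum <- function(energies, fluence, kvp = NA_real_) {
  stopifnot(length(energies) == length(fluence), all(fluence >= 0),
            any(fluence > 0), !is.unsorted(energies, strictly = TRUE))
  structure(list(energies = energies, fluence = fluence, kvp = kvp),
            class = "xray_spectrum")
}

#' Generate a filtered kVp spectrum
#'
#' Kramers continuum (N(E) proportional to (E0 - E)/E) attenuated by the
#' effective anode self-filtration path and every external filter via
#' Beer-Lambert, with tungsten characteristic lines added into their host
#' bins: the L series for any potential above the L3 edge, the K series
#' only above 69.5 kV. Line fluence follows the overvoltage power law
#' (E0/edge - 1)^p and passes the same filtration. The result is
#' normalized to unit total fluence.
#'
#' @param config A [tube_config()].
#' @param tables Element tables ([load_xsec_tables()]), loaded if `NULL`.
#' @param lines Set `FALSE` for the pure-continuum model.
#' @return An `xray_spectrum`: fields `energies` (bin centers, keV),
#'   `fluence` (relative photons per bin, summing to 1), `kvp`.
#' @export
#' @examples
#' s <- generate_spectrum(tube_config(60))
#' mean_energy(s)
generate_spectrum <- function(config, tables = NULL, lines = TRUE) {
  stopifnot(inherits(config, "tube_config"))
  if (config$kvp <= config$min_energy) {
    stop("kvp must exceed min_energy")
  }
  if (is.null(tables)) tables <- load_xsec_tables()
  bw <- config$bin_width
  e <- seq(config$min_energy + bw / 2, config$kvp, by = bw)
  e <- e[e < config$kvp]
  n <- (config$kvp - e) / e
  atten <- .tube_attenuation(e, config, tables)
  n <- n * atten
  if (lines) {
    att_of <- function(en) .tube_attenuation(en, config, tables)
    for (series in names(.w_lines)) {
      ln <- .w_lines[[series]]
      if (config$kvp <= ln$edge[1L]) next
      amp <- if (series == "L") config$line_scale_L else config$line_scale_K
      p <- if (series == "L") config$line_exponent_L else config$line_exponent_K
      strength <- amp * (config$kvp / ln$edge[1L] - 1)^p
      for (j in seq_len(nrow(ln))) {
        if (ln$energy[j] >= config$kvp) next
        bin <- which.min(abs(e - ln$energy[j]))
        n[bin] <- n[bin] + strength * ln$rel[j] * att_of(ln$energy[j])
      }
    }
  }
  new_spectrum(e, n / sum(n), kvp = config$kvp)
}

# combined self-filtration + external filter transmission at energies e
.tube_attenuation <- function(e, config, tables) {
  mu_w <- interpolate_xsec(tables[["W"]], e, "total") * .w_density
  t_cm <- config$target_selffilter_mm / 10
  a <- exp(-mu_w * t_cm)
  for (f in config$filters) {
    mat <- if (is.character(f$material)) builtin_element_material(f$material)
           else f$material
    mu <- mixture_mu(mat, e, "total", tables)$linear
    a <- a * exp(-mu * f$thickness_mm / 10)
  }
  a
}

# a pure-element material at its standard density (filters, slabs)
.element_density <- c(Be = 1.848, Lu = 9.841, W = 19.30)

#' Pure-element material at the standard elemental density
#'
#' @param symbol One of Be, Lu, W.
#' @return A [material()].
#' @export
builtin_element_material <- function(symbol) {
  symbol <- match.arg(symbol, names(.element_density))
  material(symbol, setNames(1.0, symbol), .element_density[[symbol]])
}

#' Attenuate a spectrum through a filter
#'
#' Beer-Lambert per bin: N'_i = N_i exp(-mu(E_i) t); energies unchanged.
#'
#' @param spectrum An `xray_spectrum`.
#' @param material A [material()] (or built-in element symbol).
#' @param thickness_mm Filter thickness, mm; >= 0.
#' @param tables Element tables, loaded if `NULL`.
#' @return Filtered `xray_spectrum` (not renormalized).
#' @export
apply_filter <- function(spectrum, material, thickness_mm, tables = NULL) {
  stopifnot(inherits(spectrum, "xray_spectrum"), thickness_mm >= 0)
  if (is.character(material)) material <- builtin_element_material(material)
  mu <- mixture_mu(material, spectrum$energies, "total", tables)$linear
  new_spectrum(spectrum$energies,
               spectrum$fluence * exp(-mu * thickness_mm / 10),
               kvp = spectrum$kvp)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spectrum An `xray_spectrum`.
#' @return sum(N_i E_i) / sum(N_i), keV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (sum(spectrum$fluence) <= 0) stop("spectrum has all-zero fluence")
  sum(spectrum$fluence * spectrum$energies) / sum(spectrum$fluence)
}

#' Renormalize a spectrum
#'
#' @param spectrum An `xray_spectrum`.
#' @param mode `"fluence"` scales to unit total fluence; `"peak"` scales the
#'   tallest bin to 1 (the convention of plotted tube spectra).
#' @return Rescaled `xray_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, mode = c("fluence", "peak")) {
  mode <- match.arg(mode)
  s <- if (mode == "fluence") sum(spectrum$fluence) else max(spectrum$fluence)
  new_spectrum(spectrum$energies, spectrum$fluence / s, kvp = spectrum$kvp)
}

#' Read a spectrum from two-column text
#'
#' Lines starting with `#` are comments; columns are energy (keV) and
#' relative fluence. Energies are sorted ascending on read (with a warning
#' when the file was unsorted).
#'
#' @param path File path.
#' @return An `xray_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parsed <- lapply(seq_along(rows), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(lines[rows[i]]),
                                              "[\t ,]+")[[1L]]))
    if (length(x) < 2L || anyNA(x[1:2])) {
      stop(sprintf("malformed spectrum line %d: '%s'", rows[i],
                   lines[rows[i]]))
    }
    x[1:2]
  })
  m <- do.call(rbind, parsed)
  if (any(m[, 2L] < 0)) stop("negative fluence in spectrum file")
  if (is.unsorted(m[, 1L], strictly = TRUE)) {
    warning("spectrum energies were not sorted; sorting ascending")
    m <- m[order(m[, 1L]), , drop = FALSE]
  }
  new_spectrum(m[, 1L], m[, 2L])
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An `xray_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# x-ray spectrum: energy_keV <TAB> relative_fluence",
               sprintf("%.9g\t%.12g", spectrum$energies, spectrum$fluence)),
             con)
  invisible(path)
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %d bins, %.3g-%.4g keV%s, mean %.2f keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              if (is.na(x$kvp)) "" else sprintf(" (%g kVp)", x$kvp),
              mean_energy(x)))
  invisible(x)
}

#' @export
plot.xray_spectrum <- function(x, ...) {
  plot(x$energies, x$fluence, type = "h", xlab = "energy (keV)",
       ylab = "relative fluence", ...)
  invisible(x)
}
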