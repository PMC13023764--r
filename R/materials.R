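# Elemental photon cross sections, log-log interpolation, mixture rule, and
# the built-in materials (water, nanoprobe compound, aqueous suspension).

# atomic weights of the bundled elements (IUPAC 2021, rounded)
.atomic_weight <- c(
  H = 1.008, Be = 9.0122, O = 15.999, F = 18.998, Na = 22.990,
  Gd = 157.25, Tb = 158.925, Lu = 174.967, W = 183.84
)
.atomic_number <- c(
  H = 1, Be = 4, O = 8, F = 9, Na = 11, Gd = 64, Tb = 65, Lu = 71, W = 74
)

.xsec_channels <- c("total", "photoelectric", "incoherent", "coherent",
                    "energy_absorption")
.xsec_cols <- c(total = "mu_rho_total", photoelectric = "mu_rho_pe",
                incoherent = "mu_rho_incoh", coherent = "mu_rho_coh",
                energy_absorption = "mu_en_rho")

#' Load a bundled elemental cross-section table
#'
#' Reads the plain-text mass attenuation / energy-absorption table shipped
#' with the package for one element. Tables cover 1--200 keV on a
#' log-spaced grid with absorption edges represented by duplicated
#' (just-below / just-above) energies, in cm^2/g.
#'
#' @param symbol Element symbol, one of H, Be, O, F, Na, Gd, Tb, Lu, W.
#' @return An object of class `xsec_table`: a data frame with columns
#'   `energy_keV`, `mu_rho_total`, `mu_rho_pe`, `mu_rho_incoh`,
#'   `mu_rho_coh`, `mu_en_rho`, plus attributes `symbol` and `Z`.
#' @export
#' @examples
#' tab <- xsec_table("O")
#' interpolate_xsec(tab, 60, "total")
xsec_table <- function(symbol) {
  symbol <- match.arg(symbol, names(.atomic_weight))
  path <- system.file("extdata", "xsec", paste0(symbol, ".txt"),
                      package = "xpdtdose", mustWork = TRUE)
  d <- read.table(path, header = FALSE, comment.char = "#",
                  col.names = c("energy_keV", .xsec_cols))
  stopifnot(all(diff(d$energy_keV) >= 0), all(as.matrix(d[-1]) > 0))
  structure(d, symbol = symbol, Z = .atomic_number[[symbol]],
            class = c("xsec_table", "data.frame"))
}

#' Load a set of elemental tables
#'
#' @param symbols Character vector of element symbols; default all bundled.
#' @return Named list of [xsec_table()] objects.
#' @export
load_xsec_tables <- function(symbols = names(.atomic_weight)) {
  setNames(lapply(symbols, xsec_table), symbols)
}

#' Interpolate a mass coefficient at arbitrary energy
#'
#' Log-log linear interpolation between bracketing grid points; exact at
#' grid nodes. Absorption-edge discontinuities are preserved because edge
#' energies appear twice in the grid (just below and just above the edge).
#'
#' @param table An [xsec_table()].
#' @param energy Photon energy (keV), vectorized.
#' @param channel One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`, `"energy_absorption"`.
#' @return Mass coefficient(s), cm^2/g.
#' @export
interpolate_xsec <- function(table, energy, channel = "total") {
  stopifnot(inherits(table, "xsec_table"))
  channel <- match.arg(channel, .xsec_channels)
  e <- table$energy_keV
  if (any(energy < e[1L] | energy > e[length(e)])) {
    stop(sprintf("energy outside the %s table range [%g, %g] keV",
                 attr(table, "symbol"), e[1L], e[length(e)]))
  }
  y <- table[[.xsec_cols[[channel]]]]
  # duplicated edge energies: approx() with ties kept ordered via tiny jitter
  # is avoided; instead use findInterval on the left-closed grid so a query
  # exactly at an edge returns the above-edge branch deterministically.
  idx <- findInterval(energy, e, left.open = FALSE, all.inside = TRUE)
  # exact node hits (prefer the stored value, incl. below-edge duplicate)
  hit <- match(energy, e)
  lo <- pmin(idx, length(e) - 1L)
  hi <- lo + 1L
  same <- e[hi] == e[lo]
  w <- ifelse(same, 0, log(energy / e[lo]) / log(e[hi] / e[lo]))
  out <- exp((1 - w) * log(y[lo]) + w * log(y[hi]))
  out[!is.na(hit)] <- y[hit[!is.na(hit)]]
  out
}

#' Define a material by elemental mass fractions
#'
#' @param name Label.
#' @param constituents Named numeric vector of mass fractions (names are
#'   element symbols); must sum to 1.
#' @param density Mass density, g/cm^3.
#' @return An object of class `material`.
#' @export
material <- function(name, constituents, density) {
  stopifnot(is.numeric(constituents), !is.null(names(constituents)),
            length(density) == 1L, density > 0)
  if (any(constituents <= 0) || any(constituents > 1)) {
    stop("mass fractions must lie in (0, 1]")
  }
  if (abs(sum(constituents) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", format(sum(constituents)), ")")
  }
  structure(list(name = name, constituents = constituents,
                 density = density), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, sprintf("(%.4g g/cm^3)\n", x$density))
  print(round(x$constituents, 6))
  invisible(x)
}

#' Built-in phantom water
#'
#' Liquid water, H/O mass fractions 0.1119/0.8881, density 1.000 g/cm^3.
#' @return A [material()].
#' @export
material_water <- function() {
  material("water", c(H = 0.1119, O = 0.8881), .const$water_density)
}

# stoichiometry of the doped nanocrystal Na(Lu0.65 Gd0.20 Tb0.15)F4:
# Gd/Tb percentages are molar substitutions of Lu in NaLuF4
.np_stoichiometry <- c(Na = 1, Lu = 0.65, Gd = 0.20, Tb = 0.15, F = 4)

#' Elemental mass fractions of the nanoprobe compound
#'
#' Expands Na(Lu0.65 Gd0.20 Tb0.15)F4 into elemental mass fractions from
#' standard atomic weights.
#' @return Named numeric vector summing to 1.
#' @export
np_compound_fractions <- function() {
  m <- .np_stoichiometry * .atomic_weight[names(.np_stoichiometry)]
  m / sum(m)
}

#' Homogeneous aqueous suspension of the nanoprobe
#'
#' Builds the material for nanoparticles dispersed in water at a given
#' concentration. The nanoparticle mass fraction is c / (1000 * rho_water + c)
#' with c in mg/mL (volume-additive convention) and the suspension density
#' defaults to rho_water + c/1000 (1.010 g/cm^3 at 10 mg/mL).
#'
#' @param concentration_mg_ml Nanoparticle concentration, mg/mL; >= 0.
#' @param density Optional override of the suspension density, g/cm^3.
#' @return A [material()]; pure water when the concentration is 0.
#' @export
#' @examples
#' np_suspension_composition(10)
np_suspension_composition <- function(concentration_mg_ml, density = NULL) {
  if (!is.numeric(concentration_mg_ml) || concentration_mg_ml < 0) {
    stop("concentration must be a non-negative number (mg/mL)")
  }
  c_ <- concentration_mg_ml
  rho_w <- .const$water_density
  if (is.null(density)) density <- rho_w + c_ / 1000
  if (c_ == 0) {
    w <- material_water()
    return(material("water", w$constituents, density))
  }
  f_np <- c_ / (1000 * rho_w + c_)
  np <- np_compound_fractions() * f_np
  water <- c(H = 0.1119, O = 0.8881) * (1 - f_np)
  cons <- c(np, water)
  cons <- tapply(cons, names(cons), sum)  # merge shared elements (none here)
  cons <- cons / sum(cons)
  material(sprintf("np_suspension_%gmgml", c_), c(cons), density)
}

#' Resolve a built-in material by name
#'
#' @param name `"water"` or `"np_suspension_<c>mgml"` (e.g.
#'   `"np_suspension_10mgml"`).
#' @return A [material()].
#' @export
builtin_material <- function(name) {
  if (identical(name, "water")) return(material_water())
  m <- regmatches(name, regexec("^np_suspension_([0-9.]+)mgml$", name))[[1]]
  if (length(m) == 2L) {
    return(np_suspension_composition(as.numeric(m[2L])))
  }
  stop("unknown built-in material: ", name)
}

#' Mixture-rule attenuation coefficients for a material
#'
#' Mass coefficient is the mass-fraction-weighted sum of the elemental
#' coefficients; the linear coefficient is the mass coefficient times the
#' material density.
#'
#' @param material A [material()].
#' @param energy Photon energy (keV), vectorized.
#' @param channel Coefficient channel, see [interpolate_xsec()].
#' @param tables Named list of element tables from [load_xsec_tables()];
#'   loaded on demand when `NULL`.
#' @return List with components `mass` (cm^2/g) and `linear` (1/cm).
#' @export
mixture_mu <- function(material, energy, channel = "total", tables = NULL) {
  stopifnot(inherits(material, "material"))
  syms <- names(material$constituents)
  if (is.null(tables)) tables <- load_xsec_tables(syms)
  missing <- setdiff(syms, names(tables))
  if (length(missing)) {
    stop("no cross-section table for element(s): ",
         paste(missing, collapse = ", "))
  }
  mass <- numeric(length(energy))
  for (s in syms) {
    mass <- mass + material$constituents[[s]] *
      interpolate_xsec(tables[[s]], energy, channel)
  }
  list(mass = mass, linear = mass * material$density)
}
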