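# Monte Carlo transport driver: builds per-material coefficient tables on a
# uniform energy grid, calls the compiled kernel, and wraps the scored
# energy-deposition grid as a dose_grid object.

# K-fluorescence constants for the high-Z constituents: K-edge (keV),
# fluorescence yield omega_K (Krause), mean emitted K x-ray energy (keV,
# Kalpha/Kbeta intensity-weighted single effective line)
.k_fluor <- data.frame(
  element = c("Gd", "Tb", "Lu", "W"),
  k_edge = c(50.2391, 51.9957, 63.3138, 69.525),
  omega_k = c(0.932, 0.935, 0.949, 0.958),
  line_keV = c(43.7, 45.0, 54.0, 59.3)
)

.grid_emin <- 1.0
.grid_estep <- 0.1
.grid_emax <- 200.0

#' Transport configuration
#'
#' @param n_photons Number of histories (rounded up to a multiple of
#'   `n_batches`).
#' @param seed Integer master seed; fixed seed gives identical results.
#' @param n_batches Batches for the uncertainty estimate (default 10).
#' @param energy_cutoff Photons below this energy (keV) deposit locally.
#' @param coherent Include Rayleigh scattering.
#' @param incoherent Include Compton scattering (disable only for
#'   pure-absorber validation runs).
#' @param fluorescence Emit and transport effective K-fluorescence lines of
#'   the high-Z constituents.
#' @param max_scatters Safety bound on interactions per history.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(n_photons, seed = 1L, n_batches = 10L,
                             energy_cutoff = 1.0, coherent = TRUE,
                             incoherent = TRUE, fluorescence = TRUE,
                             max_scatters = 1000L) {
  stopifnot(n_photons >= n_batches, n_batches >= 2,
            energy_cutoff >= .grid_emin)
  n_photons <- ceiling(n_photons / n_batches) * n_batches
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 n_batches = as.integer(n_batches),
                 energy_cutoff = energy_cutoff, coherent = coherent,
                 incoherent = incoherent, fluorescence = fluorescence,
                 max_scatters = as.integer(max_scatters)),
            class = "transport_config")
}

# uniform-grid linear coefficient tables + fluorescence channels for one
# material; used by both the kernel and closed-form oracles
.material_kernel_table <- function(mat, tables) {
  e <- seq(.grid_emin, .grid_emax, by = .grid_estep)
  pe <- inc <- coh <- numeric(length(e))
  fl_e <- numeric(0)
  fl_mu <- list()
  for (s in names(mat$constituents)) {
    w <- mat$constituents[[s]]
    pe_s <- w * interpolate_xsec(tables[[s]], e, "photoelectric")
    pe <- pe + pe_s
    inc <- inc + w * interpolate_xsec(tables[[s]], e, "incoherent")
    coh <- coh + w * interpolate_xsec(tables[[s]], e, "coherent")
    k <- .k_fluor[.k_fluor$element == s, ]
    if (nrow(k) == 1L && k$k_edge < .grid_emax) {
      jump <- interpolate_xsec(tables[[s]], k$k_edge + 1e-3, "photoelectric") /
        interpolate_xsec(tables[[s]], k$k_edge - 1e-3, "photoelectric")
      p_k <- 1 - 1 / jump
      mu_emit <- ifelse(e > k$k_edge, pe_s * p_k * k$omega_k, 0) * mat$density
      fl_e <- c(fl_e, k$line_keV)
      fl_mu <- c(fl_mu, list(mu_emit))
    }
  }
  list(pe = pe * mat$density, inc = inc * mat$density,
       coh = coh * mat$density,
       fluor = list(line_keV = fl_e, mu_emit = fl_mu))
}

#' Run Monte Carlo photon transport on a phantom
#'
#' Histories are sampled from the spectrum, enter uniformly over the beam
#' field travelling -z, and are tracked through the phantom's homogeneous
#' regions with exact distance-to-boundary free paths. Interactions follow
#' the photoelectric / Compton (Klein-Nishina) / Rayleigh (Thomson) channel
#' split of the material's partial cross sections; all electron energy is
#' deposited at the interaction site (kerma approximation). Deposits inside
#' the tumor are scored per 0.2 mm voxel in batches; deposits elsewhere and
#' escaping energy are tracked so that energy is conserved exactly.
#'
#' @param phantom A [build_model()] phantom.
#' @param spectrum An `xray_spectrum`.
#' @param config A [transport_config()].
#' @param tables Element tables, loaded if `NULL`.
#' @param instrument Return per-history energy bookkeeping (small runs only).
#' @return A `dose_grid`: 3-D arrays `energy_dep` (keV), `dose` (Gy),
#'   `rel_uncertainty`; matrix `edep_batches`; list `totals` (emitted,
#'   deposited in/outside tumor, escaped, all keV); `meta`.
#' @export
run_transport <- function(phantom, spectrum, config, tables = NULL,
                          instrument = FALSE) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(spectrum, "xray_spectrum"),
            inherits(config, "transport_config"))
  if (sum(spectrum$fluence) <= 0) stop("spectrum has zero total fluence")
  if (max(spectrum$energies) > .grid_emax) {
    stop("spectrum extends above the cross-section grid (200 keV)")
  }
  if (is.null(tables)) tables <- load_xsec_tables()

  mat_names <- vapply(phantom$regions, function(r) r$material, "")
  umat <- unique(mat_names)
  mat_tabs <- lapply(umat, function(nm) {
    .material_kernel_table(phantom$materials[[nm]], tables)
  })
  region_mat <- match(mat_names, umat)
  boxes <- do.call(rbind, lapply(phantom$regions, function(r) r$box))

  keep <- spectrum$fluence > 0
  spec_e <- spectrum$energies[keep]
  cdf <- cumsum(spectrum$fluence[keep])
  cdf <- cdf / cdf[length(cdf)]

  tb <- phantom$regions[[1]]$box
  res <- .mc_transport_cpp(
    boxes, as.integer(region_mat), mat_tabs, .grid_emin, .grid_estep,
    spec_e, cdf, phantom$beam$field, phantom$beam$entry_z, tb,
    as.integer(phantom$tumor_shape), config$n_photons, config$n_batches,
    config$seed, config$coherent, config$incoherent, config$fluorescence,
    config$max_scatters, config$energy_cutoff, instrument)

  sh <- phantom$tumor_shape
  edep <- array(colSums(res$edep_batches), dim = sh)
  bm <- res$edep_batches
  means <- colMeans(bm)
  sds <- apply(bm, 2L, sd)
  rel <- ifelse(means > 0, sds / sqrt(nrow(bm)) / means, NA_real_)
  rel_unc <- array(rel, dim = sh)

  grid <- structure(
    list(energy_dep = edep, dose = NULL, rel_uncertainty = rel_unc,
         edep_batches = bm,
         totals = list(emitted = sum(res$emitted),
                       deposited_tumor = sum(edep),
                       deposited_outside = sum(res$outside),
                       escaped = sum(res$escaped)),
         meta = list(phantom = phantom, kvp = spectrum$kvp,
                     config = config, histories = config$n_photons),
         instrument = if (instrument)
           list(deposited = res$hist_deposited,
                escaped = res$hist_escaped,
                emitted = res$hist_emitted)),
    class = "dose_grid")
  convert_to_dose(grid, phantom)
}

#' Convert scored energy to absorbed dose
#'
#' dose = energy (keV to J) / voxel mass, with voxel mass = tumor-material
#' density x voxel volume. Relative uncertainties are unchanged.
#'
#' @param grid A `dose_grid`.
#' @param phantom The phantom the grid was scored on.
#' @return The `dose_grid` with its `dose` array (Gy) filled in.
#' @export
convert_to_dose <- function(grid, phantom = grid$meta$phantom) {
  rho <- phantom$materials[["tumor"]]$density
  if (rho <= 0) stop("tumor material has non-positive density")
  vox_kg <- rho * (phantom$voxel_size / 10)^3 / 1000
  grid$dose <- grid$energy_dep * .const$kev_to_joule / vox_kg
  grid
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> Model %s%s, %s histories: tumor edep %.4g keV (%.1f%% of emitted)\n",
    x$meta$phantom$model,
    if (is.na(x$meta$kvp)) "" else sprintf(" @ %g kVp", x$meta$kvp),
    format(x$meta$histories, big.mark = ","),
    x$totals$deposited_tumor,
    100 * x$totals$deposited_tumor / x$totals$emitted))
  invisible(x)
}

#' @export
summary.dose_grid <- function(object, ...) {
  d <- depth_dose(object)
  cat(sprintf(
    "Model %s: AAD %.4g Gy/history-normalized, peak layer dose %.4g Gy at %.2f mm\n",
    object$meta$phantom$model, aad(object), max(d$values),
    d$depths[which.max(d$values)]))
  invisible(list(aad = aad(object), depth = d))
}

#' Sample the Klein-Nishina scattered-photon distribution
#'
#' @param energy Incident photon energy, keV.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return List with `energy` (scattered energies, keV) and `cos_theta`.
#' @export
kn_sample <- function(energy, n, seed = 1L) {
  stopifnot(energy > 0, n >= 1)
  .kn_sample_cpp(energy, as.integer(n), as.numeric(seed))
}
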