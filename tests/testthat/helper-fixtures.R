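# shared fixtures: element tables are loaded once per test run; small
# constructors for monoenergetic spectra and toy dose grids

xs_tables <- load_xsec_tables()

mono_spectrum <- function(energy_keV, fluence = 1) {
  structure(list(energies = energy_keV, fluence = fluence, kvp = NA_real_),
            class = "xray_spectrum")
}

# a dose_grid with prescribed per-voxel dose on a Model C tumor grid
toy_dose_grid <- function(dose_array, phantom = build_model("C"),
                          rel_unc = 0) {
  sh <- phantom$tumor_shape
  stopifnot(all(dim(dose_array) == sh))
  structure(list(
    energy_dep = dose_array, dose = dose_array,
    rel_uncertainty = array(rel_unc, dim = sh),
    edep_batches = matrix(rep(as.numeric(dose_array) / 2, each = 2),
                          nrow = 2),
    totals = list(emitted = sum(dose_array),
                  deposited_tumor = sum(dose_array),
                  deposited_outside = 0, escaped = 0),
    meta = list(phantom = phantom, kvp = NA_real_, histories = NA)),
    class = "dose_grid")
}

# depth values (z centers) mapped tumor-grid-wise: value v[k] on layer k
layered_dose_grid <- function(layer_values, phantom = build_model("C")) {
  sh <- phantom$tumor_shape
  arr <- array(0, dim = sh)
  for (k in seq_len(sh[3])) {
    arr[, , sh[3] - k + 1L] <- layer_values[k]
  }
  toy_dose_grid(arr, phantom)
}
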