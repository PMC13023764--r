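# Depth-dose, PDD, DER, AAD endpoints computed on the tumor voxel grid.
# Depth is measured from the beam entry face of the tumor; the beam travels
# -z, so the shallowest layer is the top voxel sheet of the cube.

new_depth_curve <- function(depths, values, uncertainties = NULL,
                            kind = "dose") {
  stopifnot(!is.unsorted(depths, strictly = TRUE), all(is.finite(values)))
  structure(list(depths = depths, values = values,
                 uncertainties = uncertainties, kind = kind),
            class = "depth_curve")
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("<depth_curve> %s: %d layers, %.2f-%.2f mm, max %.4g at %.2f mm\n",
              x$kind, length(x$depths), min(x$depths), max(x$depths),
              max(x$values), x$depths[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.depth_curve <- function(x, ...) {
  plot(x$depths, x$values, type = "b", xlab = "depth (mm)", ylab = x$kind,
       ...)
  invisible(x)
}

#' @export
as.data.frame.depth_curve <- function(x, ...) {
  d <- data.frame(depth_mm = x$depths, value = x$values)
  if (!is.null(x$uncertainties)) d$uncertainty <- x$uncertainties
  d
}

# per-layer voxel index sets along -z: layer 1 = deepest z index row? No:
# beam enters at z max, so layer k (depth (k-0.5)*vs) is z index nz-k+1
.layer_index <- function(phantom, k) {
  phantom$tumor_shape[3L] - k + 1L
}

#' Layer-averaged depth-dose curve
#'
#' Mean dose over each tumor voxel sheet perpendicular to the beam.
#' Layer uncertainty is the quadrature sum of voxel standard errors
#' divided by the voxel count (independent-voxel assumption).
#'
#' @param grid A `dose_grid` from [run_transport()].
#' @param phantom Phantom the grid was scored on (defaults to the one
#'   recorded in the grid).
#' @return A `depth_curve` (Gy per layer).
#' @export
depth_dose <- function(grid, phantom = grid$meta$phantom) {
  stopifnot(inherits(grid, "dose_grid"))
  nz <- phantom$tumor_shape[3L]
  vs <- phantom$voxel_size
  vals <- unc <- numeric(nz)
  for (k in seq_len(nz)) {
    iz <- .layer_index(phantom, k)
    layer <- grid$dose[, , iz]
    if (length(layer) == 0L) stop("empty tumor layer ", k)
    vals[k] <- mean(layer)
    sig <- layer * grid$rel_uncertainty[, , iz]
    sig[is.na(sig)] <- 0
    unc[k] <- sqrt(sum(sig^2)) / length(layer)
  }
  new_depth_curve((seq_len(nz) - 0.5) * vs, vals, unc, kind = "dose_Gy")
}

#' Percentage depth dose
#'
#' @param curve A `depth_curve` of dose values.
#' @return A `depth_curve` scaled to percent of its maximum (max = 100).
#' @export
pdd <- function(curve) {
  stopifnot(inherits(curve, "depth_curve"))
  m <- max(curve$values)
  if (m <= 0) stop("all-zero depth-dose curve")
  new_depth_curve(curve$depths, 100 * curve$values / m,
                  if (!is.null(curve$uncertainties))
                    100 * curve$uncertainties / m,
                  kind = "PDD_percent")
}

#' Depth dose-enhancement-ratio curve
#'
#' Pointwise ratio of the with-probe to without-probe depth-dose curves;
#' uncertainties combine in quadrature on the relative scale.
#'
#' @param with_probe,without_probe `depth_curve`s on identical depth grids.
#' @return A `depth_curve` of ratios.
#' @export
der_curve <- function(with_probe, without_probe) {
  stopifnot(inherits(with_probe, "depth_curve"),
            inherits(without_probe, "depth_curve"))
  if (!isTRUE(all.equal(with_probe$depths, without_probe$depths))) {
    stop("depth grids differ")
  }
  zero <- which(without_probe$values <= 0)
  if (length(zero)) {
    stop("zero dose in the without-probe arm at layer ", zero[1L])
  }
  r <- with_probe$values / without_probe$values
  unc <- NULL
  if (!is.null(with_probe$uncertainties) &&
      !is.null(without_probe$uncertainties)) {
    unc <- r * sqrt((with_probe$uncertainties / with_probe$values)^2 +
                    (without_probe$uncertainties / without_probe$values)^2)
  }
  new_depth_curve(with_probe$depths, r, unc, kind = "DER")
}

#' Average absorbed dose over the tumor
#'
#' @param grid A `dose_grid`.
#' @return Mean dose over all tumor voxels, Gy.
#' @export
aad <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  mean(grid$dose)
}

#' Enhancement ratio of the tumor average absorbed dose
#'
#' @param grid_with,grid_without `dose_grid`s for the with/without-probe
#'   arms on the same tumor grid.
#' @return AAD(with) / AAD(without).
#' @export
aad_der <- function(grid_with, grid_without) {
  a0 <- aad(grid_without)
  if (a0 <= 0) stop("zero AAD in the without-probe arm")
  aad(grid_with) / a0
}

#' Scale a dose grid to a prescribed surface dose
#'
#' Rescales the whole grid so that the entry-layer mean dose equals
#' `target` (dose is linear in fluence, so this is exact). Ratios (DER,
#' PDD) are invariant under this scaling.
#'
#' @param grid A `dose_grid`.
#' @param target Surface (entry-layer mean) dose, Gy.
#' @return The rescaled `dose_grid`.
#' @export
normalize_to_surface_dose <- function(grid, target = 3) {
  stopifnot(inherits(grid, "dose_grid"), target > 0)
  phantom <- grid$meta$phantom
  surf <- mean(grid$dose[, , .layer_index(phantom, 1L)])
  if (surf <= 0) stop("zero dose in the entry layer")
  f <- target / surf
  grid$dose <- grid$dose * f
  grid$energy_dep <- grid$energy_dep * f
  grid$edep_batches <- grid$edep_batches * f
  grid$totals <- lapply(grid$totals, function(x) x * f)
  grid$meta$surface_dose_scale <- f
  grid
}

#' Maximum relative uncertainty in the reporting region
#'
#' Maximum per-voxel relative standard error over tumor voxels receiving
#' more than `threshold` of the peak voxel dose (low-dose voxels excluded,
#' as common in Monte Carlo dosimetry reporting).
#'
#' @param grid A `dose_grid`.
#' @param threshold Dose threshold as a fraction of the peak voxel dose.
#' @return Maximum relative standard error (dimensionless).
#' @export
max_rel_uncertainty <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "dose_grid"))
  sel <- grid$dose > threshold * max(grid$dose)
  max(grid$rel_uncertainty[sel], na.rm = TRUE)
}

#' Per-kVp endpoint summary
#'
#' Bundles the endpoints reported per tube voltage: AAD of both arms, the
#' AAD enhancement ratio, the peak of the depth-DER curve and its depth,
#' and the maximum relative uncertainty of the with-probe arm.
#'
#' @param grid_with,grid_without `dose_grid`s of the two arms.
#' @return A one-row data frame.
#' @export
endpoint_summary <- function(grid_with, grid_without) {
  der <- der_curve(depth_dose(grid_with), depth_dose(grid_without))
  peak <- which.max(der$values)
  data.frame(
    kvp = grid_with$meta$kvp,
    aad_with = aad(grid_with), aad_without = aad(grid_without),
    aad_der = aad_der(grid_with, grid_without),
    peak_der = der$values[peak], peak_der_depth_mm = der$depths[peak],
    max_rel_uncertainty = max_rel_uncertainty(grid_with))
}
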