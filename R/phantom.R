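# Voxelized phantoms: 5 mm tumor cube, optional 6 x 3 x 3 cm water slab
# beneath it, parallel beam entering the tumor top face and travelling -z.

.tumor_side_mm <- 5
.slab_dims_mm <- c(x = 60, y = 30, z = 30)

#' Build one of the four study phantoms
#'
#' Model A: water tumor cube (5 mm side) sitting centered and flush on the
#' top face of a 6 x 3 x 3 cm water slab. Model B: same geometry with the
#' tumor material replaced by the 10 mg/mL nanoprobe suspension.
#' Models C/D: the isolated tumor cube (water / suspension) with the same
#' beam and no surrounding tissue. The parallel beam travels -z and its
#' rectangular field exactly covers the 5 x 5 mm tumor entry face.
#'
#' @param model `"A"`, `"B"`, `"C"` or `"D"`.
#' @param materials Optional list with elements `water` and `tumor`
#'   ([material()] objects); defaults are phantom water and the 10 mg/mL
#'   suspension (B/D).
#' @param voxel_size Scoring voxel edge, mm; must divide 5 mm evenly.
#' @return An object of class `voxel_phantom` with fields `model`, `shape`
#'   (full-grid voxel counts), `voxel_size`, `materials`, `regions`
#'   (axis-aligned boxes with material indices, first match wins),
#'   `tumor_shape`, `tumor_origin` (mm, lower corner), and `beam`.
#' @export
#' @examples
#' ph <- build_model("A")
#' length(depth_layers(ph))
build_model <- function(model = c("A", "B", "C", "D"), materials = NULL,
                        voxel_size = 0.2) {
  model <- match.arg(model)
  nvox <- .tumor_side_mm / voxel_size
  if (voxel_size <= 0 || abs(nvox - round(nvox)) > 1e-9) {
    stop("voxel_size must divide the 5 mm tumor side evenly")
  }
  nvox <- as.integer(round(nvox))
  if (is.null(materials)) {
    materials <- list(water = material_water(),
                      tumor = if (model %in% c("B", "D"))
                        np_suspension_composition(10) else material_water())
  }
  s <- .tumor_side_mm
  # tumor cube: ~centered on the slab top face, z in [0, 5]; the lateral
  # position is snapped to the slab's voxel lattice (within half a voxel of
  # center) so one lattice voxelizes every region boundary exactly
  lo <- round(-s / 2 / voxel_size) * voxel_size
  tumor_box <- c(lo, lo + s, lo, lo + s, 0, s)
  regions <- list(list(box = tumor_box, material = "tumor"))
  if (model %in% c("A", "B")) {
    d <- .slab_dims_mm
    regions <- c(regions, list(list(
      box = c(-d[["x"]] / 2, d[["x"]] / 2, -d[["y"]] / 2, d[["y"]] / 2,
              -d[["z"]], 0),
      material = "water")))
  }
  shape <- if (model %in% c("A", "B")) {
    c(x = .slab_dims_mm[["x"]] / voxel_size,
      y = .slab_dims_mm[["y"]] / voxel_size,
      z = (.slab_dims_mm[["z"]] + s) / voxel_size)
  } else {
    c(x = nvox, y = nvox, z = nvox)
  }
  beam <- list(direction = c(0, 0, -1),
               field = c(xmin = lo, xmax = lo + s,
                         ymin = lo, ymax = lo + s),
               entry_z = s)
  structure(list(model = model, shape = as.integer(round(shape)),
                 voxel_size = voxel_size, materials = materials,
                 regions = regions, tumor_shape = rep(nvox, 3L),
                 tumor_origin = c(lo, lo, 0), beam = beam),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> Model %s: %s voxels at %g mm, tumor %s (%s)\n",
              x$model, paste(x$shape, collapse = "x"), x$voxel_size,
              paste(x$tumor_shape, collapse = "x"), x$materials$tumor$name))
  invisible(x)
}

# region index (1-based into phantom$regions) at a point, 0 outside
.region_at <- function(phantom, p) {
  for (i in seq_along(phantom$regions)) {
    b <- phantom$regions[[i]]$box
    if (p[1] >= b[1] && p[1] <= b[2] && p[2] >= b[3] && p[2] <= b[4] &&
        p[3] >= b[5] && p[3] <= b[6]) return(i)
  }
  0L
}

#' Per-voxel material index array for a phantom
#'
#' Materializes the full grid (can be large for models A/B). Index 1 refers
#' to the tumor material, 2 to slab water, 0 (NA) to vacuum outside.
#'
#' @param phantom A [build_model()] phantom.
#' @return Integer array of dimension `phantom$shape`.
#' @export
phantom_materials <- function(phantom) {
  vs <- phantom$voxel_size
  sh <- phantom$shape
  if (phantom$model %in% c("A", "B")) {
    orig <- c(-.slab_dims_mm[["x"]] / 2, -.slab_dims_mm[["y"]] / 2,
              -.slab_dims_mm[["z"]])
  } else {
    orig <- phantom$tumor_origin
  }
  cx <- orig[1] + (seq_len(sh[1]) - 0.5) * vs
  cy <- orig[2] + (seq_len(sh[2]) - 0.5) * vs
  cz <- orig[3] + (seq_len(sh[3]) - 0.5) * vs
  arr <- array(0L, dim = sh)
  eps <- 1e-6  # voxel centers sit >= voxel_size/2 from any region face
  tb <- phantom$regions[[1]]$box
  inx <- cx > tb[1] + eps & cx < tb[2] - eps
  iny <- cy > tb[3] + eps & cy < tb[4] - eps
  inz <- cz > tb[5] + eps & cz < tb[6] - eps
  if (length(phantom$regions) > 1L) {
    sb <- phantom$regions[[2]]$box
    arr[, , cz > sb[5] + eps & cz < sb[6] - eps] <- 2L
  }
  arr[inx, iny, inz] <- 1L
  arr
}

#' Logical tumor mask on the full grid
#'
#' @param phantom A [build_model()] phantom.
#' @return Logical array of dimension `phantom$shape`.
#' @export
tumor_mask <- function(phantom) {
  phantom_materials(phantom) == 1L
}

#' Tumor depth layers along the beam axis
#'
#' The beam travels -z, so layer 1 is the shallowest (entry-face) tumor
#' voxel sheet. Depth of layer k is (k - 0.5) * voxel_size mm from the
#' tumor entry face.
#'
#' @param phantom A [build_model()] phantom.
#' @return Data frame with columns `layer` and `depth_mm`.
#' @export
depth_layers <- function(phantom) {
  n <- phantom$tumor_shape[3L]
  data.frame(layer = seq_len(n),
             depth_mm = (seq_len(n) - 0.5) * phantom$voxel_size)
}

#' Closed-form phantom mass
#'
#' Density times volume summed over the regions (tumor cube + slab).
#'
#' @param phantom A [build_model()] phantom.
#' @return Mass in grams.
#' @export
phantom_mass <- function(phantom) {
  m <- 0
  for (r in phantom$regions) {
    b <- r$box
    vol_cm3 <- prod(b[c(2, 4, 6)] - b[c(1, 3, 5)]) / 1000
    m <- m + vol_cm3 * phantom$materials[[r$material]]$density
  }
  m
}

#' Export a phantom as a portable text grid file
#'
#' Header lines (`#key: value`) record shape, voxel size, material names
#' and the beam; the body is one material id per line in x-fastest order.
#'
#' @param phantom A [build_model()] phantom.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#format: xpdt-phantom-grid v1",
    sprintf("#model: %s", phantom$model),
    sprintf("#shape: %s", paste(phantom$shape, collapse = " ")),
    sprintf("#voxel_size_mm: %g", phantom$voxel_size),
    sprintf("#materials: 1=%s 2=%s 0=vacuum",
            phantom$materials$tumor$name, phantom$materials$water$name),
    sprintf("#beam: dir %s field %s entry_z %g",
            paste(phantom$beam$direction, collapse = " "),
            paste(phantom$beam$field, collapse = " "),
            phantom$beam$entry_z),
    "#order: x fastest, then y, then z"), con)
  writeLines(as.character(as.integer(phantom_materials(phantom))), con)
  invisible(path)
}
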