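#' Volumetric source grid inside a spherical head model
#'
#' Builds a regular cubic lattice (default 6-mm spacing) clipped to a
#' spherical mask of radius \code{mask_fraction * head_radius}, the scan
#' volume for the beamformer. Voxels are ordered deterministically with x
#' varying fastest, then y, then z.
#'
#' @param head_radius conductor sphere radius in meters.
#' @param spacing lattice spacing in millimeters.
#' @param mask_fraction fraction of the head radius kept inside the mask.
#' @return Object of class \code{source_grid}: \code{coordinates} (V x 3,
#'   millimeters, model-head frame with origin at the sphere center),
#'   \code{spacing}, \code{mask_radius} (mm), \code{head_radius} (m).
#' @export
build_source_grid <- function(head_radius = 0.09, spacing = 6,
                              mask_fraction = 0.9) {
  if (spacing <= 0)
    stop_megdmn("grid spacing must be positive", class = "megdmn_config_error")
  rmax <- mask_fraction * head_radius * 1000
  kmax <- floor(rmax / spacing)
  ax <- seq(-kmax, kmax) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE))
  keep <- sqrt(rowSums(g^2)) <= rmax
  structure(list(coordinates = g[keep, , drop = FALSE],
                 spacing = spacing, mask_radius = rmax,
                 mask_fraction = mask_fraction,
                 head_radius = head_radius),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d voxels, %.1f mm spacing, mask %.1f mm\n",
              nrow(x$coordinates), x$spacing, x$mask_radius))
  invisible(x)
}

# Magnetic field of a current dipole in a homogeneous conducting sphere
# (Sarvas closed form), evaluated at sensor positions and projected on the
# (radial) sensor orientations. r0 in meters (3-vector), array a
# sensor_array. Returns n_channels x 3 gain (one column per unit dipole
# moment along x, y, z). A radial dipole, and any dipole at the center, is
# externally silent, so gains are exactly zero there.
sarvas_gain <- function(r0, array) {
  P <- array$positions
  N <- array$orientations
  Rn <- sqrt(rowSums(P^2))
  avec <- sweep(P, 2, r0, "-")
  an <- sqrt(rowSums(avec^2))
  adotr <- rowSums(avec * P)
  r0dotr <- as.numeric(P %*% r0)
  Fv <- an * (Rn * an + Rn^2 - r0dotr)
  c1 <- an^2 / Rn + adotr / an + 2 * an + 2 * Rn
  c2 <- an + 2 * Rn + adotr / an
  gradF <- c1 * P - outer(c2, r0)
  gain <- matrix(0, nrow(P), 3)
  for (j in 1:3) {
    q <- c(0, 0, 0); q[j] <- 1
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    qxr0_dot_r <- as.numeric(P %*% qxr0)
    B <- (1e-7 / Fv^2) * (Fv * matrix(qxr0, nrow(P), 3, byrow = TRUE) -
                            qxr0_dot_r * gradF)
    gain[, j] <- rowSums(B * N)
  }
  gain
}

#' Lead fields for a source grid under the spherical conductor model
#'
#' Computes, for each grid voxel, the n_channels x 3 gain matrix mapping a
#' unit dipole moment (x/y/z, A m) to the radial magnetometer signals, using
#' the closed-form dipole-in-sphere solution. Gains are linear in the dipole
#' moment; radial dipoles and the center voxel are silent.
#'
#' @param grid a \code{source_grid}.
#' @param array a \code{sensor_array} sharing the model-head frame.
#' @param voxels optional integer vector restricting computation to a voxel
#'   subset (e.g. the ROI voxels); defaults to the whole grid.
#' @return Object of class \code{lead_field}: \code{gain} (array
#'   n_channels x 3 x length(voxels)), \code{voxels} (grid indices),
#'   \code{grid}, \code{array}.
#' @export
compute_lead_field <- function(grid, array, voxels = NULL) {
  validate_sensor_array(array)
  co <- grid$coordinates
  if (is.null(voxels)) voxels <- seq_len(nrow(co))
  rmax <- grid$head_radius * 1000
  nr <- sqrt(rowSums(co[voxels, , drop = FALSE]^2))
  if (any(nr > rmax + 1e-9))
    stop_megdmn("voxel outside the conductor sphere",
                class = "megdmn_geometry_error")
  gain <- array(0, dim = c(array$n_channels, 3L, length(voxels)))
  for (i in seq_along(voxels))
    gain[, , i] <- sarvas_gain(co[voxels[i], ] / 1000, array)
  structure(list(gain = gain, voxels = as.integer(voxels), grid = grid,
                 array = array),
            class = "lead_field")
}

#' Merge nearby source peaks
#'
#' Greedy strongest-first pruning: peaks closer than \code{min_separation}
#' (default 10 mm) to an already-kept stronger peak are treated as the same
#' source and dropped.
#'
#' @param peaks data.frame with columns \code{x,y,z} (mm) and
#'   \code{strength}, sorted by descending strength (re-sorted defensively).
#' @param min_separation merge radius in millimeters.
#' @return The retained peaks, sorted by descending strength.
#' @export
merge_close_peaks <- function(peaks, min_separation = 10) {
  if (is.null(peaks) || nrow(peaks) == 0) return(peaks)
  peaks <- peaks[order(-peaks$strength), , drop = FALSE]
  co <- as.matrix(peaks[, c("x", "y", "z")])
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ki <- which(keep)
    if (length(ki) == 0) { keep[i] <- TRUE; next }
    d <- sqrt(colSums((t(co[ki, , drop = FALSE]) - co[i, ])^2))
    if (all(d >= min_separation)) keep[i] <- TRUE
  }
  peaks[keep, , drop = FALSE]
}
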