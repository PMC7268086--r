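#' Load and validate a DMN ROI table
#'
#' \code{dmn_roi_table()} returns the packaged table of 12 default-mode-
#' network seed regions (6-mm radius spheres) with their published MNI
#' coordinates and the anterior/posterior partition;
#' \code{load_roi_table()} reads the same TSV schema
#' (name, x_mni, y_mni, z_mni, partition) from any path.
#'
#' @param path TSV file path.
#' @return data.frame of class \code{roi_table} with one row per ROI.
#' @export
load_roi_table <- function(path) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop_megdmn("cannot parse ROI table: %s", conditionMessage(e),
                                class = "megdmn_parse_error"))
  need <- c("name", "x_mni", "y_mni", "z_mni", "partition")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_megdmn("ROI table missing column(s): %s", paste(miss, collapse = ", "),
                class = "megdmn_parse_error")
  dup <- duplicated(tab$name)
  if (any(dup))
    stop_megdmn("duplicate ROI name '%s' at row %d", tab$name[dup][1],
                which(dup)[1], class = "megdmn_parse_error")
  for (cc in c("x_mni", "y_mni", "z_mni"))
    if (!is.numeric(tab[[cc]]))
      stop_megdmn("non-numeric coordinates in column %s", cc,
                  class = "megdmn_parse_error")
  class(tab) <- c("roi_table", "data.frame")
  tab
}

#' @rdname load_roi_table
#' @export
dmn_roi_table <- function() {
  load_roi_table(system.file("extdata", "dmn_roi_table.tsv",
                             package = "megdmn", mustWork = TRUE))
}

#' Map MNI coordinates into the model-head frame
#'
#' Fixed affine scaling (default factor 0.8, both frames in mm) that places
#' all packaged ROI centers inside 0.9 x head_radius of the spherical model;
#' the same mapping is used by the forward simulation and the inverse
#' analysis, so no subject coregistration is needed.
#'
#' @param xyz n x 3 matrix of MNI coordinates (mm).
#' @param scale scalar affine factor.
#' @return n x 3 matrix in the model-head frame (mm).
#' @export
mni_to_model <- function(xyz, scale = 0.8) {
  as.matrix(xyz) * scale
}

roi_model_coords <- function(roi_table, scale = 0.8) {
  co <- mni_to_model(as.matrix(roi_table[, c("x_mni", "y_mni", "z_mni")]),
                     scale)
  rownames(co) <- roi_table$name
  co
}

# Grid voxel indices for each ROI: all voxels within `radius` mm of the
# mapped center, with the nearest voxel as a guaranteed fallback.
roi_voxel_sets <- function(roi_table, grid, radius = 6, scale = 0.8) {
  centers <- roi_model_coords(roi_table, scale)
  rmax <- grid$mask_radius
  out <- vector("list", nrow(centers))
  names(out) <- rownames(centers)
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    if (sqrt(sum(ctr^2)) > rmax)
      stop_megdmn("ROI %s maps outside the source mask", rownames(centers)[i],
                  class = "megdmn_geometry_error")
    d <- sqrt(colSums((t(grid$coordinates) - ctr)^2))
    vox <- which(d <= radius)
    if (length(vox) == 0) vox <- which.min(d)
    out[[i]] <- vox
  }
  out
}

#' Beamformed source signals for the DMN ROIs
#'
#' For each ROI, beamforms every grid voxel within the 6-mm ROI sphere
#' around the mapped center (nearest voxel as fallback) and averages the
#' reconstructed per-epoch source activity across those voxels.
#'
#' @param eps a band-passed \code{epoch_set}.
#' @param roi_table an \code{roi_table}.
#' @param lf a \code{lead_field}; must cover the ROI voxels (compute it
#'   with \code{voxels = unique(unlist(roi_voxels))} or the whole grid).
#' @param regularization covariance diagonal loading fraction.
#' @param radius ROI sphere radius in mm (model frame).
#' @param scale MNI-to-model affine factor.
#' @param cov optional precomputed channel covariance.
#' @return List with \code{signals}: per retained epoch an n_roi x
#'   samples_per_epoch matrix (rownames = ROI names), and \code{roi_voxels}.
#' @export
extract_roi_signals <- function(eps, roi_table, lf, regularization = 0.05,
                                radius = 6, scale = 0.8, cov = NULL) {
  grid <- lf$grid
  vox_sets <- roi_voxel_sets(roi_table, grid, radius, scale)
  mats <- clean_epochs(eps)
  n_ep <- length(mats)
  spe <- ncol(mats[[1]])
  if (max(vapply(mats, function(m) max(abs(m)), 0)) == 0) {
    sig <- lapply(seq_len(n_ep), function(i) {
      m <- matrix(0, nrow(roi_table), spe)
      rownames(m) <- roi_table$name
      m
    })
    return(list(signals = sig, roi_voxels = vox_sets))
  }
  if (is.null(cov)) cov <- sensor_covariance(eps, regularization)
  if (anyNA(match(unique(unlist(vox_sets)), lf$voxels)))
    stop_megdmn("lead field does not cover all ROI voxels",
                class = "megdmn_input_error")
  # one scalar-beamformer weight row per ROI (voxel average); the source
  # estimate is linear in the weights, so averaging weights equals
  # averaging the per-voxel time series
  nch <- nrow(cov)
  Wroi <- matrix(0, nrow(roi_table), nch,
                 dimnames = list(roi_table$name, NULL))
  for (r in seq_along(vox_sets)) {
    wsum <- numeric(nch)
    for (v in vox_sets[[r]]) {
      Lv <- lf$gain[, , match(v, lf$voxels)]
      sub <- select_partial_sensors(Lv)
      bf <- vector_beamformer(cov, Lv, sub)
      ori <- estimate_orientation(bf, cov)
      u <- attr(ori, "coef")
      wsum[sub] <- wsum[sub] + as.numeric(crossprod(u, bf$weights))
    }
    Wroi[r, ] <- wsum / length(vox_sets[[r]])
  }
  dat <- do.call(cbind, lapply(mats, function(m) m - rowMeans(m)))
  Qall <- Wroi %*% dat
  sig <- lapply(seq_len(n_ep), function(i)
    Qall[, ((i - 1) * spe + 1):(i * spe), drop = FALSE])
  list(signals = sig, roi_voxels = vox_sets, weights = Wroi)
}

#' Pearson correlation of a source pair
#'
#' The correlation factor R(Xa, Xb): the covariance of the two source
#' signals divided by the product of their standard deviations.
#'
#' @param x_a,x_b numeric vectors of equal length (>= 8 samples).
#' @return Correlation in [-1, 1].
#' @export
pair_correlation <- function(x_a, x_b) {
  if (length(x_a) != length(x_b) || length(x_a) < 8)
    stop_megdmn("signals must have equal length >= 8",
                class = "megdmn_input_error")
  if (sd(x_a) == 0 || sd(x_b) == 0)
    stop_megdmn("zero-variance signal: correlation undefined",
                class = "megdmn_degenerate_signal")
  r <- cor(x_a, x_b)
  min(1, max(-1, r))
}

#' Per-subject functional connectivity matrix over the DMN ROIs
#'
#' Computes the ROI x ROI Pearson correlation matrix within each retained
#' epoch, then combines epochs by Fisher z-transform averaging (variance-
#' stabilized) and back-transforms. Epochs containing a zero-variance ROI
#' signal are dropped with a warning. The diagonal is forced to 1.
#'
#' @param roi_signals list of per-epoch ROI x samples matrices
#'   (\code{extract_roi_signals()$signals}).
#' @param band optional \code{band_spec} recorded on the result.
#' @param subject_id optional label.
#' @return Object of class \code{fc_matrix}: a symmetric correlation matrix
#'   with attributes \code{band}, \code{subject_id}, \code{n_epochs_used}.
#' @export
fc_matrix <- function(roi_signals, band = NULL, subject_id = NULL) {
  if (length(roi_signals) < 2)
    stop_megdmn("need at least 2 epochs to pool a connectivity matrix",
                class = "megdmn_input_error")
  nroi <- nrow(roi_signals[[1]])
  zsum <- matrix(0, nroi, nroi)
  used <- 0L
  for (m in roi_signals) {
    if (any(apply(m, 1, sd) == 0)) next
    r <- cor(t(m))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    zsum <- zsum + atanh(r)
    used <- used + 1L
  }
  if (used == 0)
    stop_megdmn("all epochs contain a degenerate (zero-variance) ROI signal",
                class = "megdmn_degenerate_signal")
  if (used < length(roi_signals))
    warning(length(roi_signals) - used,
            " epoch(s) dropped for zero-variance ROI signals")
  R <- tanh(zsum / used)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  rownames(R) <- colnames(R) <- rownames(roi_signals[[1]])
  structure(R, band = band, subject_id = subject_id, n_epochs_used = used,
            class = c("fc_matrix", "matrix"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<fc_matrix> %d ROIs%s, %d epochs pooled\n", nrow(x),
              if (!is.null(b)) paste0(", band ", b$name) else "",
              attr(x, "n_epochs_used")))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Node degree of the thresholded connectivity graph
#'
#' Binary mode counts, for each node, the edges with |R| above the
#' correlation threshold (default 0.3); weighted mode sums |R| over the same
#' edge set. Self-connections are excluded.
#'
#' @param fc an \code{fc_matrix} (or plain symmetric matrix).
#' @param threshold correlation-factor cutoff in [0, 1).
#' @param mode "binary" or "weighted".
#' @return Named numeric vector of node degrees with attributes
#'   \code{threshold}, \code{mode}, \code{band}, \code{subject_id}.
#' @export
node_degree <- function(fc, threshold = 0.3, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold >= 1)
    stop_megdmn("threshold must lie in [0, 1)", class = "megdmn_config_error")
  A <- abs(unclass(fc))
  diag(A) <- 0
  E <- A > threshold
  s <- if (mode == "binary") rowSums(E) else rowSums(A * E)
  structure(setNames(as.numeric(s), rownames(fc)),
            threshold = threshold, mode = mode,
            band = attr(fc, "band"), subject_id = attr(fc, "subject_id"))
}
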