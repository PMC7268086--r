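#' Band-pass filter an epoch set
#'
#' Zero-phase Butterworth band-pass applied per epoch (no cross-epoch
#' leakage), selecting one of the analysis bands before source
#' reconstruction.
#'
#' @param eps an \code{epoch_set}.
#' @param band a \code{band_spec}.
#' @return The filtered \code{epoch_set}, with the band recorded.
#' @export
bandpass_epochs <- function(eps, band) {
  fs <- eps$sampling_rate
  if (band$high >= fs / 2)
    stop_megdmn("band %s (%g-%g Hz) exceeds Nyquist (%g Hz)", band$name,
                band$low, band$high, fs / 2, class = "megdmn_config_error")
  todo <- which(eps$status == "ok")
  eps$epochs[todo] <- lapply(eps$epochs[todo], zerophase_butter, fs = fs,
                             w = c(band$low, band$high), type = "pass")
  eps$band <- band
  eps
}

#' Pooled sensor covariance with diagonal loading
#'
#' Covariance of the retained epochs, pooled after removing each channel's
#' per-epoch mean, then regularized by diagonal loading equal to
#' \code{regularization} times the mean diagonal element (5% by default),
#' which keeps the inversion stable for short recordings.
#'
#' @param eps an \code{epoch_set} (>= 2 retained epochs).
#' @param regularization diagonal loading fraction.
#' @return Symmetric positive-definite channels x channels matrix.
#' @export
sensor_covariance <- function(eps, regularization = 0.05) {
  mats <- clean_epochs(eps)
  if (length(mats) < 2)
    stop_megdmn("need at least 2 retained epochs for a covariance (got %d)",
                length(mats), class = "megdmn_input_error")
  nch <- nrow(mats[[1]])
  tot <- sum(vapply(mats, ncol, 1L))
  if (tot <= nch)
    warning("total samples (", tot, ") do not exceed channel count (", nch,
            "); covariance will be rank-deficient before loading")
  S <- matrix(0, nch, nch)
  for (m in mats) {
    mc <- m - rowMeans(m)
    S <- S + tcrossprod(mc)
  }
  S <- S / max(1, tot - length(mats))
  S + diag(regularization * mean(diag(S)), nch)
}

#' Voxel-based partial sensor coverage
#'
#' Selects the channels used to beamform one voxel: every channel whose
#' lead-field row norm is at least \code{min_fraction} of the maximum row
#' norm, expanded to at least \code{min_count} channels by descending row
#' norm (ties broken by channel index).
#'
#' @param lead_field_voxel n_channels x 3 gain matrix for the voxel.
#' @param min_fraction row-norm threshold relative to the maximum.
#' @param min_count minimum number of channels retained.
#' @return Ascending channel indices.
#' @export
select_partial_sensors <- function(lead_field_voxel, min_fraction = 0.10,
                                   min_count = 30) {
  rn <- sqrt(rowSums(lead_field_voxel^2))
  mx <- max(rn)
  if (!(mx > 0))
    stop_megdmn("all-zero lead field: magnetically silent voxel",
                class = "megdmn_degenerate_voxel")
  keep <- which(rn >= min_fraction * mx)
  min_count <- min(min_count, length(rn))
  if (length(keep) < min_count) {
    ord <- order(-rn, seq_along(rn))
    keep <- union(keep, ord[seq_len(min_count)])
  }
  sort(keep)
}

#' Minimum-variance (LCMV) vector beamformer weights for one voxel
#'
#' Computes unit-gain minimum-variance weights
#' W = (L' C^-1 L)^-1 L' C^-1 on the selected channel subset. Under the
#' spherical conductor model the lead field has effective rank 2 (no radial
#' sensitivity), so the gain matrix is first reduced by SVD to its effective
#' column space; weights are computed in that basis and the unit-gain
#' property W L = I holds exactly there. Voxels with effective rank < 2 are
#' reported as degenerate.
#'
#' @param cov channel covariance (positive definite after loading).
#' @param lead_field_voxel n_channels x 3 gain matrix.
#' @param subset channel indices from \code{\link{select_partial_sensors}}.
#' @param rank_tol relative singular-value tolerance for the effective rank.
#' @return Object of class \code{voxel_beamformer}: \code{weights} (k x
#'   n_subset, in the reduced basis), \code{basis} (3 x k), \code{rank},
#'   \code{rank_deficient} flag, \code{subset}, \code{gain_err}.
#' @export
vector_beamformer <- function(cov, lead_field_voxel, subset,
                              rank_tol = 1e-7) {
  Lsub <- lead_field_voxel[subset, , drop = FALSE]
  Csub <- cov[subset, subset, drop = FALSE]
  sv <- svd(Lsub)
  k <- sum(sv$d > rank_tol * sv$d[1])
  if (k < 2)
    stop_megdmn("effective lead-field rank %d < 2: degenerate voxel", k,
                class = "megdmn_degenerate_voxel")
  Vk <- sv$v[, seq_len(k), drop = FALSE]
  Lr <- Lsub %*% Vk
  X <- solve(Csub, Lr)
  G <- crossprod(Lr, X)
  W <- solve(G, t(X))
  structure(list(weights = W, basis = Vk, rank = k,
                 rank_deficient = k < 3, subset = subset,
                 gain_err = max(abs(W %*% Lr - diag(k)))),
            class = "voxel_beamformer")
}

#' Source orientation from the beamformed covariance
#'
#' The dominant eigenvector of the 3x3 (or rank-reduced) source covariance
#' W C W', mapped back to sensor space through the reduced basis and sign-
#' fixed so the largest-magnitude component is positive. Near-ties of the
#' leading eigenvalues are broken deterministically and flagged.
#'
#' @param bf a \code{voxel_beamformer}.
#' @param cov the channel covariance used to build it.
#' @return Unit 3-vector with attributes \code{tie_break} (logical) and
#'   \code{coef} (coordinates in the reduced basis).
#' @export
estimate_orientation <- function(bf, cov) {
  Csub <- cov[bf$subset, bf$subset, drop = FALSE]
  S <- bf$weights %*% Csub %*% t(bf$weights)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  tie <- length(e$values) > 1 &&
    abs(e$values[1] - e$values[2]) <= 1e-12 * max(abs(e$values[1]), 1e-300)
  u <- e$vectors[, 1]
  if (tie) {  # deterministic lexicographic tie-break
    cand <- e$vectors[, abs(e$values - e$values[1]) <=
                        1e-12 * max(abs(e$values[1]), 1e-300), drop = FALSE]
    ord <- do.call(order, as.data.frame(t(round(cand, 12))))
    u <- cand[, ord[1]]
  }
  o <- as.numeric(bf$basis %*% u)
  o <- o / sqrt(sum(o^2))
  i <- which.max(abs(o))
  if (o[i] < 0) { o <- -o; u <- -u }
  attr(o, "tie_break") <- tie
  attr(o, "coef") <- as.numeric(u)
  o
}

#' Scalar beamformer source time series for one voxel
#'
#' Projects the vector beamformer onto the estimated orientation and applies
#' it to the retained epochs, giving the reconstructed source activity
#' Q(r, t) concatenated over epochs in time order.
#'
#' @param eps a band-passed \code{epoch_set}.
#' @param orientation unit 3-vector from \code{\link{estimate_orientation}}.
#' @param bf the \code{voxel_beamformer} for the voxel.
#' @param demean remove each channel's per-epoch mean before projection.
#' @return Numeric vector Q with attribute \code{epoch_index} (the time
#'   slice each sample belongs to).
#' @export
scalar_source_timeseries <- function(eps, orientation, bf, demean = TRUE) {
  u <- attr(orientation, "coef")
  if (is.null(u)) u <- as.numeric(crossprod(bf$basis, orientation))
  w <- as.numeric(crossprod(u, bf$weights))   # 1 x n_subset
  mats <- clean_epochs(eps)
  qs <- lapply(mats, function(m) {
    ms <- m[bf$subset, , drop = FALSE]
    if (demean) ms <- ms - rowMeans(ms)
    as.numeric(w %*% ms)
  })
  q <- unlist(qs, use.names = FALSE)
  attr(q, "epoch_index") <- rep(seq_along(qs), vapply(qs, length, 1L))
  q
}

#' Accumulated source image (volumetric strength summation)
#'
#' Sums the reconstructed source activity over time: Asi(r) = sum_t |Q(r,t)|
#' (magnitude summation; the signed sum, which cancels oscillatory activity,
#' is available with \code{signed = TRUE}). Per-epoch time-slice indices are
#' recorded as metadata.
#'
#' @param Q numeric vector (one voxel) or V x T matrix of source activity.
#' @param signed sum signed values instead of magnitudes.
#' @return Nonnegative numeric vector of accumulated strengths with
#'   attributes \code{n} (time points) and \code{slices}.
#' @export
accumulate_source_image <- function(Q, signed = FALSE) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  if (ncol(Q) == 0)
    stop_megdmn("empty time axis", class = "megdmn_input_error")
  if (!all(is.finite(Q)))
    stop_megdmn("non-finite source activity", class = "megdmn_validity_error")
  asi <- if (signed) rowSums(Q) else rowSums(abs(Q))
  ep <- attr(Q, "epoch_index")
  slices <- if (is.null(ep)) 1L else unique(ep)
  structure(asi, n = ncol(Q), slices = slices)
}

#' Whole-grid accumulated source imaging
#'
#' Runs the two-step beamformer at every grid voxel (partial sensor
#' selection, rank-reduced minimum-variance vector beamformer, orientation
#' estimation, scalar projection) and accumulates |Q| over the retained
#' epochs. The scan is compiled; it matches the per-voxel R functions to
#' numerical precision.
#'
#' @param eps a band-passed \code{epoch_set}.
#' @param lf a \code{lead_field} covering the scan voxels.
#' @param regularization covariance diagonal loading fraction.
#' @param min_fraction,min_count partial-sensor coverage rule.
#' @param cov optional precomputed covariance.
#' @return Object of class \code{asi_image}: \code{asi}, \code{gain_err},
#'   \code{rank}, \code{orientation} per voxel, the grid and metadata.
#' @export
asi_map <- function(eps, lf, regularization = 0.05, min_fraction = 0.10,
                    min_count = 30, cov = NULL) {
  if (is.null(cov)) cov <- sensor_covariance(eps, regularization)
  mats <- clean_epochs(eps)
  dat <- do.call(cbind, lapply(mats, function(m) m - rowMeans(m)))
  res <- .cpp_beamform_scan(dat, cov, lf$gain, min_fraction,
                            as.integer(min_count), 1e-7)
  structure(list(asi = as.numeric(res$asi),
                 gain_err = as.numeric(res$gain_err),
                 rank = as.integer(res$rank),
                 orientation = res$orientation,
                 voxels = lf$voxels, grid = lf$grid,
                 n = ncol(dat), n_epochs = length(mats),
                 band = eps$band %||% NULL),
            class = "asi_image")
}

#' @export
print.asi_image <- function(x, ...) {
  cat(sprintf("<asi_image> %d voxels, %d time points%s\n", length(x$asi),
              x$n, if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Peak localization on an accumulated source image
#'
#' Finds strict local maxima of Asi on the lattice (26-neighborhood), sorts
#' them by strength and prunes peaks closer than \code{min_separation} with
#' \code{\link{merge_close_peaks}}. A flat image yields a single
#' deterministic, flagged peak at the lowest voxel index.
#'
#' @param asi an \code{asi_image}.
#' @param min_separation merge radius in mm.
#' @return data.frame of peaks (x, y, z, strength, voxel) sorted by
#'   descending strength, with attribute \code{flat} when degenerate.
#' @export
localize_peak <- function(asi, min_separation = 10) {
  grid <- asi$grid
  co <- grid$coordinates[asi$voxels, , drop = FALSE]
  sp <- grid$spacing
  idx <- round(sweep(co, 2, apply(co, 2, min)) / sp) + 1L
  dims <- apply(idx, 2, max)
  arr <- array(-Inf, dim = dims)
  arr[idx] <- asi$asi
  lin <- idx[, 1] + dims[1] * (idx[, 2] - 1L) + dims[1] * dims[2] * (idx[, 3] - 1L)
  is_peak <- rep(TRUE, length(asi$asi))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ni <- idx[, 1] + dx; nj <- idx[, 2] + dy; nk <- idx[, 3] + dz
    inside <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    nb <- rep(-Inf, length(lin))
    nb[inside] <- arr[cbind(ni[inside], nj[inside], nk[inside])]
    is_peak <- is_peak & (asi$asi > nb)
  }
  flat <- FALSE
  which_pk <- which(is_peak)
  if (length(which_pk) == 0) {  # flat or plateau image
    flat <- TRUE
    which_pk <- which(asi$asi == max(asi$asi))[1]
  }
  pk <- data.frame(x = co[which_pk, 1], y = co[which_pk, 2],
                   z = co[which_pk, 3], strength = asi$asi[which_pk],
                   voxel = asi$voxels[which_pk])
  out <- merge_close_peaks(pk, min_separation)
  attr(out, "flat") <- flat
  out
}
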