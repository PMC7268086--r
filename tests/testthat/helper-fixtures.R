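# Shared small fixtures; built once per test run.

fix <- new.env()

fix$arr24 <- make_sensor_array(24)
fix$arr102 <- make_sensor_array(102)
fix$grid <- build_source_grid(0.09, 6)
fix$roi <- dmn_roi_table()
fix$roi_vox <- megdmn:::roi_voxel_sets(fix$roi, fix$grid)
fix$lf24 <- compute_lead_field(fix$grid, fix$arr24,
                               unique(unlist(fix$roi_vox)))

# full 102-channel lead field over the whole grid, built on first use
get_full_lf <- function() {
  if (is.null(fix$lf102_full))
    fix$lf102_full <- compute_lead_field(fix$grid, fix$arr102)
  fix$lf102_full
}

# full 3 x n weights of a voxel beamformer (unit gain: weights %*% L = I on
# the effective basis, i.e. full_weights %*% L = basis %*% t(basis))
full_weights <- function(bf) bf$basis %*% bf$weights

# quick epoch_set constructor around a plain matrix
as_epochs <- function(mat_list, fs = 1000, epoch_length = 0.5) {
  structure(list(epochs = mat_list, status = rep("ok", length(mat_list)),
                 epoch_length = epoch_length, sampling_rate = fs,
                 subject_id = "fix", group = "x"),
            class = "epoch_set")
}

# band-limited unit-sd noise rows
band_noise <- function(nrow, T, fs, low, high, seed) {
  with_seed_test(seed, {
    Z <- matrix(rnorm(nrow * T), nrow, T)
    Z <- megdmn:::zerophase_butter(Z, fs, c(low, high), "pass")
    Z / apply(Z, 1, sd)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# simulate one single-dipole recording at a given grid voxel (gamma band),
# returns the recording and the source series
simulate_dipole_recording <- function(voxel, arr, grid, snr_db = 20,
                                      duration = 4, fs = 1000, seed = 1,
                                      freq_band = c(31, 80), moment = 1e-8) {
  with_seed_test(seed, {
    T <- duration * fs
    r0 <- grid$coordinates[voxel, ] / 1000
    rhat <- r0 / sqrt(sum(r0^2))
    v <- rnorm(3)
    tv <- v - sum(v * rhat) * rhat
    tv <- tv / sqrt(sum(tv^2))
    src <- as.numeric(megdmn:::zerophase_butter(matrix(rnorm(T), 1), fs,
                                                freq_band, "pass"))
    g <- megdmn:::sarvas_gain(r0, arr) %*% tv
    clean <- (g * moment) %*% t(matrix(src))
    noise_sd <- sqrt(mean(clean^2) / 10^(snr_db / 10))
    dat <- clean + matrix(rnorm(length(clean), sd = noise_sd), nrow(clean))
    list(rec = sensor_recording(dat, fs, arr), src = src, orientation = tv,
         voxel = voxel)
  })
}
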