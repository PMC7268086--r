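rms <- function(x) sqrt(mean(x^2))

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 1000
  t4 <- seq_len(4 * fs) / fs
  bands <- dmn_bands()
  # multi-second segment: attenuation is filter-limited, not window-limited
  seg <- function(f) as_epochs(list(matrix(sin(2 * pi * f * t4), 1)),
                               epoch_length = 4)
  g <- function(f, band) {
    out <- bandpass_epochs(seg(f), bands[[band]])$epochs[[1]]
    20 * log10(rms(out) / rms(sin(2 * pi * f * t4)))
  }
  expect_lte(abs(g(10, "alpha")), 1)
  expect_lte(g(50, "alpha"), -30)
  expect_lte(g(4, "alpha"), -30)    # one octave below the low edge
  expect_lte(g(26, "alpha"), -30)   # one octave above the high edge
  expect_lte(abs(g(20, "beta")), 1)
  expect_lte(abs(g(50, "gamma")), 1)
  # per-epoch application at the analysis epoch length still passes in-band
  t05 <- seq_len(500) / fs
  ep <- as_epochs(list(matrix(sin(2 * pi * 10 * t05), 1)))
  out <- bandpass_epochs(ep, bands$alpha)$epochs[[1]]
  expect_lte(abs(20 * log10(rms(out) / rms(sin(2 * pi * 10 * t05)))), 1)
  # zero in, zero out; Nyquist violation errors
  z <- as_epochs(list(matrix(0, 2, 500)))
  expect_true(all(bandpass_epochs(z, bands$alpha)$epochs[[1]] == 0))
  expect_error(bandpass_epochs(as_epochs(list(matrix(0, 1, 50)), fs = 100),
                               bands$gamma),
               class = "megdmn_config_error")
})

test_that("pooled covariance estimates identity white noise within 10%", {
  with_seed_test(21, {
    mats <- replicate(100, matrix(rnorm(16 * 500), 16), simplify = FALSE)
    C <- sensor_covariance(as_epochs(mats), regularization = 0.05)
    expect_lt(norm(C - diag(16), "F") / norm(diag(16), "F"), 0.10)
  })
})

test_that("diagonal loading adds exactly regularization x mean diagonal", {
  with_seed_test(22, {
    mats <- replicate(4, matrix(rnorm(8 * 500), 8), simplify = FALSE)
    C0 <- sensor_covariance(as_epochs(mats), regularization = 0)
    C5 <- sensor_covariance(as_epochs(mats), regularization = 0.05)
    expect_equal(diag(C5), diag(C0) + 0.05 * mean(diag(C0)),
                 tolerance = 1e-12)
    expect_equal(C5[upper.tri(C5)], C0[upper.tri(C0)], tolerance = 1e-12)
  })
})

test_that("rank-deficient data still yields a positive-definite covariance", {
  with_seed_test(23, {
    m <- matrix(rnorm(7 * 2000), 7)
    m <- rbind(m, m[1, ])  # duplicate channel
    mats <- lapply(1:4, function(i) m[, ((i - 1) * 500 + 1):(i * 500)])
    C <- sensor_covariance(as_epochs(mats), regularization = 0.05)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_error(sensor_covariance(as_epochs(mats[1])),
                 class = "megdmn_input_error")
  })
})

test_that("partial sensor coverage follows the norm-threshold + floor rule", {
  L <- matrix(1, 40, 3)
  expect_equal(select_partial_sensors(L), 1:40)       # uniform: all kept
  L2 <- matrix(1e-6, 40, 3)
  L2[17, ] <- 1                                        # one dominant channel
  sub <- select_partial_sensors(L2, min_fraction = 0.10, min_count = 30)
  expect_equal(length(sub), 30)
  # brute-force check: the 30 largest row norms, ties by index
  rn <- sqrt(rowSums(L2^2))
  expect_equal(sub, sort(order(-rn, seq_along(rn))[1:30]))
  expect_error(select_partial_sensors(matrix(0, 10, 3)),
               class = "megdmn_degenerate_voxel")
})

test_that("vector beamformer: closed form, unit gain, minimum variance", {
  with_seed_test(31, {
    # C = I, orthonormal lead-field columns -> full weights equal t(L)
    L <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
    bf <- vector_beamformer(diag(20), L, 1:20)
    expect_equal(full_weights(bf) %*% L, diag(3), tolerance = 1e-10)
    expect_equal(full_weights(bf), t(L), tolerance = 1e-8)
    expect_lt(bf$gain_err, 1e-8)
    # random SPD covariance, random rank-3 lead field: unit gain and
    # minimal output variance among random unit-gain alternatives
    A <- matrix(rnorm(400), 20)
    C <- crossprod(A) / 20 + diag(20)
    L <- matrix(rnorm(60), 20, 3)
    bf <- vector_beamformer(C, L, 1:20)
    W <- full_weights(bf)
    expect_lt(max(abs(W %*% L - diag(3))), 1e-8)
    v0 <- sum(diag(W %*% C %*% t(W)))
    P <- diag(20) - L %*% solve(crossprod(L), t(L))  # null space of t(L)
    for (i in 1:100) {
      D <- matrix(rnorm(60), 3, 20) %*% P
      Wa <- W + D
      expect_lt(max(abs(Wa %*% L - diag(3))), 1e-6)
      expect_gte(sum(diag(Wa %*% C %*% t(Wa))), v0 - 1e-10)
    }
  })
})

test_that("rank-2 sphere lead fields are reduced, flagged and unit-gain", {
  vx <- fix$roi_vox$LAG[1]
  Lv <- fix$lf24$gain[, , match(vx, fix$lf24$voxels)]
  C <- diag(24)
  bf <- vector_beamformer(C, Lv, select_partial_sensors(Lv))
  expect_equal(bf$rank, 2)
  expect_true(bf$rank_deficient)
  expect_lt(bf$gain_err, 1e-8)
})

test_that("orientation estimation follows the dominant source axis", {
  bf <- structure(list(weights = diag(3), basis = diag(3), rank = 3,
                       rank_deficient = FALSE, subset = 1:3, gain_err = 0),
                  class = "voxel_beamformer")
  o <- estimate_orientation(bf, diag(c(4, 1, 0.1)))
  expect_equal(as.numeric(o), c(1, 0, 0), tolerance = 1e-12)
  expect_false(attr(o, "tie_break"))
  o2 <- estimate_orientation(bf, diag(3))
  expect_true(attr(o2, "tie_break"))
})

test_that("orientation is recovered within 10 degrees from simulated data", {
  grid <- fix$grid
  rr <- sqrt(rowSums(grid$coordinates^2))
  vx <- which(rr > 50 & rr < 60)[5]
  sim <- simulate_dipole_recording(vx, fix$arr102, grid, snr_db = 20,
                                   duration = 4, seed = 41)
  eps <- bandpass_epochs(segment_epochs(sim$rec), dmn_bands()$gamma)
  C <- sensor_covariance(eps)
  lf <- compute_lead_field(grid, fix$arr102, vx)
  Lv <- lf$gain[, , 1]
  bf <- vector_beamformer(C, Lv, select_partial_sensors(Lv))
  o <- estimate_orientation(bf, C)
  ang <- acos(min(1, abs(sum(o * sim$orientation)))) * 180 / pi
  expect_lt(ang, 10)
  # scalar time series recovers the generating source
  q <- scalar_source_timeseries(eps, o, bf)
  src_band <- as.numeric(megdmn:::zerophase_butter(matrix(sim$src, 1), 1000,
                                                   c(31, 80), "pass"))
  expect_gte(abs(cor(q, src_band)), 0.9)
})

test_that("scalar beamformer output is linear and zero-preserving", {
  with_seed_test(42, {
    L <- matrix(rnorm(30), 10, 3)
    C <- diag(10)
    bf <- vector_beamformer(C, L, 1:10)
    o <- estimate_orientation(bf, C + tcrossprod(L[, 1] / 3))
    mats <- replicate(3, matrix(rnorm(10 * 100), 10), simplify = FALSE)
    eps <- as_epochs(mats, epoch_length = 0.1)
    q1 <- scalar_source_timeseries(eps, o, bf)
    eps2 <- eps; eps2$epochs <- lapply(eps$epochs, function(m) 3 * m)
    expect_equal(scalar_source_timeseries(eps2, o, bf), 3 * q1,
                 tolerance = 1e-12)
    eps0 <- eps; eps0$epochs <- lapply(eps$epochs, function(m) 0 * m)
    expect_true(all(scalar_source_timeseries(eps0, o, bf) == 0))
  })
})

test_that("accumulated source image equals the naive loop oracle", {
  with_seed_test(43, {
    for (r in 1:20) {
      V <- sample(1:6, 1); T <- sample(10:200, 1)
      Q <- matrix(rnorm(V * T), V, T)
      oracle <- numeric(V)
      for (v in 1:V) for (tt in 1:T) oracle[v] <- oracle[v] + abs(Q[v, tt])
      expect_equal(as.numeric(accumulate_source_image(Q)), oracle,
                   tolerance = 1e-12)
    }
    expect_equal(as.numeric(accumulate_source_image(rep(1, 10))), 10)
    expect_equal(as.numeric(accumulate_source_image(matrix(0, 2, 5))),
                 c(0, 0))
    expect_error(accumulate_source_image(matrix(0, 2, 0)),
                 class = "megdmn_input_error")
    # signed variant cancels oscillations
    expect_equal(as.numeric(accumulate_source_image(matrix(c(1, -1), 1, 2),
                                                    signed = TRUE)), 0)
  })
})

test_that("compiled grid scan agrees with the per-voxel R implementation", {
  grid <- fix$grid
  rr <- sqrt(rowSums(grid$coordinates^2))
  vxs <- c(which(rr > 45 & rr < 55)[c(2, 30)], which(rr == 0))
  sim <- simulate_dipole_recording(vxs[1], fix$arr102, grid, duration = 2,
                                   seed = 44)
  eps <- bandpass_epochs(segment_epochs(sim$rec), dmn_bands()$gamma)
  lf <- compute_lead_field(grid, fix$arr102, vxs)
  im <- asi_map(eps, lf)
  C <- sensor_covariance(eps)
  for (i in 1:2) {
    Lv <- lf$gain[, , i]
    sub <- select_partial_sensors(Lv)
    bf <- vector_beamformer(C, Lv, sub)
    o <- estimate_orientation(bf, C)
    q <- scalar_source_timeseries(eps, o, bf)
    expect_equal(im$asi[i], sum(abs(q)), tolerance = 1e-8)
    expect_equal(im$rank[i], bf$rank)
    expect_equal(abs(sum(im$orientation[, i] * o)), 1, tolerance = 1e-6)
  }
  expect_equal(im$rank[3], 0)   # center voxel silent
  expect_equal(im$asi[3], 0)
})

test_that("two well-separated dipoles are both localized within the grid step", {
  grid <- fix$grid
  co <- grid$coordinates
  v1 <- which(co[, 1] == -24 & co[, 2] == -24 & co[, 3] == 48)
  v2 <- which(co[, 1] == 18 & co[, 2] == 24 & co[, 3] == 48)
  stopifnot(length(v1) == 1, length(v2) == 1)
  s1 <- simulate_dipole_recording(v1, fix$arr102, grid, duration = 4,
                                  seed = 45)
  s2 <- simulate_dipole_recording(v2, fix$arr102, grid, duration = 4,
                                  seed = 46)
  rec <- s1$rec; rec$data <- s1$rec$data + s2$rec$data
  eps <- bandpass_epochs(segment_epochs(rec), dmn_bands()$gamma)
  pk <- localize_peak(asi_map(eps, get_full_lf()))
  err <- function(v) min(sqrt((pk$x - co[v, 1])^2 + (pk$y - co[v, 2])^2 +
                                (pk$z - co[v, 3])^2))
  expect_lte(err(v1), 6)
  expect_lte(err(v2), 6)
})

test_that("a flat accumulated image yields one deterministic flagged peak", {
  grid <- build_source_grid(0.09, 20)
  lfv <- seq_len(nrow(grid$coordinates))
  im <- structure(list(asi = rep(1, length(lfv)), voxels = lfv, grid = grid,
                       rank = rep(2L, length(lfv)), n = 10),
                  class = "asi_image")
  pk <- localize_peak(im)
  expect_equal(nrow(pk), 1)
  expect_true(attr(pk, "flat"))
  expect_equal(pk$voxel, 1)
})

test_that("a 40-Hz source shows up in the gamma image, not the alpha image", {
  grid <- fix$grid
  rr <- sqrt(rowSums(grid$coordinates^2))
  vx <- which(rr > 50 & rr < 60)[10]
  sim <- simulate_dipole_recording(vx, fix$arr102, grid, duration = 4,
                                   seed = 47, freq_band = c(39, 41))
  lf <- compute_lead_field(grid, fix$arr102, vx)
  eps <- segment_epochs(sim$rec)
  asi_g <- asi_map(bandpass_epochs(eps, dmn_bands()$gamma), lf)$asi
  asi_a <- asi_map(bandpass_epochs(eps, dmn_bands()$alpha), lf)$asi
  expect_gte(asi_g, 10 * asi_a)
})
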