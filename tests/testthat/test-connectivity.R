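test_that("the packaged ROI table matches the published DMN coordinates", {
  roi <- dmn_roi_table()
  expect_equal(nrow(roi), 12)
  expect_equal(unlist(roi[roi$name == "LAG", c("x_mni", "y_mni", "z_mni")],
                      use.names = FALSE), c(-43, -76, 35))
  expect_equal(unlist(roi[roi$name == "RPCC", c("x_mni", "y_mni", "z_mni")],
                      use.names = FALSE), c(3, -54, 31))
  expect_setequal(roi$name[roi$partition == "anterior"],
                  c("LvMPFC", "RvMPFC", "LdMPFC", "RdMPFC", "LACC", "RACC"))
  expect_setequal(roi$name[roi$partition == "posterior"],
                  c("LAG", "RAG", "LPCC", "RPCC", "LITG", "RITG"))
})

test_that("ROI table validation catches schema problems", {
  f <- tempfile(fileext = ".tsv")
  roi <- dmn_roi_table()
  write.table(roi[, c("name", "x_mni", "y_mni")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_roi_table(f), class = "megdmn_parse_error")
  roi2 <- as.data.frame(roi)
  roi2$name[2] <- "LAG"
  write.table(roi2, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_roi_table(f), class = "megdmn_parse_error")
})

test_that("the MNI-to-model affine keeps every ROI inside the source mask", {
  co <- mni_to_model(as.matrix(dmn_roi_table()[, c("x_mni", "y_mni", "z_mni")]))
  expect_true(all(sqrt(rowSums(co^2)) <= 0.9 * 0.09 * 1000))
  expect_equal(mni_to_model(matrix(c(10, 0, 0), 1)), matrix(c(8, 0, 0), 1))
})

test_that("pair correlation equals the from-scratch formula and flags degeneracy", {
  expect_equal(pair_correlation(1:10, 1:10), 1)
  expect_equal(pair_correlation(1:10, -(1:10)), -1)
  expect_equal(pair_correlation(c(1, 2, 3, 4, 5, 6, 7, 8),
                                2 * c(1, 2, 3, 4, 5, 6, 7, 8)), 1)
  with_seed_test(51, {
    for (r in 1:50) {
      n <- sample(8:200, 1)
      x <- rnorm(n); y <- rnorm(n)
      cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
      oracle <- cxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
                         sqrt(sum((y - mean(y))^2) / (n - 1)))
      expect_equal(pair_correlation(x, y), oracle, tolerance = 1e-12)
    }
  })
  expect_error(pair_correlation(rep(1, 10), rnorm(10)),
               class = "megdmn_degenerate_signal")
  expect_error(pair_correlation(1:4, 1:4), class = "megdmn_input_error")
})

test_that("Fisher pooling is a fixed point on identical epochs and is order-invariant", {
  with_seed_test(52, {
    m <- matrix(rnorm(6 * 400), 6)
    rownames(m) <- paste0("R", 1:6)
    same <- fc_matrix(list(m, m, m))
    expect_equal(unclass(same), cor(t(m)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    eps <- replicate(8, matrix(rnorm(6 * 300), 6,
                               dimnames = list(paste0("R", 1:6), NULL)),
                     simplify = FALSE)
    f1 <- fc_matrix(eps)
    f2 <- fc_matrix(rev(eps))
    expect_equal(unclass(f1), unclass(f2), tolerance = 1e-12)
    expect_true(isSymmetric(unclass(f1), tol = 1e-12))
    expect_true(all(diag(f1) == 1))
    expect_true(all(abs(f1) <= 1))
  })
})

test_that("pooled correlation recovers a constant generative coupling", {
  # band-limited pair mixed to c = 0.5, long signals, 0.5-s epochs
  z <- band_noise(3, 40000, 1000, 31, 80, seed = 53)
  c0 <- 0.5
  xa <- sqrt(c0) * z[1, ] + sqrt(1 - c0) * z[2, ]
  xb <- sqrt(c0) * z[1, ] + sqrt(1 - c0) * z[3, ]
  eps <- lapply(1:80, function(i) {
    m <- rbind(xa, xb)[, ((i - 1) * 500 + 1):(i * 500)]
    rownames(m) <- c("a", "b"); m
  })
  expect_lt(abs(fc_matrix(eps)["a", "b"] - c0), 0.05)
})

test_that("degenerate epochs are dropped with a warning, all-degenerate errors", {
  m1 <- matrix(rnorm(8), 2, 4 * 2, dimnames = list(c("a", "b"), NULL))
  m1 <- cbind(m1, m1)  # 2 x 16
  m0 <- matrix(0, 2, 16, dimnames = list(c("a", "b"), NULL))
  expect_warning(fc <- fc_matrix(list(m1, m0)), "dropped")
  expect_equal(attr(fc, "n_epochs_used"), 1L)
  expect_error(suppressWarnings(fc_matrix(list(m0, m0))),
               class = "megdmn_degenerate_signal")
})

test_that("node degree matches hand computations and the handshake lemma", {
  R9 <- matrix(0.9, 12, 12); diag(R9) <- 1
  expect_true(all(node_degree(R9) == 11))
  R1 <- matrix(0.1, 12, 12); diag(R1) <- 1
  expect_true(all(node_degree(R1) == 0))
  # printed toy: 4 nodes, edges 1-2:0.5, 1-3:0.4, 3-4:0.35
  toy <- diag(4)
  toy[1, 2] <- toy[2, 1] <- 0.5
  toy[1, 3] <- toy[3, 1] <- 0.4
  toy[3, 4] <- toy[4, 3] <- 0.35
  expect_equal(as.numeric(node_degree(toy, 0.3)), c(2, 1, 2, 1))
  expect_equal(as.numeric(node_degree(toy, 0.3, mode = "weighted")),
               c(0.9, 0.5, 0.75, 0.35))
  with_seed_test(54, {
    for (r in 1:200) {
      n <- sample(3:12, 1)
      A <- matrix(runif(n * n, -1, 1), n); A <- (A + t(A)) / 2; diag(A) <- 1
      s <- node_degree(A, runif(1, 0, 0.9))
      expect_equal(sum(s) %% 2, 0)   # handshake lemma
      expect_true(all(s <= n - 1))
    }
  })
  expect_error(node_degree(toy, threshold = 1), class = "megdmn_config_error")
})

test_that("degree is monotone non-increasing in the threshold", {
  with_seed_test(55, {
    A <- matrix(runif(144, -1, 1), 12); A <- (A + t(A)) / 2; diag(A) <- 1
    th <- seq(0, 0.9, by = 0.1)
    degs <- sapply(th, function(x) sum(node_degree(A, x)))
    expect_true(all(diff(degs) <= 0))
  })
})

test_that("ROI extraction recovers a seeded source and stays deterministic", {
  grid <- fix$grid
  roi <- fix$roi
  arr <- fix$arr102
  # place a gamma source exactly at the mapped LAG center's nearest voxel
  ctr <- megdmn:::roi_model_coords(roi)["LAG", ]
  vx <- which.min(colSums((t(grid$coordinates) - ctr)^2))
  sim <- simulate_dipole_recording(vx, arr, grid, duration = 6, seed = 56)
  eps <- bandpass_epochs(segment_epochs(sim$rec), dmn_bands()$gamma)
  lf <- compute_lead_field(grid, arr, unique(unlist(fix$roi_vox)))
  out1 <- extract_roi_signals(eps, roi, lf)
  out2 <- extract_roi_signals(eps, roi, lf)
  expect_identical(out1$signals, out2$signals)
  q <- do.call(cbind, out1$signals)
  src_band <- as.numeric(megdmn:::zerophase_butter(matrix(sim$src, 1), 1000,
                                                   c(31, 80), "pass"))
  expect_gte(abs(cor(q["LAG", ], src_band)), 0.9)
  expect_lte(abs(cor(q["RITG", ], src_band)), 0.5)
  # zero input gives zero ROI signals
  z <- eps; z$epochs <- lapply(z$epochs, function(m) 0 * m)
  zs <- extract_roi_signals(z, roi, lf)
  expect_true(all(vapply(zs$signals, function(m) all(m == 0), TRUE)))
})

test_that("an ROI outside the mask raises a geometry error naming it", {
  roi <- as.data.frame(dmn_roi_table())
  roi$x_mni[1] <- 300
  class(roi) <- c("roi_table", "data.frame")
  expect_error(megdmn:::roi_voxel_sets(roi, fix$grid), "LAG",
               class = "megdmn_geometry_error")
})
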