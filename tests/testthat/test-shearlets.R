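test_that("system construction tiles the frequency plane", {
  sys <- build_system_2d(c(64, 64), n_scales = 3, shears_per_scale = 12,
                         filter_length = 20)
  expect_equal(sum(sys$index$scale == 1), 12)   # 12 directional filters
  S <- Reduce(`+`, lapply(sys$windows, function(w) w^2))
  expect_lt(max(abs(S - 1)), 1e-12)
  sys2 <- build_system_2d(c(64, 64), n_scales = 3, shears_per_scale = 12,
                          filter_length = 20)
  expect_identical(sys$windows, sys2$windows)
  expect_error(build_system_2d(c(32, 32), filter_length = 40),
               "filter_length")
})

test_that("forward transform is linear and matches the spatial oracle", {
  sys <- build_system_2d(c(48, 48))
  z <- transform_forward(matrix(0, 48, 48), sys)
  expect_true(all(vapply(z$bands, function(b) all(b == 0), logical(1))))

  set.seed(4)
  f <- matrix(rnorm(48 * 48), 48)
  g <- matrix(rnorm(48 * 48), 48)
  cf <- transform_forward(f, sys)
  cg <- transform_forward(g, sys)
  cfg2 <- transform_forward(f + g, sys)
  for (b in seq_along(cf$bands))
    expect_equal(cfg2$bands[[b]], cf$bands[[b]] + cg$bands[[b]],
                 tolerance = 1e-12)

  ## oracle: coefficient = inner product with the circularly shifted
  ## analyzing function, computed by direct spatial summation
  b <- 20
  psi <- Re(stats::fft(sys$windows[[b]] + 0i, inverse = TRUE)) / (48 * 48)
  idx <- function(k) ((k - 1) %% 48) + 1
  for (p in list(c(7, 13), c(40, 2))) {
    oracle <- 0
    for (i in 1:48) for (j in 1:48)
      oracle <- oracle + f[i, j] * psi[idx(i - (p[1] - 1)),
                                       idx(j - (p[2] - 1))]
    expect_equal(cf$bands[[b]][p[1], p[2]], oracle, tolerance = 1e-9)
  }

  ## shifted impulse response = circular shift of centered response
  imp <- matrix(0, 48, 48); imp[1, 1] <- 1
  imps <- matrix(0, 48, 48); imps[5, 9] <- 1
  c0 <- transform_forward(imp, sys)$bands[[b]]
  c1 <- transform_forward(imps, sys)$bands[[b]]
  shifted <- c0[((seq_len(48) - 5) %% 48) + 1, , drop = FALSE]
  shifted <- shifted[, ((seq_len(48) - 9) %% 48) + 1, drop = FALSE]
  expect_equal(c1, shifted, tolerance = 1e-12)

  expect_error(transform_forward(matrix(0, 32, 32), sys), "shape")
})

test_that("inverse transform reconstructs within tolerance", {
  sys <- build_system_2d(c(128, 128))
  set.seed(5)
  f <- matrix(rnorm(128 * 128), 128)
  co <- transform_forward(f, sys)
  fr <- transform_inverse(co, sys)
  expect_lt(sqrt(sum((fr - f)^2) / sum(f^2)), 1e-3)

  z <- transform_forward(matrix(0, 128, 128), sys)
  expect_true(all(transform_inverse(z, sys) == 0))

  fr2 <- transform_inverse(transform_forward(fr, sys), sys)
  expect_equal(fr2, fr, tolerance = 1e-10)

  other <- build_system_2d(c(64, 64))
  expect_error(transform_inverse(co, other), "match")
})

test_that("shrinkage denoising raises PSNR and spares clean images", {
  sys <- cached_system(c(128, 128))
  expect_true(all(shrink_denoise(matrix(0, 128, 128), sys) == 0))

  clean <- 0.1 + 0.9 * disk_mask(128, 64, 64, 30)
  noisy <- apply_noise_and_attenuation(clean, photon_scale = 50, seed = 3)
  den <- shrink_denoise(noisy, sys)
  expect_gt(psnr(den, clean), psnr(noisy, clean))

  den_clean <- shrink_denoise(clean, sys)
  expect_lt(sqrt(sum((den_clean - clean)^2) / sum(clean^2)), 0.05)

  ## shrinkage is a contraction: with a tight frame the output norm
  ## cannot exceed the input norm
  expect_lte(sum(den^2), sum(noisy^2))
})
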