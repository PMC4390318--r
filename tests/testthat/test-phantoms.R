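test_that("2D phantom rendering matches its ground truth by construction", {
  spec <- phantom_spec(c(128, 128),
                       somas = list(
                         list(center = c(30, 30), semi_axes = c(12, 12)),
                         list(center = c(30, 95), semi_axes = c(14, 10)),
                         list(center = c(95, 60), semi_axes = c(10, 14))))
  r <- generate_neuron_image_2d(spec)
  lab <- EBImage::bwlabel((r$truth$soma_labels > 0) * 1)
  expect_equal(max(lab), 3)
  expect_setequal(unique(as.vector(r$truth$soma_labels)), 0:3)
  ## every rendered soma pixel is labeled (intensity 1 iff inside a soma)
  expect_true(all((r$image == 1) == (r$truth$soma_labels > 0)))
})

test_that("an empty spec renders a constant background", {
  r <- generate_neuron_image_2d(phantom_spec(c(32, 32),
                                             background_level = 0.07))
  expect_true(all(r$image == 0.07))
  expect_true(all(r$truth$soma_labels == 0))
})

test_that("overlapping somas keep distinct labels", {
  spec <- phantom_spec(c(96, 96),
                       somas = list(
                         list(center = c(48, 40), semi_axes = c(14, 14)),
                         list(center = c(48, 58), semi_axes = c(14, 14))))
  r <- generate_neuron_image_2d(spec)
  expect_setequal(setdiff(unique(as.vector(r$truth$soma_labels)), 0), 1:2)
  ## the overlap is split, not handed wholesale to one soma
  expect_gt(sum(r$truth$soma_labels == 1), 300)
  expect_gt(sum(r$truth$soma_labels == 2), 300)
})

test_that("geometry outside the image bounds is rejected", {
  expect_error(phantom_spec(c(64, 64),
                            somas = list(list(center = c(5, 5),
                                              semi_axes = c(10, 10)))),
               "outside")
  expect_error(phantom_spec(c(64, 64),
                            neurites = list(list(path = rbind(c(10, 10),
                                                              c(10, 70)),
                                            width = 4))),
               "outside")
})

test_that("depth attenuation dims the bottom of the stack", {
  ## z-uniform content (pure background): strictly decreasing slice means
  bg <- phantom_spec(c(16, 16, 12), background_level = 0.5,
                     z_attenuation = 0.9)
  mb <- apply(generate_neuron_stack_3d(bg)$stack, 3, mean)
  expect_true(all(diff(mb) < 0))

  ## z-symmetric soma: the bottom mirror slice is dimmer than the top one
  spec <- phantom_spec(c(48, 48, 21),
                       somas = list(list(center = c(24, 24, 11),
                                         semi_axes = c(12, 12, 7))),
                       z_attenuation = 0.9)
  r <- generate_neuron_stack_3d(spec)
  m <- apply(r$stack, 3, mean)
  expect_lt(m[21], m[1])
  expect_lt(m[15], m[7])

  spec1 <- phantom_spec(c(48, 48, 21),
                        somas = list(list(center = c(24, 24, 11),
                                          semi_axes = c(12, 12, 7))),
                        z_attenuation = 1)
  m1 <- apply(generate_neuron_stack_3d(spec1)$stack, 3, mean)
  ## z-symmetric phantom, no attenuation: symmetric slice means
  expect_equal(m1, rev(m1))
})

test_that("identical spec and seed give bit-identical stacks", {
  mk <- function() generate_neuron_stack_3d(
    phantom_spec(c(40, 40, 12),
                 somas = list(list(center = c(20, 20, 6),
                                   semi_axes = c(10, 10, 4))),
                 photon_scale = 40, z_attenuation = 0.92, seed = 11))
  expect_identical(mk()$stack, mk()$stack)
})

test_that("ellipsoid phantom equals the lattice-point count oracle", {
  shape <- c(64, 64, 32)
  semi <- c(20, 15, 8)
  ph <- generate_ellipsoid_phantom(semi, shape, 0)
  c0 <- (shape + 1) / 2
  g <- as.matrix(expand.grid(y = 1:64, x = 1:64, z = 1:32))
  brute <- sum(((g[, 1] - c0[1]) / semi[1])^2 +
                 ((g[, 2] - c0[2]) / semi[2])^2 +
                 ((g[, 3] - c0[3]) / semi[3])^2 <= 1)
  expect_equal(sum(ph$stack), brute)
  ## boundary voxels lie inside the ellipsoid support
  expect_true(all(ph$stack[ph$surface_voxels] == 1))
})

test_that("smoothed ellipsoid stays in [0,1]; degenerate case is tiny", {
  ph <- generate_ellipsoid_phantom(c(20, 15, 8), c(64, 64, 32), 0.6)
  expect_gte(min(ph$stack), 0)
  expect_lte(max(ph$stack), 1)
  tiny <- generate_ellipsoid_phantom(c(1, 1, 1), c(16, 16, 9), 0)
  expect_gt(nrow(tiny$surface_voxels), 0)
  expect_lte(nrow(tiny$surface_voxels), 27)
})

test_that("Poisson noise model behaves at its limits", {
  ys <- matrix(seq_len(32), 32, 32)
  ph <- array(rep((ys - 16)^2 / 512, 8), c(32, 32, 8))  # values in [0,1]
  out <- apply_noise_and_attenuation(ph, photon_scale = 1e6, seed = 2)
  expect_lt(max(abs(out - ph)), 0.02)
  expect_identical(apply_noise_and_attenuation(ph * 0, 100, seed = 1),
                   ph * 0)
  a <- apply_noise_and_attenuation(ph, 30, 0.95, seed = 9)
  b <- apply_noise_and_attenuation(ph, 30, 0.95, seed = 9)
  expect_identical(a, b)
  expect_error(apply_noise_and_attenuation(ph - 1, 100), "nonnegative")
})

test_that("phantom specs round-trip through YAML", {
  spec <- random_neuron_spec_2d(4, 1, seed = 31)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  r1 <- generate_neuron_image_2d(spec)
  r2 <- generate_neuron_image_2d(back)
  expect_equal(r1$image, r2$image)
  expect_identical(r1$truth$soma_labels, r2$truth$soma_labels)
})
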