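test_that("feature bank: channel count, constants, exact isotropy", {
  f <- matrix(0.4, 64, 64)
  fb <- compute_feature_bank(f, c(1, 2, 4, 8))
  expect_equal(dim(fb)[3], 5)
  for (k in 1:4) expect_lt(max(abs(fb[, , k])), 1e-12)
  expect_error(compute_feature_bank(f, numeric(0)), "scale")

  set.seed(8)
  g <- matrix(rnorm(64 * 64), 64)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  fb_g <- compute_feature_bank(g, c(2, 4))
  fb_r <- compute_feature_bank(rot90(g), c(2, 4))
  for (k in 1:2)
    expect_equal(fb_r[, , k], rot90(fb_g[, , k]), tolerance = 1e-10)
})

test_that("training handles separable data and rejects one-class labels", {
  set.seed(21)
  img <- matrix(runif(32 * 32), 32)
  lab <- img > 0.5
  img[lab] <- img[lab] + 1      # linearly separable on intensity
  fb <- compute_feature_bank(img, c(1, 2))
  model <- train_segmenter(list(fb), list(lab),
                           list(n_samples = 400, seed = 3,
                                min_component_area = 0))
  pred <- segment_image(img, model)
  expect_equal(mean(pred == lab), 1)

  expect_error(train_segmenter(list(fb), list(lab & FALSE)),
               "both classes")
  expect_error(segment_image(img, list()), "model")
})

test_that("training is reproducible under a fixed seed", {
  r <- generate_neuron_image_2d(random_neuron_spec_2d(3, 0, seed = 61))
  fb <- compute_feature_bank(r$image, c(1, 2, 4))
  lab <- r$truth$soma_labels > 0 | r$truth$neurite_mask
  m1 <- train_segmenter(list(fb), list(lab), list(seed = 5))
  m2 <- train_segmenter(list(fb), list(lab), list(seed = 5))
  expect_identical(m1$w, m2$w)
  expect_identical(m1$center, m2$center)
})

test_that("phantom-trained segmenter generalizes to held-out phantoms", {
  model <- cached_segmenter_2d()
  sys <- cached_system(c(256, 256))
  r <- generate_neuron_image_2d(random_neuron_spec_2d(5, 0, seed = 999))
  truth <- r$truth$soma_labels > 0 | r$truth$neurite_mask
  m <- segment_image(shrink_denoise(r$image, sys), model)
  expect_true(is.logical(m))
  expect_identical(dim(m), dim(r$image))
  expect_gte(mean(m == truth), 0.95)
  expect_gte(segmentation_scores(confusion_counts(m, truth))$DC, 0.9)

  ## constant background -> empty mask
  bg <- matrix(0.05, 256, 256)
  expect_equal(sum(segment_image(bg, model)), 0)
})

test_that("segmentation quality degrades monotonically with noise", {
  cfg <- somatect_config()
  sys <- cached_system(c(256, 256))
  dice_at <- function(photon) {
    feats <- list(); labs <- list()
    for (i in 1:3) {
      r <- generate_neuron_image_2d(
        random_neuron_spec_2d(4, 0, seed = 600 + i, photon_scale = photon))
      feats[[i]] <- compute_feature_bank(shrink_denoise(r$image, sys),
                                         cfg$feature_scales)
      labs[[i]] <- r$truth$soma_labels > 0 | r$truth$neurite_mask
    }
    model <- train_segmenter(feats, labs, list(seed = 1))
    r <- generate_neuron_image_2d(
      random_neuron_spec_2d(5, 0, seed = 777, photon_scale = photon))
    truth <- r$truth$soma_labels > 0 | r$truth$neurite_mask
    segmentation_scores(confusion_counts(
      segment_image(shrink_denoise(r$image, sys), model), truth))$DC
  }
  d <- vapply(c(100, 8, 1.2), dice_at, numeric(1))
  expect_true(all(diff(d) < 0))
})
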