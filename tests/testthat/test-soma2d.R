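test_that("stack projection implements MIP and AIP", {
  one <- array(runif(64), c(8, 8, 1))
  expect_equal(project_stack(one, "MIP"), one[, , 1])
  expect_equal(project_stack(one, "AIP"), one[, , 1])

  st <- array(0, c(4, 4, 2)); st[, , 2] <- 1
  expect_true(all(project_stack(st, "MIP") == 1))
  expect_true(all(project_stack(st, "AIP") == 0.5))

  set.seed(2)
  r <- array(runif(4 * 4 * 5), c(4, 4, 5))
  expect_true(all(project_stack(r, "MIP") >= project_stack(r, "AIP")))
  expect_error(project_stack(st, "median"))
})

test_that("area model fits sample moments and checks normality", {
  m <- fit_area_model(c(900, 1000, 1100))
  expect_equal(m$mu, 1000)
  expect_equal(m$sigma, 100)

  expect_error(fit_area_model(rep(1000, 5)), "degenerate")
  expect_error(fit_area_model(c(900, 1000)), "3")

  a <- somatect:::with_seed(5, rnorm(200, 1000, 100))
  mn <- fit_area_model(a)
  expect_gt(mn$ks_p, 0.05)
})

test_that("the 3-sigma rule flags multi-soma areas, with N generalization", {
  model <- list(mu = 1000, sigma = 100)
  recs <- data.frame(id = 1:4, area = c(1350, 1100, 2050, 3050))
  out <- flag_multi_soma_regions(recs, model)
  expect_equal(out$n_somas, c(2L, 1L, 2L, 3L))
  expect_equal(out$flagged, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("clustered regions split at the coarse scale", {
  n <- 192
  sys40 <- cached_system(c(n, n), 40)
  two <- disk_mask(n, 96, 76, 20) | disk_mask(n, 96, 113, 20)
  parts <- suppressWarnings(separate_clustered(two, 2, sys40))
  expect_equal(max(parts), 2)
  for (k in 1:2) {
    truth_k <- if (k == 1) disk_mask(n, 96, 76, 20) else
      disk_mask(n, 96, 113, 20)
    best <- which.max(c(sum(parts == 1 & truth_k), sum(parts == 2 & truth_k)))
    dc <- segmentation_scores(confusion_counts(parts == best, truth_k))$DC
    expect_gte(dc, 0.85)
  }

  ## a single blob wrongly flagged is returned whole, with a warning
  one <- disk_mask(n, 96, 96, 20)
  expect_warning(p1 <- separate_clustered(one, 2, sys40), "unsplit")
  expect_identical(p1 > 0, one)

  ## three contiguous somas in a row
  three <- two | disk_mask(n, 96, 150, 20)
  p3 <- suppressWarnings(separate_clustered(three, 3, sys40))
  expect_equal(max(p3), 3)
})

test_that("full 2D pipeline recovers phantom soma counts", {
  cfg <- somatect_config(segmenter = cached_segmenter_2d())

  r5 <- generate_neuron_image_2d(random_neuron_spec_2d(5, 0, seed = 881))
  det5 <- suppressWarnings(detect_somas_2d(r5$image, cfg))
  expect_equal(nrow(det5$records), 5)

  r32 <- generate_neuron_image_2d(random_neuron_spec_2d(5, 1, seed = 883))
  det32 <- suppressWarnings(detect_somas_2d(r32$image, cfg))
  expect_equal(nrow(det32$records), 5)
  expect_true(any(det32$records$split_from_cluster))

  empty <- matrix(0.05, 256, 256)
  expect_warning(det0 <- detect_somas_2d(empty, cfg))
  expect_equal(nrow(det0$records), 0)
})

test_that("detection is deterministic", {
  cfg <- somatect_config(segmenter = cached_segmenter_2d())
  r <- generate_neuron_image_2d(random_neuron_spec_2d(4, 1, seed = 884))
  d1 <- suppressWarnings(detect_somas_2d(r$image, cfg))
  d2 <- suppressWarnings(detect_somas_2d(r$image, cfg))
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$records, d2$records)
})

test_that("front labels stay within the segmentation mask", {
  cfg <- somatect_config(segmenter = cached_segmenter_2d())
  r <- generate_neuron_image_2d(random_neuron_spec_2d(4, 0, seed = 885))
  det <- suppressWarnings(detect_somas_2d(r$image, cfg))
  expect_true(all(det$mask[det$labels > 0]))
})
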