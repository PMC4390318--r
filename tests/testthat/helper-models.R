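## expensive fixtures (trained models, benchmark suites) built once per run

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

cached_system <- function(shape, filter_length = 20) {
  memo(paste0("sys_", paste(shape, collapse = "x"), "_", filter_length),
       function() build_system_2d(shape, filter_length = filter_length))
}

## segmenter trained on five 2D phantoms of the default imaging condition
cached_segmenter_2d <- function() {
  memo("segmenter_2d", function() {
    cfg <- somatect_config()
    sys <- cached_system(c(256, 256))
    feats <- list(); labs <- list()
    for (i in 1:5) {
      r <- generate_neuron_image_2d(
        random_neuron_spec_2d(4 + (i %% 3), 0, seed = 100 + i))
      feats[[i]] <- compute_feature_bank(shrink_denoise(r$image, sys),
                                         cfg$feature_scales)
      labs[[i]] <- r$truth$soma_labels > 0 | r$truth$neurite_mask
    }
    train_segmenter(feats, labs, list(seed = 42))
  })
}

## segmenter for the thin-stack condition, trained on projections
cached_segmenter_3d <- function() {
  memo("segmenter_3d", function() {
    cfg <- somatect_config()
    sys <- cached_system(c(160, 160))
    feats <- list(); labs <- list()
    for (i in 1:4) {
      r <- generate_neuron_stack_3d(
        random_neuron_spec_3d(2 + i %% 2, seed = 300 + i))
      den <- shrink_denoise(project_stack(r$stack, "MIP"), sys)
      feats[[i]] <- compute_feature_bank(den, cfg$feature_scales)
      labs[[i]] <- apply(r$truth$soma_labels > 0 | r$truth$neurite_mask,
                         c(1, 2), any)
    }
    train_segmenter(feats, labs, list(seed = 7))
  })
}

## benchmark: 20 seeded 2D phantoms (3-8 somas, up to 2 contiguous pairs)
cached_suite_2d <- function() {
  memo("suite_2d", function() {
    cfg <- somatect_config(segmenter = cached_segmenter_2d())
    draws <- somatect:::with_seed(202, {
      ns <- sample(3:8, 20, replace = TRUE)
      list(ns = ns, np = pmin(sample(0:2, 20, replace = TRUE), ns %/% 2))
    })
    res <- lapply(1:20, function(i) {
      sp <- random_neuron_spec_2d(draws$ns[i], draws$np[i], seed = 2000 + i)
      r <- generate_neuron_image_2d(sp)
      det <- suppressWarnings(detect_somas_2d(r$image, cfg))
      per_soma <- lapply(seq_along(sp$somas), function(k) {
        tm <- r$truth$soma_labels == k
        ids <- setdiff(unique(det$labels[tm]), 0)
        if (!length(ids)) return(list(TPR = 0, DC = 0))
        best <- ids[which.max(vapply(ids, function(q)
          sum(det$labels == q & tm), numeric(1)))]
        segmentation_scores(confusion_counts(det$labels == best, tm))
      })
      list(n_true = length(sp$somas), n_pairs = draws$np[i],
           n_det = nrow(det$records),
           tpr = vapply(per_soma, `[[`, numeric(1), "TPR"),
           dice = vapply(per_soma, `[[`, numeric(1), "DC"))
    })
    res
  })
}

## benchmark: three seeded thin-stack phantoms, three somas each
cached_suite_3d <- function() {
  memo("suite_3d", function() {
    cfg <- somatect_config(segmenter = cached_segmenter_3d())
    lapply(1:3, function(i) {
      sp <- random_neuron_spec_3d(3, seed = 400 + i)
      r <- generate_neuron_stack_3d(sp)
      res <- suppressWarnings(detect_somas_3d(r$stack, cfg))
      dice <- vapply(res$volumes, function(v) {
        if (!nrow(v$voxels)) return(0)
        pred <- array(FALSE, dim(r$stack))
        pred[v$voxels] <- TRUE
        tl <- r$truth$soma_labels[v$voxels]
        tl <- tl[tl > 0]
        if (!length(tl)) return(0)
        k <- as.integer(names(which.max(table(tl))))
        segmentation_scores(
          confusion_counts(pred, r$truth$soma_labels == k))$DC
      }, numeric(1))
      list(n_true = length(sp$somas), n_det = length(res$volumes),
           dice = dice)
    })
  })
}
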