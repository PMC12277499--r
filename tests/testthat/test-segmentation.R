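tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(preset = "desk", crop_size = 16, embed_dim = 8, head_dim = 4,
         n_stages = 2, iterations = 5, seed = 3),
    list(...))
  do.call(segmentation_config, args)
}

test_that("CT preprocessing clips, scales and resamples", {
  g <- volume_grid(c(8, 8, 8), c(3, 3, 3))
  vals <- array(0, c(8, 8, 8))
  vals[1:4, , ] <- -175; vals[5, , ] <- 250; vals[6, , ] <- 37.5
  vals[7, , ] <- -1000; vals[8, , ] <- 1000
  ct <- scalar_volume(vals, g, "CT")
  cfg <- tiny_cfg()
  out <- preprocess_ct(ct, cfg)
  expect_equal(out$grid$spacing, c(3, 3, 3))
  expect_equal(out$values[1, 1, 1], 0)        # -175 -> 0
  expect_equal(out$values[5, 1, 1], 1)        # 250 -> 1
  expect_equal(out$values[6, 1, 1], 0.5)      # (37.5+175)/425
  expect_equal(out$values[7, 1, 1], 0)        # clipped below
  expect_equal(out$values[8, 1, 1], 1)        # clipped above
  # resampling to a different spacing changes the lattice
  cfg2 <- segmentation_config("desk", target_spacing = c(1.5, 1.5, 1.5))
  out2 <- preprocess_ct(ct, cfg2)
  expect_equal(out2$grid$dims, c(16L, 16L, 16L))
  expect_error(preprocess_ct(scalar_volume(vals, g, "PET"), cfg), "CT")
})

test_that("augmentation with zero probabilities is the identity", {
  cfg <- segmentation_config("desk", flip_prob = 0, rotate_prob = 0,
                             intensity_prob = 0)
  set.seed(2)
  s <- list(volume = array(runif(16^3), c(16, 16, 16)),
            labels = array(sample(0:5, 16^3, TRUE), c(16, 16, 16)))
  out <- augment(s, cfg, seed = 5)
  expect_identical(out$volume, s$volume)
  expect_identical(out$labels, s$labels)
})

test_that("forced flips are involutions and keep labels aligned", {
  cfg <- tiny_cfg()
  set.seed(2)
  s <- list(volume = array(runif(16^3), c(16, 16, 16)),
            labels = array(sample(0:5, 16^3, TRUE), c(16, 16, 16)))
  once <- augment(s, cfg, seed = 5, force_flip = c(TRUE, FALSE, TRUE))
  twice <- augment(once, cfg, seed = 6, force_flip = c(TRUE, FALSE, TRUE))
  expect_identical(twice$volume, s$volume)
  expect_identical(twice$labels, s$labels)
})

test_that("forced rotations transform volume and labels identically", {
  cfg <- tiny_cfg()
  set.seed(7)
  vol <- array(runif(16^3), c(16, 16, 16))
  lab <- array(0L, c(16, 16, 16))
  lab[vol > 0.8] <- 1L  # labels carved from the volume itself
  out <- augment(list(volume = vol, labels = lab), cfg, seed = 1,
                 force_rotation = list(axes = c(1, 2), k = 1))
  # voxel-wise correspondence survives the rotation
  expect_identical(out$labels, array(as.integer(out$volume > 0.8),
                                     dim(out$volume)))
  # four quarter turns restore the original
  full <- augment(list(volume = vol, labels = lab), cfg, seed = 1,
                  force_rotation = list(axes = c(2, 3), k = 4))
  expect_identical(full$volume, vol)
})

test_that("augmentation is deterministic per seed", {
  cfg <- segmentation_config("desk", flip_prob = 0.5, rotate_prob = 0.5,
                             intensity_prob = 0.5)
  set.seed(3)
  s <- list(volume = array(runif(16^3), c(16, 16, 16)),
            labels = array(sample(0:5, 16^3, TRUE), c(16, 16, 16)))
  a <- augment(s, cfg, seed = 42)
  b <- augment(s, cfg, seed = 42)
  expect_identical(a, b)
})

test_that("the network outputs one probability simplex per voxel", {
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  set.seed(1)
  x <- array(runif(16^3), c(16, 16, 16))
  pred <- predict_segmentation(m, x)
  expect_equal(dim(pred$probs), c(16, 16, 16, 6))
  sums <- apply(pred$probs, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(pred$labels %in% 0:5))
  # deterministic per seed: same config -> same parameters -> same output
  m2 <- build_model(cfg)
  pred2 <- predict_segmentation(m2, x)
  expect_identical(pred$probs, pred2$probs)
  expect_true(all(is.finite(pred$probs)))
})

test_that("encoder stages halve token resolution and double channels", {
  cfg <- tiny_cfg()
  plan <- petquant:::model_plan(cfg)
  expect_equal(plan$token_grids[[1]], c(8L, 8L, 8L))
  expect_equal(plan$token_grids[[2]], c(4L, 4L, 4L))
  expect_equal(plan$token_grids[[3]], c(2L, 2L, 2L))
  expect_equal(plan$channels, c(8L, 16L, 32L))
  # window dims never exceed the token grid and always divide it
  for (i in seq_along(plan$token_grids)) {
    expect_true(all(plan$windows[[i]] <= plan$token_grids[[i]]))
    expect_true(all(plan$token_grids[[i]] %% plan$windows[[i]] == 0))
  }
})

test_that("incompatible crop/patch/stage combinations are named", {
  expect_error(segmentation_config("desk", crop_size = 20),
               "divisible")
  m <- build_model(tiny_cfg())
  expect_error(petquant:::model_forward(m, array(0, c(12, 12, 12))),
               "divisible")
})

test_that("segmentation evaluation matches dice oracle cases", {
  lab <- array(0L, c(6, 6, 6)); lab[2:3, 2:3, 2:3] <- 1L
  expect_equal(evaluate_segmentation(lab, lab, n_classes = 2), 1)
  none <- array(0L, c(6, 6, 6))
  expect_equal(evaluate_segmentation(none, lab, n_classes = 2), 0)
  # half-overlap construction: 8-voxel cubes sharing 4 voxels
  half <- array(0L, c(6, 6, 6)); half[2:3, 2:3, 3:4] <- 1L
  expect_equal(evaluate_segmentation(half, lab, n_classes = 2), 0.5)
  # mask-list interface agrees
  g <- volume_grid(c(6, 6, 6), c(1, 1, 1))
  expect_equal(evaluate_segmentation(list(binary_mask(half == 1, g)),
                                     list(binary_mask(lab == 1, g))), 0.5)
})

test_that("zero training iterations leave parameters untouched", {
  cfg <- tiny_cfg(iterations = 0)
  m <- build_model(cfg)
  before <- lapply(ls(m$params), function(nm) m$params[[nm]])
  res <- train(m, segmentation_dataset_from_phantoms(1, cfg, seed = 2), cfg)
  after <- lapply(ls(m$params), function(nm) m$params[[nm]])
  expect_identical(before, after)
  expect_length(res$loss, 0)
})

test_that("a short training run reduces the loss", {
  cfg <- tiny_cfg(iterations = 25, learning_rate = 3e-3)
  ds <- segmentation_dataset_from_phantoms(2, cfg, seed = 5)
  m <- build_model(cfg)
  res <- train(m, ds, cfg, dice_every = 0)
  expect_length(res$loss, 25)
  expect_lt(mean(tail(res$loss, 5)), mean(head(res$loss, 5)))
  expect_error(train(build_model(cfg), list(), cfg), "empty")
})

test_that("the threshold baseline recovers distinct-intensity organs", {
  cfg <- tiny_cfg()
  ds <- segmentation_dataset_from_phantoms(1, cfg, seed = 8)
  s <- ds[[1]]
  # preprocessed intensities of the five organs (HU mapped to [0,1])
  levels <- (c(-60, -60, 60, 120, 220) + 175) / 425
  pred <- segment_by_threshold(s$volume, levels,
                               background_below = 0.05)
  # intensity alone cannot separate the two breasts; merge them for the
  # check by treating labels 1/2 as one class
  merged_pred <- ifelse(pred == 2L, 1L, pred)
  merged_true <- ifelse(s$labels == 2L, 1L, s$labels)
  expect_gt(evaluate_segmentation(merged_pred, merged_true, 6), 0.9)
})
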