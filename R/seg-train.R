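#' Normalize and resample a CT volume for segmentation
#'
#' Clips intensities to the configured HU range, maps them linearly to
#' `[0, 1]`, and resamples (trilinear) to the configured target spacing.
#'
#' @param ct a CT [scalar_volume()].
#' @param config a [segmentation_config()].
#' @return A CT [scalar_volume()] with values in `[0, 1]` on the
#'   resampled grid.
#' @export
preprocess_ct <- function(ct, config) {
  stopifnot(is_scalar_volume(ct), inherits(config, "segmentation_config"))
  if (ct$modality != "CT") stop("preprocess_ct expects a CT volume",
                                call. = FALSE)
  lo <- config$clip_range[1]; hi <- config$clip_range[2]
  vals <- (pmin(pmax(ct$values, lo), hi) - lo) / (hi - lo)
  vol <- scalar_volume(vals, ct$grid, "CT")
  sp <- config$target_spacing
  if (max(abs(sp - ct$grid$spacing)) < 1e-9) return(vol)
  new_dims <- pmax(1L, as.integer(round(ct$grid$dims * ct$grid$spacing / sp)))
  target <- volume_grid(new_dims, sp, ct$grid$origin, ct$grid$orientation)
  resample(vol, target, "trilinear")
}

#' Augment a volume/label pair
#'
#' Spatial transforms (per-axis flips and 90-degree rotations, each with
#' its configured probability) are applied identically to the volume and
#' labels; the intensity shift (uniform offset up to
#' `intensity_offset`, with probability `intensity_prob`) touches the
#' volume only. Deterministic for a fixed seed. `force_flip` /
#' `force_rotation` bypass the coin flips (used in tests).
#'
#' @param sample list with 3D arrays `volume` and `labels` of identical
#'   dims.
#' @param config a [segmentation_config()].
#' @param seed RNG seed.
#' @param force_flip optional logical length 3: flip exactly these axes.
#' @param force_rotation optional list `list(axes = c(i, j), k = n)`:
#'   rotate the `(i, j)` plane by `k` quarter turns.
#' @return Sample of the same shape.
#' @export
augment <- function(sample, config, seed = 1L, force_flip = NULL,
                    force_rotation = NULL) {
  stopifnot(is.list(sample), !is.null(sample$volume), !is.null(sample$labels))
  if (!all(dim(sample$volume) == dim(sample$labels))) {
    stop("volume and labels dims differ", call. = FALSE)
  }
  set.seed(seed)
  vol <- sample$volume
  lab <- sample$labels

  flips <- if (!is.null(force_flip)) {
    as.logical(force_flip)
  } else {
    stats::runif(3) < config$flip_prob
  }
  for (ax in which(flips)) {
    vol <- flip_axis(vol, ax)
    lab <- flip_axis(lab, ax)
  }

  rot <- force_rotation
  if (is.null(rot) && stats::runif(1) < config$rotate_prob) {
    axes <- sample.int(3, 2)
    rot <- list(axes = axes, k = sample.int(3, 1))
  }
  if (!is.null(rot)) {
    if (dim(vol)[rot$axes[1]] != dim(vol)[rot$axes[2]]) {
      stop("90-degree rotation needs equal extents on the rotated axes",
           call. = FALSE)
    }
    vol <- rot90_3d(vol, rot$axes, rot$k)
    lab <- rot90_3d(lab, rot$axes, rot$k)
  }

  if (!is.null(force_flip) || !is.null(force_rotation)) {
    shift_it <- FALSE
  } else {
    shift_it <- stats::runif(1) < config$intensity_prob
  }
  if (shift_it) {
    vol <- vol + stats::runif(1, -config$intensity_offset,
                              config$intensity_offset)
  }
  list(volume = vol, labels = lab)
}

flip_axis <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx))
}

rot90_3d <- function(a, axes, k = 1L) {
  k <- ((k - 1L) %% 4L) + 1L
  for (r in seq_len(k)) {
    a <- flip_axis(a, axes[1])
    perm <- seq_len(3)
    perm[axes] <- rev(axes)
    a <- aperm(a, perm)
  }
  a
}

# ---- loss ------------------------------------------------------------

# Combined soft-dice + cross-entropy on softmax probabilities. Returns
# the scalar loss and dL/dlogits. Labels are 0-based class integers.
seg_loss <- function(probs, logits, labels_vec, config) {
  n <- nrow(probs)
  nc <- config$n_classes
  onehot <- matrix(0, n, nc)
  onehot[cbind(seq_len(n), labels_vec + 1L)] <- 1

  eps <- 1e-6
  inter <- colSums(probs * onehot)
  tot <- colSums(probs) + colSums(onehot)
  dvals <- (2 * inter + eps) / (tot + eps)
  dice_loss <- 1 - mean(dvals)

  p_true <- probs[cbind(seq_len(n), labels_vec + 1L)]
  ce_loss <- -mean(log(pmax(p_true, 1e-12)))

  loss <- config$dice_weight * dice_loss + config$ce_weight * ce_loss

  # dice gradient wrt probs, then through softmax
  dprob <- -(config$dice_weight / nc) *
    sweep(2 * onehot, 2, tot + eps, `/`)
  dprob <- dprob + (config$dice_weight / nc) *
    matrix((2 * inter + eps) / (tot + eps)^2, n, nc, byrow = TRUE)
  dlog_dice <- probs * (dprob - rowSums(dprob * probs))
  dlog_ce <- config$ce_weight * (probs - onehot) / n
  list(loss = loss, dice_loss = dice_loss, ce_loss = ce_loss,
       dlogits = dlog_dice + dlog_ce)
}

# ---- optimizer -------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(P, G, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in ls(G)) {
    g <- G[[nm]]
    key_m <- paste0(nm, ".m"); key_v <- paste0(nm, ".v")
    m <- state[[key_m]]; v <- state[[key_v]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[key_m]] <- m; state[[key_v]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# ---- training --------------------------------------------------------

random_crop <- function(vol, lab, edge) {
  d <- dim(vol)
  if (all(d == edge)) return(list(volume = vol, labels = lab))
  if (any(d < edge)) stop("volume smaller than crop size", call. = FALSE)
  corner <- vapply(seq_len(3), function(ax) {
    if (d[ax] == edge) 1L else sample.int(d[ax] - edge + 1L, 1L)
  }, 1L)
  ix <- lapply(seq_len(3), function(ax) corner[ax]:(corner[ax] + edge - 1L))
  list(volume = vol[ix[[1]], ix[[2]], ix[[3]]],
       labels = lab[ix[[1]], ix[[2]], ix[[3]]])
}

#' Train the segmentation network
#'
#' Iteratively samples a (cropped, augmented) volume/label pair,
#' minimizes the combined dice + cross-entropy loss with Adam, and
#' records the loss per iteration plus the mean foreground dice on the
#' (uncropped) training volumes at a fixed cadence. Deterministic for a
#' fixed `config$seed`.
#'
#' @param model a `seg_model` from [build_model()].
#' @param dataset list of samples, each `list(volume = 3D array in
#'   [0,1], labels = 3D integer array)`; arrays may also be
#'   [scalar_volume()]s.
#' @param config a [segmentation_config()] (typically the one the model
#'   was built with).
#' @param dice_every evaluate training dice every this many iterations
#'   (0 disables tracking).
#' @return List with `model` (parameters updated in place), `loss`
#'   (numeric vector per iteration), `dice` (data.frame iteration/dice).
#' @export
train <- function(model, dataset, config = model$config, dice_every = 50) {
  stopifnot(inherits(model, "seg_model"))
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  dataset <- lapply(dataset, function(s) {
    v <- if (is_scalar_volume(s$volume)) s$volume$values else s$volume
    l <- if (is.array(s$labels)) s$labels else array(s$labels, dim(v))
    list(volume = v, labels = l)
  })
  iters <- config$iterations
  losses <- numeric(iters)
  dice_track <- list()
  if (iters == 0L) {
    return(list(model = model, loss = losses,
                dice = data.frame(iteration = integer(0), dice = numeric(0))))
  }
  state <- adam_state()
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, iters)
  for (t in seq_len(iters)) {
    set.seed(seeds[t])
    s <- dataset[[sample.int(length(dataset), 1L)]]
    s <- random_crop(s$volume, s$labels, config$crop_size)
    if (config$flip_prob > 0 || config$rotate_prob > 0 ||
        config$intensity_prob > 0) {
      s <- augment(s, config, seed = seeds[t] %% 1000000L)
    }
    fwd <- model_forward(model, s$volume, keep_cache = TRUE)
    ls_ <- seg_loss(fwd$probs, fwd$logits, as.integer(s$labels), config)
    losses[t] <- ls_$loss
    G <- new.env(parent = emptyenv())
    model_backward(model, fwd, ls_$dlogits, G)
    adam_step(model$params, G, state, config$learning_rate, t)
    if (dice_every > 0 && (t %% dice_every == 0L || t == iters)) {
      dice_track[[length(dice_track) + 1L]] <-
        data.frame(iteration = t, dice = training_dice(model, dataset))
    }
  }
  list(model = model, loss = losses,
       dice = if (length(dice_track)) do.call(rbind, dice_track) else
         data.frame(iteration = integer(0), dice = numeric(0)))
}

training_dice <- function(model, dataset) {
  mean(vapply(dataset, function(s) {
    pred <- predict_segmentation(model, s$volume)
    evaluate_segmentation(pred$labels, s$labels,
                          n_classes = model$config$n_classes)
  }, 0))
}

#' Mean foreground dice between predicted and reference labels
#'
#' Unweighted mean of the per-class dice over the foreground classes
#' (label 0 is background). A class empty in both volumes is skipped; a
#' class predicted empty against a non-empty reference scores 0.
#'
#' @param pred,truth 3D integer label arrays of identical dims, or
#'   named lists of [binary_mask()]s on a common grid.
#' @param n_classes total classes including background (ignored for
#'   mask lists).
#' @return Mean dice in `[0, 1]`.
#' @export
evaluate_segmentation <- function(pred, truth, n_classes = 6) {
  if (is.list(pred) && !is.array(pred)) {
    stopifnot(is.list(truth), length(pred) == length(truth))
    ds <- vapply(seq_along(pred), function(i) dice(pred[[i]], truth[[i]]), 0)
    return(mean(ds))
  }
  stopifnot(all(dim(pred) == dim(truth)))
  ds <- c()
  for (cl in seq_len(n_classes - 1)) {
    a <- pred == cl
    b <- truth == cl
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) next
    ds <- c(ds, 2 * sum(a & b) / (na + nb))
  }
  if (!length(ds)) 1 else mean(ds)
}

#' Build a phantom training set for the segmentation backend
#'
#' Generates `n` small CT phantoms with the five target organs
#' (distinct attenuation, jittered positions per sample), preprocesses
#' them with [preprocess_ct()], and pairs each with its integer label
#' volume (1 = right breast, 2 = left breast, 3 = liver, 4 = spleen,
#' 5 = bone marrow).
#'
#' @param n number of samples.
#' @param config a [segmentation_config()]; its `crop_size` and
#'   `target_spacing` set the phantom geometry.
#' @param seed base seed; sample `i` uses `seed + i`.
#' @param jitter_mm maximum per-axis displacement of each organ center.
#' @return List of `list(volume, labels)` samples.
#' @export
segmentation_dataset_from_phantoms <- function(n = 3, config = segmentation_config("desk"),
                                               seed = 1L, jitter_mm = 3) {
  edge <- config$crop_size
  sp <- config$target_spacing
  grid <- volume_grid(rep(edge, 3), sp)
  extent <- (rep(edge, 3) - 1) * sp
  cx <- extent / 2
  s <- min(extent) / 46
  base <- list(
    breast_right = list(c(-14, -10, 0), c(8, 7, 7), -60),
    breast_left = list(c(14, -10, 0), c(8, 7, 7), -60),
    liver = list(c(-8, 10, 8), c(10, 7, 6), 60),
    spleen = list(c(13, 10, 8), c(5.5, 5.5, 5.5), 120),
    bone_marrow = list(c(0, 10, -10), c(15, 3.5, 3.5), 220))
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    organs <- lapply(names(base), function(nm) {
      b <- base[[nm]]
      organ_spec(nm, cx + b[[1]] * s + stats::runif(3, -jitter_mm, jitter_mm),
                 b[[2]] * s, ct_value = b[[3]], suv = 1)
    })
    spec <- phantom_spec(grid, grid, organs, suv_params = default_suv_params(),
                         seed = seed + i)
    ph <- generate_phantom(spec)
    lab <- array(0L, grid$dims)
    for (k in seq_along(organs)) lab[ph$masks_ct[[k]]$voxels] <- k
    list(volume = preprocess_ct(ph$ct, config)$values, labels = lab)
  })
}

#' Threshold baseline segmenter
#'
#' A deliberately simple reference backend: assigns each foreground
#' class by nearest configured intensity among voxels above a
#' background cutoff. Useful as a sanity baseline and in tests where a
#' trained network would be overkill.
#'
#' @param volume 3D array (or [scalar_volume()]) of preprocessed
#'   intensities.
#' @param class_levels numeric vector of expected intensities for
#'   classes `1..K` (foreground).
#' @param background_below voxels at or below this intensity stay
#'   background.
#' @return 3D integer label array.
#' @export
segment_by_threshold <- function(volume, class_levels, background_below = 0) {
  if (is_scalar_volume(volume)) volume <- volume$values
  lab <- array(0L, dim(volume))
  fg <- volume > background_below
  if (any(fg)) {
    d <- abs(outer(volume[fg], class_levels, `-`))
    lab[fg] <- max.col(-d, ties.method = "first")
  }
  lab
}
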