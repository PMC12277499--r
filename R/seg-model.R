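#' Configuration for the transformer segmentation backend
#'
#' Describes a Swin-UNETR-style network and its training recipe: a
#' patch-embedding stem, repeated pairs of windowed-attention blocks
#' (W-MSA, then the shifted SW-MSA variant) with patch merging that
#' halves token resolution while doubling channels, a residual
#' convolutional decoder with instance normalization and skip
#' connections, and a 1x1x1 softmax head over the six classes
#' (background, right breast, left breast, liver, spleen, bone marrow).
#' The `"study"` preset mirrors the clinical recipe (48 features, 4
#' stages, 96 crops, 20,000 iterations); the `"desk"` preset is a small
#' configuration for CPU-scale experiments and tests.
#'
#' @param preset `"study"` or `"desk"`.
#' @param patch_size voxels per patch edge in the embedding stem.
#' @param embed_dim features per token after embedding.
#' @param n_stages number of attention+merge repetitions.
#' @param window attention window edge in tokens (capped per stage to a
#'   divisor of the token grid).
#' @param crop_size training crop edge; must be divisible by
#'   `patch_size * 2^n_stages`.
#' @param clip_range HU clipping range for CT normalization.
#' @param target_spacing mm resampling target for preprocessing.
#' @param flip_prob,rotate_prob per-axis flip / 90-degree rotation
#'   probability during augmentation.
#' @param intensity_prob,intensity_offset intensity-shift augmentation:
#'   probability and maximum absolute offset.
#' @param dice_weight,ce_weight loss mixing weights.
#' @param iterations training iterations.
#' @param learning_rate Adam step size.
#' @param n_classes output classes including background.
#' @param head_dim channels per attention head.
#' @param mlp_ratio MLP expansion factor inside attention blocks.
#' @param pos_embed add a learned absolute position embedding to the
#'   tokens (gives the network direct access to laterality).
#' @param seed RNG seed for initialization, cropping and augmentation.
#' @return A `segmentation_config`.
#' @export
segmentation_config <- function(preset = c("desk", "study"),
                                patch_size = 2,
                                embed_dim = NULL,
                                n_stages = NULL,
                                window = NULL,
                                crop_size = NULL,
                                clip_range = c(-175, 250),
                                target_spacing = NULL,
                                flip_prob = 0.1,
                                rotate_prob = 0.1,
                                intensity_prob = 0.5,
                                intensity_offset = 0.1,
                                dice_weight = 1,
                                ce_weight = 1,
                                iterations = NULL,
                                learning_rate = 3e-3,
                                n_classes = 6,
                                head_dim = NULL,
                                mlp_ratio = 2,
                                pos_embed = TRUE,
                                seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "study") {
    embed_dim <- embed_dim %||% 48
    n_stages <- n_stages %||% 4
    window <- window %||% 7
    crop_size <- crop_size %||% 96
    target_spacing <- target_spacing %||% c(1.5, 1.5, 2.0)
    iterations <- iterations %||% 20000
  } else {
    embed_dim <- embed_dim %||% 12
    n_stages <- n_stages %||% 2
    window <- window %||% 4
    crop_size <- crop_size %||% 24
    target_spacing <- target_spacing %||% c(3, 3, 3)
    iterations <- iterations %||% 300
    # desk preset favors determinism of small overfit runs
    flip_prob <- if (missing(flip_prob)) 0 else flip_prob
    rotate_prob <- if (missing(rotate_prob)) 0 else rotate_prob
    intensity_prob <- if (missing(intensity_prob)) 0 else intensity_prob
  }
  head_dim <- head_dim %||% max(4L, embed_dim %/% 3L)
  div <- patch_size * 2^n_stages
  if (crop_size %% div != 0) {
    stop(sprintf("crop_size (%d) must be divisible by patch_size * 2^n_stages (%d)",
                 crop_size, div), call. = FALSE)
  }
  if (embed_dim %% head_dim != 0) {
    stop("embed_dim must be a multiple of head_dim", call. = FALSE)
  }
  probs <- c(flip_prob, rotate_prob, intensity_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("augmentation probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(preset = preset, patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_stages = as.integer(n_stages),
                 window = as.integer(window),
                 crop_size = as.integer(crop_size),
                 clip_range = clip_range,
                 target_spacing = target_spacing,
                 flip_prob = flip_prob, rotate_prob = rotate_prob,
                 intensity_prob = intensity_prob,
                 intensity_offset = intensity_offset,
                 dice_weight = dice_weight, ce_weight = ce_weight,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 n_classes = as.integer(n_classes),
                 head_dim = as.integer(head_dim),
                 mlp_ratio = mlp_ratio,
                 pos_embed = isTRUE(pos_embed),
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

# Geometry of every stage for an input of edge `size`: token grids,
# channel counts, fitted window dims.
model_plan <- function(config, dims = rep(config$crop_size, 3)) {
  dims <- as.integer(dims)
  p <- config$patch_size
  if (any(dims %% (p * 2^config$n_stages) != 0)) {
    stop(sprintf("input dims (%s) must be divisible by patch_size * 2^n_stages (%d)",
                 paste(dims, collapse = "x"), p * 2^config$n_stages),
         call. = FALSE)
  }
  S <- config$n_stages
  tg <- vector("list", S + 1)
  ch <- integer(S + 1)
  tg[[1]] <- dims %/% p
  ch[1] <- config$embed_dim
  for (i in seq_len(S)) {
    tg[[i + 1]] <- tg[[i]] %/% 2L
    ch[i + 1] <- ch[i] * 2L
  }
  wins <- lapply(tg, function(g) {
    vapply(g, fit_window_axis, 1L, w = config$window)
  })
  list(dims = dims, token_grids = tg, channels = ch, windows = wins)
}

#' Build the segmentation network
#'
#' Instantiates all parameters of the network described by the config.
#' Initialization is deterministic for a fixed `config$seed`. The
#' returned model carries its parameters (a flat named list of arrays),
#' the stage plan, and caches of precomputed index tables.
#'
#' @param config a [segmentation_config()].
#' @return A `seg_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "segmentation_config"))
  plan <- model_plan(config)
  set.seed(config$seed)
  P <- new.env(parent = emptyenv())
  p3 <- config$patch_size^3
  S <- config$n_stages
  ch <- plan$channels

  linear_init(P, "embed", p3, ch[1])
  if (config$pos_embed) {
    nn_init_param(P, "pos.E",
                  matrix(trunc_normal(prod(plan$token_grids[[1]]) * ch[1]),
                         prod(plan$token_grids[[1]]), ch[1]))
  }
  for (i in seq_len(S)) {
    swin_block_init(P, sprintf("enc%d.a", i), ch[i], config$mlp_ratio)
    swin_block_init(P, sprintf("enc%d.b", i), ch[i], config$mlp_ratio)
    layernorm_init(P, sprintf("merge%d.ln", i), 8 * ch[i])
    linear_init(P, sprintf("merge%d.red", i), 8 * ch[i], ch[i + 1])
  }
  conv_block_init(P, "bottleneck", ch[S + 1], ch[S + 1])
  for (i in seq(S, 1)) {
    conv_block_init(P, sprintf("dec%d", i), ch[i + 1] + ch[i], ch[i])
  }
  conv_block_init(P, "enc0", 1, ch[1])
  conv_block_init(P, "dec0", 2 * ch[1], ch[1])
  linear_init(P, "head", ch[1], config$n_classes)

  structure(list(config = config, plan = plan, params = P,
                 index_cache = new.env(parent = emptyenv())),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  n <- sum(vapply(ls(x$params), function(nm) length(x$params[[nm]]), 0))
  cat(sprintf(paste0("seg_model: %d stages, embed %d, crop %d^3, ",
                     "%d classes, %s parameters\n"),
              x$config$n_stages, x$config$embed_dim, x$config$crop_size,
              x$config$n_classes, format(n, big.mark = ",")))
  invisible(x)
}

# Cached index tables for a given input size.
model_indices <- function(model, dims) {
  key <- paste(dims, collapse = "x")
  env <- model$index_cache
  if (!is.null(env[[key]])) return(env[[key]])
  plan <- model_plan(model$config, dims)
  S <- model$config$n_stages
  idx <- list(
    plan = plan,
    embed_gidx = make_group_index(plan$dims, model$config$patch_size),
    merge_gidx = lapply(seq_len(S), function(i) {
      make_group_index(plan$token_grids[[i]], 2L)
    }),
    wins = lapply(seq_len(S), function(i) {
      tg <- plan$token_grids[[i]]
      w <- plan$windows[[i]]
      list(plain = make_window_index(tg, w),
           shifted = make_window_index(tg, w, shift = w %/% 2L))
    }),
    shifts = lapply(seq_len(S + 1), function(i) {
      make_shift_index(plan$token_grids[[i]])
    }),
    shifts_full = make_shift_index(plan$dims),
    up_parent = lapply(seq_len(S), function(i) {
      # child (finer) token -> parent (coarser) token, for upsampling
      tgf <- plan$token_grids[[i]]
      co <- (arrayInd(seq_len(prod(tgf)), tgf) - 1L) %/% 2L
      tgc <- plan$token_grids[[i + 1]]
      1L + co[, 1] + tgc[1] * (co[, 2] + tgc[2] * co[, 3])
    }),
    up0_parent = {
      co <- (arrayInd(seq_len(prod(plan$dims)), plan$dims) - 1L) %/%
        as.integer(model$config$patch_size)
      tg0 <- plan$token_grids[[1]]
      1L + co[, 1] + tg0[1] * (co[, 2] + tg0[2] * co[, 3])
    })
  env[[key]] <- idx
  idx
}

# Resize the learned position embedding to another token grid
# (nearest-neighbor in token space), for inference on sizes other than
# the training crop.
resize_pos_embed <- function(E, from_tg, to_tg) {
  if (identical(from_tg, to_tg)) return(E)
  co <- arrayInd(seq_len(prod(to_tg)), to_tg) - 1L
  src <- sweep(co, 2, (from_tg - 1) / pmax(to_tg - 1, 1), `*`)
  src <- round(src)
  lin <- 1 + src[, 1] + from_tg[1] * (src[, 2] + from_tg[2] * src[, 3])
  E[lin, , drop = FALSE]
}

# Full forward pass. `x` is a 3D array. Returns per-voxel class
# probabilities (n_voxels x n_classes, array order) and, when
# keep_cache, everything backward needs.
model_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  P <- model$params
  dims <- dim(x)
  ix <- model_indices(model, dims)
  plan <- ix$plan
  S <- cfg$n_stages
  cache <- list(dims = dims)

  xv <- matrix(as.numeric(x), ncol = 1)

  # stem: patch embedding (+ position embedding)
  wide <- group_gather(xv, ix$embed_gidx)
  emb <- linear_fwd(P, "embed", wide)
  tok <- emb$out
  if (cfg$pos_embed) {
    E <- resize_pos_embed(P[["pos.E"]],
                          model$plan$token_grids[[1]],
                          plan$token_grids[[1]])
    tok <- tok + E
  }
  cache$embed <- emb$cache

  skips <- vector("list", S)
  enc_caches <- vector("list", S)
  merge_caches <- vector("list", S)
  for (i in seq_len(S)) {
    a <- swin_block_fwd(P, sprintf("enc%d.a", i), tok, ix$wins[[i]]$plain,
                        plan$channels[i] %/% cfg$head_dim)
    b <- swin_block_fwd(P, sprintf("enc%d.b", i), a$out,
                        ix$wins[[i]]$shifted,
                        plan$channels[i] %/% cfg$head_dim)
    skips[[i]] <- b$out
    wide <- group_gather(b$out, ix$merge_gidx[[i]])
    ln <- layernorm_fwd(P, sprintf("merge%d.ln", i), wide)
    red <- linear_fwd(P, sprintf("merge%d.red", i), ln$out)
    tok <- red$out
    enc_caches[[i]] <- list(a = a$cache, b = b$cache)
    merge_caches[[i]] <- list(ln = ln$cache, red = red$cache,
                              n = nrow(b$out), C = ncol(b$out))
  }
  cache$enc <- enc_caches
  cache$merge <- merge_caches

  bn <- conv_block_fwd(P, "bottleneck", tok, ix$shifts[[S + 1]])
  cache$bn <- bn$cache
  feat <- bn$out

  dec_caches <- vector("list", S)
  for (i in seq(S, 1)) {
    up <- feat[ix$up_parent[[i]], , drop = FALSE]
    cat_in <- cbind(up, skips[[i]])
    dc <- conv_block_fwd(P, sprintf("dec%d", i), cat_in, ix$shifts[[i]])
    dec_caches[[i]] <- list(conv = dc$cache, up_cols = ncol(up))
    feat <- dc$out
  }
  cache$dec <- dec_caches

  e0 <- conv_block_fwd(P, "enc0", xv, ix$shifts_full)
  cache$enc0 <- e0$cache
  up0 <- feat[ix$up0_parent, , drop = FALSE]
  cat0 <- cbind(up0, e0$out)
  d0 <- conv_block_fwd(P, "dec0", cat0, ix$shifts_full)
  cache$dec0 <- list(conv = d0$cache, up_cols = ncol(up0))
  hd <- linear_fwd(P, "head", d0$out)
  cache$head <- hd$cache
  probs <- softmax_rows(hd$out)

  list(probs = probs, logits = hd$out,
       cache = if (keep_cache) cache else NULL, indices = ix)
}

# Backward pass from dL/dlogits; accumulates gradients into env G.
model_backward <- function(model, fwd, dlogits, G) {
  cfg <- model$config
  P <- model$params
  ix <- fwd$indices
  plan <- ix$plan
  S <- cfg$n_stages
  cache <- fwd$cache

  dfeat <- linear_bwd(P, G, "head", cache$head, dlogits)
  dcat0 <- conv_block_bwd(P, G, "dec0", cache$dec0$conv, dfeat,
                          ix$shifts_full)
  k0 <- cache$dec0$up_cols
  dup0 <- dcat0[, seq_len(k0), drop = FALSE]
  de0 <- dcat0[, (k0 + 1):ncol(dcat0), drop = FALSE]
  dxv <- conv_block_bwd(P, G, "enc0", cache$enc0, de0, ix$shifts_full)
  dfeat <- rowsum(dup0, ix$up0_parent)

  dskips <- vector("list", S)
  for (i in seq(1, S)) {
    dc <- conv_block_bwd(P, G, sprintf("dec%d", i), cache$dec[[i]]$conv,
                         dfeat, ix$shifts[[i]])
    k <- cache$dec[[i]]$up_cols
    dup <- dc[, seq_len(k), drop = FALSE]
    dskips[[i]] <- dc[, (k + 1):ncol(dc), drop = FALSE]
    dfeat <- rowsum(dup, ix$up_parent[[i]])
  }

  dtok <- conv_block_bwd(P, G, "bottleneck", cache$bn, dfeat,
                         ix$shifts[[S + 1]])

  for (i in seq(S, 1)) {
    mc <- cache$merge[[i]]
    dred <- linear_bwd(P, G, sprintf("merge%d.red", i), mc$red, dtok)
    dwide <- layernorm_bwd(P, G, sprintf("merge%d.ln", i), mc$ln, dred)
    db_out <- group_scatter(dwide, ix$merge_gidx[[i]], mc$n, mc$C) +
      dskips[[i]]
    da_out <- swin_block_bwd(P, G, sprintf("enc%d.b", i),
                             cache$enc[[i]]$b, db_out)
    dtok <- swin_block_bwd(P, G, sprintf("enc%d.a", i),
                           cache$enc[[i]]$a, da_out)
  }

  if (cfg$pos_embed &&
      identical(plan$token_grids[[1]], model$plan$token_grids[[1]])) {
    nn_grad_add(G, "pos.E", dtok)
  }
  dwide <- linear_bwd(P, G, "embed", cache$embed, dtok)
  invisible(NULL)
}

#' Predict per-voxel class probabilities
#'
#' Runs the network on a full volume (dims must be divisible by
#' `patch_size * 2^n_stages`; pad beforehand otherwise).
#'
#' @param model a `seg_model`.
#' @param x 3D array (preprocessed intensities in `[0, 1]`) or a
#'   [scalar_volume()].
#' @return List with `probs` (4D array `dims x n_classes`) and `labels`
#'   (3D integer array of argmax classes, 0 = background).
#' @export
predict_segmentation <- function(model, x) {
  if (is_scalar_volume(x)) x <- x$values
  fwd <- model_forward(model, x)
  dims <- dim(x)
  nc <- model$config$n_classes
  labels <- array(max.col(fwd$probs, ties.method = "first") - 1L, dims)
  list(probs = array(fwd$probs, c(dims, nc)), labels = labels)
}
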