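#' Architecture specification for the binary classifiers
#'
#' Two variants are provided.  `"basic_cnn"` is four blocks of
#' convolution (3x3, same padding), batch normalization, ReLU and 2x2
#' max-pooling, emitting 16/32/64/128 feature maps, followed by three fully
#' connected layers (flatten -> 1024 -> 32 -> 2) with 0.25 dropout and ReLU
#' between them and a softmax head.  Because convolutions preserve spatial
#' size, only the pools shrink the grid (floor division per axis), so a
#' 1024 x 428 input reaches the first fully connected layer with
#' 128 x 26 x 64 = 212,992 features.
#'
#' `"dla"` is a deep-layer-aggregation style network: a three-block stem
#' (16/32/32 maps, no pooling), then four tree stages (64/128/256/512 maps),
#' each downsampling by 2 and aggregating two stacked blocks through a
#' concatenation node with a residual skip, then average pooling and two
#' fully connected layers (-> 32 -> 2) with dropout.  By default the average
#' pool is global (adaptive to any input size); a fixed 4x4-kernel average
#' pool is available via `dla_pool = "kernel4"`.
#'
#' @param variant `"basic_cnn"` or `"dla"`.
#' @param input_size `c(width, height)` in pixels.  Defaults: 1024 x 428 for
#'   the basic CNN, 512 x 214 for the DLA.
#' @param conv_channels feature maps per basic-CNN block.
#' @param stem_channels,tree_channels DLA stem / tree-stage feature maps.
#' @param fc_hidden hidden fully connected widths (the final 2-way layer is
#'   implied).
#' @param dropout_p dropout probability.
#' @param dla_pool `"global"` (adaptive average pool) or `"kernel4"` (4x4
#'   average pool, floor).
#' @param n_classes number of classes (2).
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(variant = c("basic_cnn", "dla"),
                              input_size = NULL,
                              conv_channels = c(16L, 32L, 64L, 128L),
                              stem_channels = c(16L, 32L, 32L),
                              tree_channels = c(64L, 128L, 256L, 512L),
                              fc_hidden = NULL,
                              dropout_p = 0.25,
                              dla_pool = c("global", "kernel4"),
                              n_classes = 2L) {
  variant <- match.arg(variant)
  dla_pool <- match.arg(dla_pool)
  if (is.null(input_size)) {
    input_size <- if (variant == "basic_cnn") c(1024L, 428L) else c(512L, 214L)
  }
  if (is.null(fc_hidden)) {
    fc_hidden <- if (variant == "basic_cnn") c(1024L, 32L) else 32L
  }
  structure(list(variant = variant,
                 input_size = as.integer(input_size),
                 conv_channels = as.integer(conv_channels),
                 stem_channels = as.integer(stem_channels),
                 tree_channels = as.integer(tree_channels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_p = dropout_p,
                 dla_pool = dla_pool,
                 n_classes = as.integer(n_classes)),
            class = "architecture_spec")
}

#' Number of features entering the first fully connected layer
#'
#' Pure arithmetic, no model instantiation: convolutions preserve spatial
#' size (same padding), every 2x2 max-pool (and each DLA tree stage) halves
#' each axis with floor, and the DLA's global average pool collapses the
#' grid to 1x1.
#'
#' @param spec an [architecture_spec()].
#' @param input_size `c(width, height)`; defaults to the spec's input size.
#' @return integer feature count.
#' @examples
#' flattened_dim(architecture_spec("basic_cnn"))  # 212992 = 128 * 26 * 64
#' @export
flattened_dim <- function(spec, input_size = spec$input_size) {
  w <- as.integer(input_size[1]); h <- as.integer(input_size[2])
  if (spec$variant == "basic_cnn") {
    for (i in seq_along(spec$conv_channels)) {
      w <- w %/% 2L; h <- h %/% 2L
      if (w < 1L || h < 1L) {
        stop("pooling chain collapses a spatial dimension to 0", call. = FALSE)
      }
    }
    return(tail(spec$conv_channels, 1) * w * h)
  }
  # dla: stem keeps size, each tree stage halves
  for (i in seq_along(spec$tree_channels)) {
    w <- w %/% 2L; h <- h %/% 2L
    if (w < 1L || h < 1L) {
      stop("tree-stage downsampling collapses a spatial dimension to 0",
           call. = FALSE)
    }
  }
  if (spec$dla_pool == "global") {
    tail(spec$tree_channels, 1)
  } else {
    w <- w %/% 4L; h <- h %/% 4L
    if (w < 1L || h < 1L) {
      stop("4x4 average pool collapses a spatial dimension to 0", call. = FALSE)
    }
    tail(spec$tree_channels, 1) * w * h
  }
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_conv_params <- function(cin, cout) {
  list(w = he_init(c(3, 3, cin, cout), 9 * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rmean = numeric(cout), rvar = rep(1, cout))
}

new_fc_params <- function(din, dout) {
  list(w = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

#' Build a classifier model
#'
#' Instantiates the parameters of an [architecture_spec()] (He-normal
#' initialization).  The returned model accepts batches shaped
#' `(height, width, 3, n)` at the spec's input size.
#'
#' @param spec an [architecture_spec()].
#' @param seed optional seed for reproducible initialization.
#' @param preprocess optional [preprocess_config()] remembered by the model
#'   and applied by [classify()].
#' @return an object of class `tv_model`.
#' @export
build_model <- function(spec, seed = NULL, preprocess = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  flattened_dim(spec)  # errors if the pooling chain collapses
  make <- function() {
    params <- list()
    if (spec$variant == "basic_cnn") {
      cin <- 3L
      for (i in seq_along(spec$conv_channels)) {
        params[[paste0("conv", i)]] <- new_conv_params(cin, spec$conv_channels[i])
        cin <- spec$conv_channels[i]
      }
    } else {
      cin <- 3L
      for (i in seq_along(spec$stem_channels)) {
        params[[paste0("stem", i)]] <- new_conv_params(cin, spec$stem_channels[i])
        cin <- spec$stem_channels[i]
      }
      for (i in seq_along(spec$tree_channels)) {
        oc <- spec$tree_channels[i]
        params[[paste0("tree", i, "_b1")]] <- new_conv_params(cin, oc)
        params[[paste0("tree", i, "_b2")]] <- new_conv_params(oc, oc)
        params[[paste0("tree", i, "_root")]] <- new_conv_params(2L * oc, oc)
        cin <- oc
      }
    }
    din <- flattened_dim(spec)
    widths <- c(spec$fc_hidden, spec$n_classes)
    for (i in seq_along(widths)) {
      params[[paste0("fc", i)]] <- new_fc_params(din, widths[i])
      din <- widths[i]
    }
    params
  }
  params <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(list(spec = spec, params = params, preprocess = preprocess),
            class = "tv_model")
}

#' @export
print.tv_model <- function(x, ...) {
  n_par <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf("<tv_model> %s, input %d x %d, %s parameters\n",
              x$spec$variant, x$spec$input_size[1], x$spec$input_size[2],
              format(n_par, big.mark = ",")))
  invisible(x)
}

relu <- function(x) x * (x > 0)

# conv -> batchnorm+relu (fused) -> optional 2x2 max-pool; returns output and
# the cache needed for the backward pass.
cbr_fwd <- function(x, p, training, pool = FALSE) {
  z <- cv_conv3_fwd(x, p$w, p$b)
  bn <- cv_bn_fwd(z, p$gamma, p$beta, p$rmean, p$rvar, 0.1, 1e-5, training,
                  TRUE)
  a <- bn$y
  cache <- list(x = x, xhat = bn$xhat, invstd = bn$invstd)
  if (pool) {
    mp <- cv_maxpool2_fwd(a)
    cache$pool_idx <- mp$idx
    cache$pre_pool_dim <- dim(a)
    a <- mp$y
  }
  list(a = a, cache = cache, rmean = bn$rmean, rvar = bn$rvar)
}

cbr_bwd <- function(da, p, cache, need_dx = TRUE) {
  if (!is.null(cache$pool_idx)) {
    da <- cv_maxpool2_bwd(da, cache$pool_idx, cache$pre_pool_dim)
  }
  bn <- cv_bn_relu_bwd(da, cache$xhat, p$gamma, p$beta, cache$invstd)
  cv <- cv_conv3_bwd(cache$x, p$w, bn$dx, need_dx)
  list(dx = if (need_dx) cv$dx else NULL,
       grads = list(w = cv$dw, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta))
}

dropout_mask <- function(dims, p, training) {
  if (!training || p <= 0) return(NULL)
  array((runif(prod(dims)) >= p) / (1 - p), dims)
}

# Full forward pass.  Returns class probabilities (n x n_classes), logits
# and, when `keep_cache`, everything needed by model_backward().  Dropout
# masks are drawn from the current RNG when training.
model_forward <- function(model, x, training = FALSE, keep_cache = training) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != spec$input_size[2] || d[2] != spec$input_size[1] || d[3] != 3) {
    stop(sprintf("input must be %d x %d x 3, got %d x %d x %d",
                 spec$input_size[2], spec$input_size[1], d[1], d[2], d[3]),
         call. = FALSE)
  }
  n <- d[4]
  caches <- list()
  state_updates <- list()

  if (spec$variant == "basic_cnn") {
    a <- x
    for (i in seq_along(spec$conv_channels)) {
      nm <- paste0("conv", i)
      r <- cbr_fwd(a, model$params[[nm]], training, pool = TRUE)
      a <- r$a
      if (keep_cache) caches[[nm]] <- r$cache
      if (training) state_updates[[nm]] <- list(rmean = r$rmean, rvar = r$rvar)
    }
  } else {
    a <- x
    for (i in seq_along(spec$stem_channels)) {
      nm <- paste0("stem", i)
      r <- cbr_fwd(a, model$params[[nm]], training, pool = FALSE)
      a <- r$a
      if (keep_cache) caches[[nm]] <- r$cache
      if (training) state_updates[[nm]] <- list(rmean = r$rmean, rvar = r$rvar)
    }
    for (i in seq_along(spec$tree_channels)) {
      nm <- paste0("tree", i)
      mp <- cv_maxpool2_fwd(a)
      down <- mp$y
      r1 <- cbr_fwd(down, model$params[[paste0(nm, "_b1")]], training)
      r2 <- cbr_fwd(r1$a, model$params[[paste0(nm, "_b2")]], training)
      cat_a <- abind2(r1$a, r2$a)
      zr <- cv_conv3_fwd(cat_a, model$params[[paste0(nm, "_root")]]$w,
                         model$params[[paste0(nm, "_root")]]$b)
      pr <- model$params[[paste0(nm, "_root")]]
      bnr <- cv_bn_fwd(zr, pr$gamma, pr$beta, pr$rmean, pr$rvar, 0.1, 1e-5, training)
      s <- bnr$y + r1$a   # residual aggregation
      a_out <- relu(s)
      if (keep_cache) {
        caches[[nm]] <- list(pool_idx = mp$idx, pre_pool_dim = dim(a),
                             c1 = r1$cache, c2 = r2$cache,
                             cat_x = cat_a,
                             root = list(xhat = bnr$xhat, invstd = bnr$invstd),
                             mask = s > 0, oc = spec$tree_channels[i])
      }
      if (training) {
        state_updates[[paste0(nm, "_b1")]] <- list(rmean = r1$rmean, rvar = r1$rvar)
        state_updates[[paste0(nm, "_b2")]] <- list(rmean = r2$rmean, rvar = r2$rvar)
        state_updates[[paste0(nm, "_root")]] <- list(rmean = bnr$rmean, rvar = bnr$rvar)
      }
      a <- a_out
    }
    if (spec$dla_pool == "kernel4") {
      if (keep_cache) caches$avgpool <- dim(a)
      a <- cv_avgpool_fwd(a, 4L)
    } else {
      if (keep_cache) caches$gap_dim <- dim(a)
      da <- dim(a)
      a <- array(colMeans(matrix(a, da[1] * da[2], da[3] * da[4])),
                 c(1L, 1L, da[3], da[4]))
    }
  }

  # flatten: (H, W, C, N) -> n x D, feature order h-fastest
  flat_dim <- dim(a)
  flat <- t(matrix(a, ncol = n))
  caches$flat_dim <- flat_dim

  widths <- c(spec$fc_hidden, spec$n_classes)
  h <- flat
  for (i in seq_along(widths)) {
    nm <- paste0("fc", i)
    p <- model$params[[nm]]
    z <- sweep(h %*% p$w, 2, p$b, "+")
    if (i < length(widths)) {
      m <- dropout_mask(dim(z), spec$dropout_p, training)
      dz <- if (is.null(m)) z else z * m
      a_fc <- relu(dz)
      if (keep_cache) {
        caches[[nm]] <- list(x = h, drop = m, mask = dz > 0)
      }
      h <- a_fc
    } else {
      if (keep_cache) caches[[nm]] <- list(x = h)
      h <- z
    }
  }
  logits <- h
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  colnames(probs) <- CLASS_LEVELS[seq_len(spec$n_classes)]
  list(probs = probs, logits = logits, caches = if (keep_cache) caches else NULL,
       state_updates = state_updates)
}

# concatenate two (H, W, C, N) arrays along the channel axis
abind2 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backward pass from dlogits (n x n_classes); returns gradients named like
# model$params.
model_backward <- function(model, dlogits, caches) {
  spec <- model$spec
  grads <- list()
  widths <- c(spec$fc_hidden, spec$n_classes)
  dh <- dlogits
  for (i in rev(seq_along(widths))) {
    nm <- paste0("fc", i)
    p <- model$params[[nm]]
    cc <- caches[[nm]]
    if (i < length(widths)) {
      dh <- dh * cc$mask
      if (!is.null(cc$drop)) dh <- dh * cc$drop
    }
    grads[[nm]] <- list(w = crossprod(cc$x, dh), b = colSums(dh))
    dh <- tcrossprod(dh, p$w)
  }
  dflat <- array(t(dh), caches$flat_dim)

  if (spec$variant == "basic_cnn") {
    da <- dflat
    for (i in rev(seq_along(spec$conv_channels))) {
      nm <- paste0("conv", i)
      r <- cbr_bwd(da, model$params[[nm]], caches[[nm]], need_dx = i > 1)
      grads[[nm]] <- r$grads
      da <- r$dx
    }
    return(grads)
  }

  # dla
  da <- dflat
  if (spec$dla_pool == "kernel4") {
    da <- cv_avgpool_bwd(da, 4L, caches$avgpool)
  } else {
    gd <- caches$gap_dim
    plane <- gd[1] * gd[2]
    da <- array(rep(as.vector(da), each = plane) / plane, gd)
  }
  for (i in rev(seq_along(spec$tree_channels))) {
    nm <- paste0("tree", i)
    cc <- caches[[nm]]
    pr <- model$params[[paste0(nm, "_root")]]
    ds <- da * cc$mask
    bnr <- cv_bn_bwd(ds, cc$root$xhat, pr$gamma, cc$root$invstd)
    cvr <- cv_conv3_bwd(cc$cat_x, pr$w, bnr$dx)
    grads[[paste0(nm, "_root")]] <- list(w = cvr$dw, b = cvr$db,
                                         gamma = bnr$dgamma, beta = bnr$dbeta)
    oc <- cc$oc
    db1 <- cvr$dx[, , seq_len(oc), , drop = FALSE] + ds   # concat + residual
    db2 <- cvr$dx[, , oc + seq_len(oc), , drop = FALSE]
    r2 <- cbr_bwd(db2, model$params[[paste0(nm, "_b2")]], cc$c2)
    grads[[paste0(nm, "_b2")]] <- r2$grads
    db1 <- db1 + r2$dx
    r1 <- cbr_bwd(db1, model$params[[paste0(nm, "_b1")]], cc$c1)
    grads[[paste0(nm, "_b1")]] <- r1$grads
    da <- cv_maxpool2_bwd(r1$dx, cc$pool_idx, cc$pre_pool_dim)
  }
  for (i in rev(seq_along(spec$stem_channels))) {
    nm <- paste0("stem", i)
    r <- cbr_bwd(da, model$params[[nm]], caches[[nm]], need_dx = i > 1)
    grads[[nm]] <- r$grads
    da <- r$dx
  }
  grads
}

# apply batchnorm running-stat updates recorded during a training forward pass
apply_state_updates <- function(model, updates) {
  for (nm in names(updates)) {
    model$params[[nm]]$rmean <- updates[[nm]]$rmean
    model$params[[nm]]$rvar <- updates[[nm]]$rvar
  }
  model
}
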