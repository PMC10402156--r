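#' Channel configuration presets
#'
#' Layer widths are not constrained by the published architecture text (only
#' the block counts and the overall length reductions are), so they are
#' configuration. `"full"` is sized for genome-scale training, `"mini"` for
#' the miniature desk-scale geometry.
#'
#' @param preset `"full"` or `"mini"`.
#' @return list of channel settings.
#' @export
model_channels <- function(preset = c("full", "mini")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(fe1 = c(rep(16L, 3), rep(32L, 6), rep(64L, 6)),
         fe1_kernel = 5L, conv2d = c(32L, 32L, 16L), conv2d_kernel = 3L,
         d1 = 32L, fe2_width = 32L, fe2_kernel = 5L, d2 = 16L,
         pool_type = "max", head_norm = TRUE)
  } else {
    list(fe1 = c(rep(8L, 3), rep(12L, 6), rep(16L, 6)),
         fe1_kernel = 5L, conv2d = c(16L, 16L, 8L), conv2d_kernel = 3L,
         d1 = 16L, fe2_width = 12L, fe2_kernel = 5L, d2 = 8L,
         pool_type = "max", head_norm = TRUE)
  }
}

#' Construct the V-stripe prediction model
#'
#' The network has two feature extractors and a linear predictor. Feature
#' extractor 1 maps the 2-channel accessibility + CTCF window (50bp bins)
#' through fifteen conv1d/norm/ReLU blocks with interleaved average pooling
#' (total reduction 200x, to contact-bin resolution), lifts the result to a
#' pairwise tensor by outer-concatenation, adds an outer-concatenated
#' average-pooled copy of the raw input as a skip connection, applies three
#' conv2d layers, extracts the center row (all pairs involving the center
#' bin) and a linear layer. Feature extractor 2 maps the co-accessibility
#' slice (center 500bp bins as channels) through three conv1d layers, two
#' residual blocks and three more conv1d layers, pools to contact-bin
#' resolution, keeps the right half and applies a linear layer. The final
#' linear predictor consumes the concatenated features; a dummy linear head
#' on feature extractor 1 alone is used during stage-1 training.
#'
#' Normalization uses per-example statistics (batch statistics at batch size
#' one), which keeps inference deterministic and independent of batch
#' composition.
#'
#' @param geometry a [model_geometry()].
#' @param channels a [model_channels()] list; default chosen from the
#'   geometry size.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `chromafold_model`.
#' @export
chromafold_model <- function(geometry, channels = NULL, seed = 1L) {
  if (is.null(channels))
    channels <- model_channels(if (geometry$hic_window_bins >= 200) "full"
                               else "mini")
  ch <- channels
  n_blocks <- length(ch$fe1)
  if (n_blocks != 15L)
    stop("feature extractor 1 uses fifteen conv blocks; got ", n_blocks)
  p <- list()
  withr_seed(seed, {
    k <- ch$fe1_kernel
    for (i in seq_len(n_blocks)) {
      cin <- if (i == 1) 2L else ch$fe1[i - 1]
      p[[paste0("fe1.conv.", i, ".W")]] <- he_init(k * cin, ch$fe1[i], k * cin)
      p[[paste0("fe1.conv.", i, ".b")]] <- numeric(ch$fe1[i])
      p[[paste0("fe1.bn.", i, ".gamma")]] <- rep(1, ch$fe1[i])
      p[[paste0("fe1.bn.", i, ".beta")]] <- numeric(ch$fe1[i])
    }
    k2 <- ch$conv2d_kernel
    for (j in seq_along(ch$conv2d)) {
      cin <- if (j == 1) 2L * ch$fe1[n_blocks] + 4L else ch$conv2d[j - 1]
      p[[paste0("fe1.c2d.", j, ".W")]] <- he_init(k2^2 * cin, ch$conv2d[j],
                                                   k2^2 * cin)
      p[[paste0("fe1.c2d.", j, ".b")]] <- numeric(ch$conv2d[j])
    }
    c2out <- ch$conv2d[length(ch$conv2d)]
    p[["fe1.lin.W"]] <- he_init(c2out, ch$d1, c2out)
    p[["fe1.lin.b"]] <- numeric(ch$d1)
    p[["fe1.pn.gamma"]] <- rep(1, ch$d1)
    p[["fe1.pn.beta"]] <- numeric(ch$d1)
    kf <- ch$fe2_kernel; w2 <- ch$fe2_width
    for (i in 1:6) {
      cin <- if (i == 1) geometry$center_coacc_bins else w2
      p[[paste0("fe2.conv.", i, ".W")]] <- he_init(kf * cin, w2, kf * cin)
      p[[paste0("fe2.conv.", i, ".b")]] <- numeric(w2)
      p[[paste0("fe2.bn.", i, ".gamma")]] <- rep(1, w2)
      p[[paste0("fe2.bn.", i, ".beta")]] <- numeric(w2)
    }
    for (r in 1:2) for (s in c("a", "b")) {
      p[[paste0("fe2.res.", r, ".", s, ".W")]] <- he_init(kf * w2, w2, kf * w2)
      p[[paste0("fe2.res.", r, ".", s, ".b")]] <- numeric(w2)
      p[[paste0("fe2.rbn.", r, ".", s, ".gamma")]] <- rep(1, w2)
      p[[paste0("fe2.rbn.", r, ".", s, ".beta")]] <- numeric(w2)
    }
    p[["fe2.lin.W"]] <- he_init(w2, ch$d2, w2)
    p[["fe2.lin.b"]] <- numeric(ch$d2)
    p[["fe2.pn.gamma"]] <- rep(1, ch$d2)
    p[["fe2.pn.beta"]] <- numeric(ch$d2)
    p[["head.dummy.W"]] <- he_init(ch$d1, 1L, ch$d1)
    p[["head.dummy.b"]] <- numeric(1)
    p[["head.final.W"]] <- he_init(ch$d1 + ch$d2, 1L, ch$d1 + ch$d2)
    p[["head.final.b"]] <- numeric(1)
  })
  structure(list(geometry = geometry, channels = ch, params = p,
                 n_params = sum(vapply(p, length, 1L)),
                 trained_stages = character()),
            class = "chromafold_model")
}

#' @export
print.chromafold_model <- function(x, ...) {
  cat("chromafold_model:", x$n_params, "parameters; window",
      x$geometry$hic_window_bins, "bins; stripe", x$geometry$out_len,
      "; trained:", if (length(x$trained_stages))
        paste(x$trained_stages, collapse = ",") else "none", "\n")
  invisible(x)
}

# ---- feature extractor 1 ----------------------------------------------------

fe1_forward <- function(model, acc_ctcf, keep_cache = FALSE) {
  g <- model$geometry; ch <- model$channels; p <- model$params
  k <- ch$fe1_kernel
  pools <- g$pool_after
  h <- acc_ctcf
  caches <- list(blocks = vector("list", length(ch$fe1)))
  for (i in seq_along(ch$fe1)) {
    cv <- conv1d_fwd(h, p[[paste0("fe1.conv.", i, ".W")]],
                     p[[paste0("fe1.conv.", i, ".b")]], k)
    no <- inorm_fwd(cv$y, p[[paste0("fe1.bn.", i, ".gamma")]],
                    p[[paste0("fe1.bn.", i, ".beta")]])
    rl <- relu_fwd(no$y)
    h <- rl$y
    pool_cache <- NULL
    w <- which(pools == i)
    if (length(w)) {
      pl <- pool1d_fwd(h, g$pool_schedule[w[1]],
                       if (is.null(ch$pool_type)) "avg" else ch$pool_type)
      h <- pl$y
      pool_cache <- pl$cache
    }
    if (keep_cache)
      caches$blocks[[i]] <- list(conv = cv$cache, norm = no$cache,
                                 relu = rl$cache, pool = pool_cache)
  }
  L <- nrow(h)  # hic_window_bins
  P <- outer_concat(h)
  skip <- avgpool1d_fwd(acc_ctcf, g$reduction_factor)
  S <- outer_concat(skip$y)
  Tt <- array(c(P, S), c(L, L, dim(P)[3] + dim(S)[3]))
  caches$n_pair_channels <- dim(P)[3]
  t2 <- Tt
  caches$c2d <- vector("list", length(ch$conv2d))
  for (j in seq_along(ch$conv2d)) {
    cv <- conv2d_fwd(t2, p[[paste0("fe1.c2d.", j, ".W")]],
                     p[[paste0("fe1.c2d.", j, ".b")]], ch$conv2d_kernel)
    rl <- relu_fwd(cv$y)
    t2 <- rl$y
    if (keep_cache) caches$c2d[[j]] <- list(conv = cv$cache, relu = rl$cache)
  }
  center <- g$max_distance_bins + 1L
  R <- matrix(t2[center, , ], nrow = L)
  lin <- linear_fwd(R, p[["fe1.lin.W"]], p[["fe1.lin.b"]])
  pn <- if (isTRUE(ch$head_norm))
    inorm_fwd(lin$y, p[["fe1.pn.gamma"]], p[["fe1.pn.beta"]])
  else list(y = lin$y, cache = NULL)
  if (keep_cache) {
    caches$lin <- lin$cache
    caches$pn <- pn$cache
    caches$L <- L
    caches$center <- center
    caches$c2d_out_channels <- dim(t2)[3]
  }
  list(F1 = pn$y, cache = if (keep_cache) caches else NULL)
}

fe1_backward <- function(model, dF1, cache) {
  g <- model$geometry; ch <- model$channels; p <- model$params
  grads <- list()
  if (!is.null(cache$pn)) {
    pb <- inorm_bwd(dF1, cache$pn)
    grads[["fe1.pn.gamma"]] <- pb$dgamma; grads[["fe1.pn.beta"]] <- pb$dbeta
    dF1 <- pb$dx
  }
  lb <- linear_bwd(dF1, p[["fe1.lin.W"]], cache$lin)
  grads[["fe1.lin.W"]] <- lb$dW; grads[["fe1.lin.b"]] <- lb$db
  L <- cache$L
  dT2 <- array(0, c(L, L, cache$c2d_out_channels))
  dT2[cache$center, , ] <- lb$dx
  for (j in rev(seq_along(ch$conv2d))) {
    dT2 <- relu_bwd(dT2, cache$c2d[[j]]$relu)
    cb <- conv2d_bwd(dT2, p[[paste0("fe1.c2d.", j, ".W")]],
                     cache$c2d[[j]]$conv)
    grads[[paste0("fe1.c2d.", j, ".W")]] <- cb$dW
    grads[[paste0("fe1.c2d.", j, ".b")]] <- cb$db
    dT2 <- cb$dx
  }
  nP <- cache$n_pair_channels
  dP <- dT2[, , seq_len(nP), drop = FALSE]  # skip path carries no parameters
  dh <- outer_concat_bwd(dP)
  pools <- g$pool_after
  for (i in rev(seq_along(ch$fe1))) {
    blk <- cache$blocks[[i]]
    if (!is.null(blk$pool)) dh <- pool1d_bwd(dh, blk$pool)
    dh <- relu_bwd(dh, blk$relu)
    nb <- inorm_bwd(dh, blk$norm)
    grads[[paste0("fe1.bn.", i, ".gamma")]] <- nb$dgamma
    grads[[paste0("fe1.bn.", i, ".beta")]] <- nb$dbeta
    cb <- conv1d_bwd(nb$dx, p[[paste0("fe1.conv.", i, ".W")]], blk$conv)
    grads[[paste0("fe1.conv.", i, ".W")]] <- cb$dW
    grads[[paste0("fe1.conv.", i, ".b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

# ---- feature extractor 2 ----------------------------------------------------

fe2_forward <- function(model, coacc, keep_cache = FALSE) {
  g <- model$geometry; ch <- model$channels; p <- model$params
  kf <- ch$fe2_kernel
  x <- t(coacc)  # positions x center-bin channels
  caches <- list()
  h <- x
  conv_block <- function(h, nm, bn) {
    cv <- conv1d_fwd(h, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]], kf)
    no <- inorm_fwd(cv$y, p[[paste0(bn, ".gamma")]], p[[paste0(bn, ".beta")]])
    rl <- relu_fwd(no$y)
    list(y = rl$y, cache = list(conv = cv$cache, norm = no$cache,
                                relu = rl$cache))
  }
  for (i in 1:3) {
    b <- conv_block(h, paste0("fe2.conv.", i), paste0("fe2.bn.", i))
    h <- b$y; caches[[paste0("conv", i)]] <- b$cache
  }
  for (r in 1:2) {
    a <- conv_block(h, paste0("fe2.res.", r, ".a"),
                    paste0("fe2.rbn.", r, ".a"))
    cvb <- conv1d_fwd(a$y, p[[paste0("fe2.res.", r, ".b.W")]],
                      p[[paste0("fe2.res.", r, ".b.b")]], kf)
    nob <- inorm_fwd(cvb$y, p[[paste0("fe2.rbn.", r, ".b.gamma")]],
                     p[[paste0("fe2.rbn.", r, ".b.beta")]])
    s <- h + nob$y
    rl <- relu_fwd(s)
    caches[[paste0("res", r)]] <- list(a = a$cache, b = cvb$cache,
                                       nb = nob$cache, relu = rl$cache)
    h <- rl$y
  }
  for (i in 4:6) {
    b <- conv_block(h, paste0("fe2.conv.", i), paste0("fe2.bn.", i))
    h <- b$y; caches[[paste0("conv", i)]] <- b$cache
  }
  pl <- pool1d_fwd(h, g$coacc_per_hic,
                   if (is.null(ch$pool_type)) "avg" else ch$pool_type)
  caches$pool <- pl$cache
  center <- g$max_distance_bins + 1L
  right <- pl$y[center:nrow(pl$y), , drop = FALSE]
  caches$center <- center
  caches$L <- nrow(pl$y)
  lin <- linear_fwd(right, p[["fe2.lin.W"]], p[["fe2.lin.b"]])
  pn <- if (isTRUE(ch$head_norm))
    inorm_fwd(lin$y, p[["fe2.pn.gamma"]], p[["fe2.pn.beta"]])
  else list(y = lin$y, cache = NULL)
  caches$lin <- lin$cache
  caches$pn <- pn$cache
  list(F2 = pn$y, cache = if (keep_cache) caches else NULL)
}

fe2_backward <- function(model, dF2, cache) {
  ch <- model$channels; p <- model$params
  grads <- list()
  if (!is.null(cache$pn)) {
    pb <- inorm_bwd(dF2, cache$pn)
    grads[["fe2.pn.gamma"]] <- pb$dgamma; grads[["fe2.pn.beta"]] <- pb$dbeta
    dF2 <- pb$dx
  }
  lb <- linear_bwd(dF2, p[["fe2.lin.W"]], cache$lin)
  grads[["fe2.lin.W"]] <- lb$dW; grads[["fe2.lin.b"]] <- lb$db
  dpool <- matrix(0, cache$L, ncol(lb$dx))
  dpool[cache$center:cache$L, ] <- lb$dx
  dh <- pool1d_bwd(dpool, cache$pool)
  # conv -> norm -> relu block backward; returns dx and appends grads
  conv_block_bwd <- function(dh, nm, bn, cc) {
    dh <- relu_bwd(dh, cc$relu)
    nb <- inorm_bwd(dh, cc$norm)
    grads[[paste0(bn, ".gamma")]] <<- nb$dgamma
    grads[[paste0(bn, ".beta")]] <<- nb$dbeta
    cb <- conv1d_bwd(nb$dx, p[[paste0(nm, ".W")]], cc$conv)
    grads[[paste0(nm, ".W")]] <<- cb$dW
    grads[[paste0(nm, ".b")]] <<- cb$db
    cb$dx
  }
  for (i in 6:4) dh <- conv_block_bwd(dh, paste0("fe2.conv.", i),
                                      paste0("fe2.bn.", i),
                                      cache[[paste0("conv", i)]])
  for (r in 2:1) {
    cc <- cache[[paste0("res", r)]]
    ds <- relu_bwd(dh, cc$relu)
    # branch: conv_a -> norm -> relu -> conv_b -> norm; plus identity
    nb <- inorm_bwd(ds, cc$nb)
    grads[[paste0("fe2.rbn.", r, ".b.gamma")]] <- nb$dgamma
    grads[[paste0("fe2.rbn.", r, ".b.beta")]] <- nb$dbeta
    cb <- conv1d_bwd(nb$dx, p[[paste0("fe2.res.", r, ".b.W")]], cc$b)
    grads[[paste0("fe2.res.", r, ".b.W")]] <- cb$dW
    grads[[paste0("fe2.res.", r, ".b.b")]] <- cb$db
    da <- conv_block_bwd(cb$dx, paste0("fe2.res.", r, ".a"),
                         paste0("fe2.rbn.", r, ".a"), cc$a)
    dh <- ds + da
  }
  for (i in 3:1) dh <- conv_block_bwd(dh, paste0("fe2.conv.", i),
                                      paste0("fe2.bn.", i),
                                      cache[[paste0("conv", i)]])
  grads
}

# ---- full forward / backward ------------------------------------------------

model_forward <- function(model, acc_ctcf, coacc, stage = "full",
                          keep_cache = FALSE, cache_fe1 = TRUE) {
  g <- model$geometry; p <- model$params
  f1 <- fe1_forward(model, acc_ctcf, keep_cache = keep_cache && cache_fe1)
  center <- g$max_distance_bins + 1L
  F1right <- f1$F1[center:nrow(f1$F1), , drop = FALSE]
  if (stage == "stage1") {
    lin <- linear_fwd(F1right, p[["head.dummy.W"]], p[["head.dummy.b"]])
    return(list(pred = as.numeric(lin$y),
                cache = if (keep_cache)
                  list(fe1 = f1$cache, head = lin$cache, stage = stage,
                       center = center, Lfull = nrow(f1$F1)) else NULL))
  }
  f2 <- fe2_forward(model, coacc, keep_cache = keep_cache)
  H <- cbind(F1right, f2$F2)
  lin <- linear_fwd(H, p[["head.final.W"]], p[["head.final.b"]])
  list(pred = as.numeric(lin$y),
       cache = if (keep_cache)
         list(fe1 = f1$cache, fe2 = f2$cache, head = lin$cache,
              stage = stage, center = center, Lfull = nrow(f1$F1),
              d1 = ncol(F1right)) else NULL)
}

model_backward <- function(model, dpred, cache, backprop_fe1 = TRUE) {
  p <- model$params
  dpred <- matrix(dpred, ncol = 1)
  grads <- list()
  if (cache$stage == "stage1") {
    lb <- linear_bwd(dpred, p[["head.dummy.W"]], cache$head)
    grads[["head.dummy.W"]] <- lb$dW; grads[["head.dummy.b"]] <- lb$db
    dF1 <- matrix(0, cache$Lfull, ncol(lb$dx))
    dF1[cache$center:cache$Lfull, ] <- lb$dx
    if (backprop_fe1)
      grads <- c(grads, fe1_backward(model, dF1, cache$fe1))
    return(grads)
  }
  lb <- linear_bwd(dpred, p[["head.final.W"]], cache$head)
  grads[["head.final.W"]] <- lb$dW; grads[["head.final.b"]] <- lb$db
  d1 <- cache$d1
  dF2 <- lb$dx[, (d1 + 1L):ncol(lb$dx), drop = FALSE]
  grads <- c(grads, fe2_backward(model, dF2, cache$fe2))
  if (backprop_fe1) {
    dF1 <- matrix(0, cache$Lfull, d1)
    dF1[cache$center:cache$Lfull, ] <- lb$dx[, seq_len(d1), drop = FALSE]
    grads <- c(grads, fe1_backward(model, dF1, cache$fe1))
  }
  grads
}

#' Reverse a window example
#'
#' Mirrors all inputs about the window center: the accessibility/CTCF window
#' is flipped along the genomic axis, the co-accessibility slice along its
#' window axis, and its center-bin channels are reordered accordingly.
#' `reverse_example(reverse_example(x))` is `x`.
#'
#' @param example list with `acc_ctcf` (L0 x 2) and `coacc` (center-bins x
#'   window-bins).
#' @return the mirrored example.
#' @export
reverse_example <- function(example) {
  example$acc_ctcf <- example$acc_ctcf[rev(seq_len(nrow(example$acc_ctcf))), ,
                                       drop = FALSE]
  example$coacc <- example$coacc[rev(seq_len(nrow(example$coacc))),
                                 rev(seq_len(ncol(example$coacc))),
                                 drop = FALSE]
  example
}

#' Predict one side of the V-stripe
#'
#' @param model a [chromafold_model()].
#' @param example list with `acc_ctcf` and `coacc` inputs.
#' @param side `"right"` or `"left"`; the left side is predicted by
#'   reversing the input (shared weights).
#' @param stage `"full"` or `"stage1"` (dummy head on feature extractor 1).
#' @return numeric vector of length `geometry$out_len`.
#' @export
predict_one_side <- function(model, example, side = "right",
                             stage = "full") {
  if (side == "left") example <- reverse_example(example)
  model_forward(model, example$acc_ctcf, example$coacc, stage = stage)$pred
}

#' Predict both sides of the V-stripe
#'
#' @inheritParams predict_one_side
#' @return list with `left` and `right` vectors (each length `out_len`;
#'   entry 1 of both estimates the diagonal).
#' @export
predict_vstripe <- function(model, example, stage = "full") {
  list(right = predict_one_side(model, example, "right", stage),
       left = predict_one_side(model, example, "left", stage))
}
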