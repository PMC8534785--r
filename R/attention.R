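# Additive attention gate for 2-D feature maps.
#
# Given input features x at a fine scale and a gating signal g from a
# coarser scale, the gate computes per-pixel coefficients
#   a   = psi^T relu(W_x^T x_i + W_g^T g_i + b_g) + b_psi
#   d_i = sigmoid(a_i)            in [0, 1]
# and rescales the input features by elementwise multiplication. The
# gating branch W_g^T g + b_g is computed on g's grid and bilinearly
# upsampled to x's grid before the additive merge; all transforms are
# pointwise (1x1).

#' Attention-gate parameters
#'
#' Pointwise linear maps of the additive attention gate. `w_x` carries the
#' input-feature branch (no bias), `w_g`/`b_g` the gating branch, and
#' `psi`/`b_psi` project the ReLU-merged intermediate map to the single
#' pre-activation channel. `b_psi` starts at zero so an untrained gate
#' passes roughly half of every feature (coefficients near 0.5).
#'
#' @param c_x Channels of the input feature map.
#' @param c_g Channels of the gating feature map.
#' @param c_inter Intermediate channels; defaults to half of `c_x`.
#' @param seed Seed for the small random initialization.
#' @return An `ag_params` list: `w_x` (`c_x` x `c_inter`), `w_g`
#'   (`c_g` x `c_inter`), `b_g` (length `c_inter`), `psi`
#'   (`c_inter` x 1), `b_psi` (scalar).
#' @export
ag_params <- function(c_x, c_g, c_inter = NULL, seed = 1) {
  c_inter <- c_inter %||% max(1L, floor(c_x / 2))
  stopifnot(c_x >= 1, c_g >= 1, c_inter >= 1)
  with_local_seed(seed, {
    list(
      w_x = matrix(rnorm(c_x * c_inter, 0, sqrt(2 / c_x)), c_x, c_inter),
      w_g = matrix(rnorm(c_g * c_inter, 0, sqrt(2 / c_g)), c_g, c_inter),
      b_g = rep(0, c_inter),
      psi = matrix(rnorm(c_inter, 0, sqrt(2 / c_inter)), c_inter, 1),
      b_psi = 0
    )
  })
}

check_gate_shapes <- function(x, g, params) {
  dx <- dim(x); dg <- dim(g)
  if (dg[1] > dx[1] || dg[2] > dx[2]) {
    stop_input("gating signal (%dx%d) must not be finer than the input features (%dx%d)",
               dg[1], dg[2], dx[1], dx[2])
  }
  if (dx[3] != nrow(params$w_x)) {
    stop_input("input features have %d channels but w_x expects %d",
               dx[3], nrow(params$w_x))
  }
  if (dg[3] != nrow(params$w_g)) {
    stop_input("gating signal has %d channels but w_g expects %d",
               dg[3], nrow(params$w_g))
  }
}

#' Compute attention coefficients and gated features
#'
#' Additive attention: the pointwise projections of the input features and
#' the (bilinearly upsampled) gating branch are summed, passed through
#' ReLU, projected to one channel, offset by `b_psi` and squashed by a
#' sigmoid. The resulting per-pixel coefficients in \[0, 1\] multiply the
#' input features, broadcast across channels.
#'
#' @param x Input feature map, (H, W, C_x) array (a matrix is treated as
#'   one channel).
#' @param g Gating feature map at an equal or coarser spatial scale.
#' @param params An [ag_params()] set with matching channel counts.
#' @param keep_cache Retain intermediates for backpropagation.
#' @return A list: `pre_activation` (H x W matrix), `coefficients`
#'   (H x W matrix in \[0, 1\]), `gated` ((H, W, C_x) array), and `cache`
#'   when requested.
#' @export
#' @examples
#' p <- ag_params(c_x = 4, c_g = 8, seed = 1)
#' out <- attention_gate(array(rnorm(4 * 4 * 4), c(4, 4, 4)),
#'                       array(rnorm(2 * 2 * 8), c(2, 2, 8)), p)
#' range(out$coefficients)
attention_gate <- function(x, g, params, keep_cache = FALSE) {
  x <- as_map(x); g <- as_map(g)
  check_gate_shapes(x, g, params)
  dx <- dim(x); dg <- dim(g)
  xm <- map_to_mat(x)
  gm <- map_to_mat(g)
  theta <- xm %*% params$w_x
  phi <- sweep(gm %*% params$w_g, 2L, params$b_g, "+")
  phi_up <- map_to_mat(bilinear_resize(mat_to_map(phi, dg[1], dg[2]),
                                       dx[1], dx[2]))
  s_pre <- theta + phi_up
  s <- relu(s_pre)
  a <- drop(s %*% params$psi) + params$b_psi
  coef <- sigmoid_(a)
  gated <- x * array(coef, dx)
  out <- list(
    pre_activation = matrix(a, dx[1], dx[2]),
    coefficients = matrix(coef, dx[1], dx[2]),
    gated = gated
  )
  if (keep_cache) {
    out$cache <- list(xm = xm, gm = gm, s = s, s_pre = s_pre,
                      coef = coef, dx = dx, dg = dg)
  }
  out
}

# Reverse pass of attention_gate. g_gated: gradient at the gated output.
# Returns gradients for x, g and every gate parameter.
attention_gate_backward <- function(g_gated, params, cache) {
  dx <- cache$dx; dg <- cache$dg
  gg <- matrix(g_gated, nrow = dx[1] * dx[2])
  coef <- cache$coef
  gx_mat <- gg * coef
  g_coef <- rowSums(gg * cache$xm)
  g_a <- g_coef * coef * (1 - coef)
  g_psi <- crossprod(cache$s, g_a)
  g_bpsi <- sum(g_a)
  g_s <- (g_a %*% t(params$psi)) * (cache$s_pre > 0)
  gx_mat <- gx_mat + g_s %*% t(params$w_x)
  g_wx <- crossprod(cache$xm, g_s)
  g_phi <- map_to_mat(bilinear_resize_backward(
    mat_to_map(g_s, dx[1], dx[2]), dg[1], dg[2]))
  g_wg <- crossprod(cache$gm, g_phi)
  g_bg <- colSums(g_phi)
  g_gmat <- g_phi %*% t(params$w_g)
  list(
    gx = mat_to_map(gx_mat, dx[1], dx[2]),
    gg = mat_to_map(g_gmat, dg[1], dg[2]),
    grads = list(w_x = g_wx, w_g = g_wg, b_g = g_bg,
                 psi = g_psi, b_psi = g_bpsi)
  )
}

#' Rescale features by attention coefficients
#'
#' Elementwise product of a feature map with per-pixel coefficients in
#' \[0, 1\], broadcast over channels; the operation is contractive
#' (`|out| <= |x|` elementwise).
#'
#' @param x Feature map, (H, W, C) array or matrix.
#' @param coefficients H x W matrix of values in \[0, 1\].
#' @return The gated feature map, same shape as `x`.
#' @export
gate_features <- function(x, coefficients) {
  x <- as_map(x)
  d <- dim(x)
  if (!all(dim(coefficients)[1:2] == d[1:2])) {
    stop_input("coefficient grid (%dx%d) does not match features (%dx%d)",
               dim(coefficients)[1], dim(coefficients)[2], d[1], d[2])
  }
  x * array(coefficients, d)
}

#' Fuse gated features with upsampled context
#'
#' Bilinearly upsamples a coarser context map to the gated features' grid,
#' concatenates along channels and applies a pointwise convolution + ReLU
#' projecting to `ncol(w)` output channels.
#'
#' @param gated Gated feature map, (H, W, C1).
#' @param context Coarser feature map, (h, w, C2).
#' @param w Pointwise weights, (C1 + C2) x C_out.
#' @param b Length-`C_out` bias.
#' @param keep_cache Retain intermediates for backpropagation.
#' @return (H, W, C_out) array (with `cache` attribute when requested).
#' @export
fuse_attended <- function(gated, context, w, b, keep_cache = FALSE) {
  gated <- as_map(gated); context <- as_map(context)
  d1 <- dim(gated); d2 <- dim(context)
  if (d1[3] + d2[3] != nrow(w)) {
    stop_input("fuse weights expect %d channels, got %d + %d",
               nrow(w), d1[3], d2[3])
  }
  ctx_up <- bilinear_resize(context, d1[1], d1[2])
  cat_mat <- cbind(map_to_mat(gated), map_to_mat(ctx_up))
  pre <- sweep(cat_mat %*% w, 2L, b, "+")
  out <- mat_to_map(relu(pre), d1[1], d1[2])
  if (keep_cache) {
    attr(out, "cache") <- list(cat_mat = cat_mat, pre = pre, d1 = d1, d2 = d2)
  }
  out
}

fuse_attended_backward <- function(gout, w, cache) {
  d1 <- cache$d1; d2 <- cache$d2
  g <- matrix(gout, nrow = d1[1] * d1[2]) * (cache$pre > 0)
  g_cat <- g %*% t(w)
  c1 <- d1[3]
  g_ctx_up <- mat_to_map(g_cat[, (c1 + 1):ncol(g_cat), drop = FALSE],
                         d1[1], d1[2])
  list(
    g_gated = mat_to_map(g_cat[, 1:c1, drop = FALSE], d1[1], d1[2]),
    g_context = bilinear_resize_backward(g_ctx_up, d2[1], d2[2]),
    gw = crossprod(cache$cat_mat, g),
    gb = colSums(g)
  )
}
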