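# Minimal tensor kernels for 2-D feature maps stored as (H, W, C) arrays.
# Convolutions are im2col + BLAS matrix products; every op has a matching
# backward so the whole network trains by hand-written reverse accumulation.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

softmax_ <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

as_map <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Flatten (H, W, C) to the (H*W) x C matrix used by pointwise ops.
map_to_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

mat_to_map <- function(m, h, w) {
  dim(m) <- c(h, w, ncol(m) %||% 1L)
  m
}

# im2col for a 3x3 kernel, stride 1, zero padding 1. Column blocks are
# ordered offset-major: block k holds all input channels for kernel tap k.
# Gather/scatter index vectors are memoized per feature-map shape; the
# gather itself is then a single C-level subset.
.conv_geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(h, w, cin) {
  key <- paste(h, w, cin, sep = "x")
  geom <- .conv_geom_cache[[key]]
  if (!is.null(geom)) return(geom)
  hp <- h + 2L; wp <- w + 2L
  # flat index into the padded (hp, wp, cin) array for pixel (i+dy, j+dx, c)
  plane <- hp * wp
  interior <- as.vector(outer(2:(h + 1L), (2:(w + 1L) - 1L) * hp, "+"))
  interior <- as.vector(outer(interior, (seq_len(cin) - 1L) * plane, "+"))
  offsets <- vector("list", 9L)
  k <- 1L
  for (dx in 0:2) {
    for (dy in 0:2) {
      base <- as.vector(outer((1:h) + dy, ((1:w) + dx - 1L) * hp, "+"))
      offsets[[k]] <- as.vector(outer(base, (seq_len(cin) - 1L) * plane, "+"))
      k <- k + 1L
    }
  }
  geom <- list(hp = hp, wp = wp, cin = cin, n_pad = plane * cin,
               interior = interior, gather = unlist(offsets),
               offsets = offsets)
  .conv_geom_cache[[key]] <- geom
  geom
}

im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  geom <- conv_geom(h, w, cin)
  xp <- numeric(geom$n_pad)
  xp[geom$interior] <- x
  p <- xp[geom$gather]
  dim(p) <- c(h * w, 9L * cin)
  p
}

col2im3 <- function(g, h, w, cin) {
  geom <- conv_geom(h, w, cin)
  gp <- numeric(geom$n_pad)
  block <- h * w * cin
  for (k in 1:9) {
    idx <- geom$offsets[[k]]
    gp[idx] <- gp[idx] + g[((k - 1L) * block + 1L):(k * block)]
  }
  out <- gp[geom$interior]
  dim(out) <- c(h, w, cin)
  out
}

# w: (9*Cin) x Cout weight matrix, b: length-Cout bias.
conv3x3_forward <- function(x, w, b, keep_cache = FALSE) {
  d <- dim(x)
  p <- im2col3(x)
  out <- p %*% w
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1], d[2], ncol(w))
  list(out = out, cache = if (keep_cache) list(p = p, dim_in = d) else NULL)
}

# The input gradient of a stride-1 pad-1 3x3 convolution is itself such a
# convolution of the output gradient by the 180-degree-flipped kernel with
# input and output channels swapped; this reuses the fast im2col path
# instead of a scatter-add. The permutation is memoized per channel pair.
.wback_cache <- new.env(parent = emptyenv())

backward_weight_perm <- function(cin, cout) {
  key <- paste(cin, cout, sep = "x")
  perm <- .wback_cache[[key]]
  if (!is.null(perm)) return(perm)
  k <- rep(1:9, each = cout)
  co <- rep(1:cout, times = 9)
  src_row <- (9 - k) * cin # + ci
  perm <- matrix(0L, 9L * cout, cin)
  for (ci in 1:cin) perm[, ci] <- src_row + ci + (co - 1L) * 9L * cin
  perm <- as.vector(perm)
  .wback_cache[[key]] <- perm
  perm
}

conv3x3_backward <- function(gout, w, cache) {
  d <- cache$dim_in
  cout <- ncol(w)
  g <- matrix(gout, nrow = d[1] * d[2])
  wb <- w[backward_weight_perm(d[3], cout)]
  dim(wb) <- c(9L * cout, d[3])
  list(
    gx = conv3x3_forward(array(gout, c(d[1], d[2], cout)), wb, numeric(d[3]))$out,
    gw = crossprod(cache$p, g),
    gb = colSums(g)
  )
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  q <- list(
    x[io, jo, , drop = FALSE],
    x[io + 1L, jo, , drop = FALSE],
    x[io, jo + 1L, , drop = FALSE],
    x[io + 1L, jo + 1L, , drop = FALSE]
  )
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  # Ties route the gradient to the first matching quadrant.
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (q[[k]] == out) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(out = out, cache = list(masks = masks, dim_in = d))
}

maxpool2_backward <- function(gout, cache) {
  d <- cache$dim_in
  gx <- array(0, d)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  m <- cache$masks
  gx[io, jo, ] <- gout * m[[1]]
  gx[io + 1L, jo, ] <- gout * m[[2]]
  gx[io, jo + 1L, ] <- gout * m[[3]]
  gx[io + 1L, jo + 1L, ] <- gout * m[[4]]
  gx
}

# Row-interpolation matrix for bilinear resampling with half-pixel centres;
# exact identity when n_out == n_in.
resize_matrix <- function(n_in, n_out) {
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out - 0.5
    s0 <- floor(s)
    t <- s - s0
    i0 <- min(max(s0, 0), n_in - 1)
    i1 <- min(max(s0 + 1, 0), n_in - 1)
    m[i, i0 + 1] <- m[i, i0 + 1] + (1 - t)
    m[i, i1 + 1] <- m[i, i1 + 1] + t
  }
  m
}

bilinear_resize <- function(x, h_out, w_out) {
  x <- as_map(x)
  d <- dim(x)
  a <- resize_matrix(d[1], h_out)
  b <- resize_matrix(d[2], w_out)
  out <- array(0, c(h_out, w_out, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- a %*% x[, , ch] %*% t(b)
  out
}

# Adjoint of bilinear_resize: scatters an (h_out, w_out, C) gradient back
# onto the (h_in, w_in, C) grid.
bilinear_resize_backward <- function(gout, h_in, w_in) {
  d <- dim(gout)
  a <- resize_matrix(h_in, d[1])
  b <- resize_matrix(w_in, d[2])
  gx <- array(0, c(h_in, w_in, d[3]))
  for (ch in seq_len(d[3])) gx[, , ch] <- t(a) %*% gout[, , ch] %*% b
  gx
}
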