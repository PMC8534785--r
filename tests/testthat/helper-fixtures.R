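# Shared fixtures, built in code at test time.

# Tiny network configuration that keeps forward/backward passes cheap.
tiny_net <- function(..., seed = 7) {
  network_config(input_size = 32, width_multiplier = 1 / 32, seed = seed, ...)
}

# A labelled samples tibble of random images for pipeline tests.
random_samples <- function(n_per_class, size = 32, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(lab) tibble::tibble(
      id = paste0(lab, "_", seq_len(n_per_class)),
      label = lab,
      pixels = lapply(seq_len(n_per_class), function(i) {
        matrix(stats::runif(size * size), size, size)
      })
    )
    dplyr::bind_rows(mk("benign"), mk("malignant"))
  })
}

# Central finite difference of a scalar function at x (vector or matrix).
central_diff <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Independent bilinear interpolation written as an explicit per-pixel
# loop with half-pixel centres; the oracle for the vectorized resampler.
bilinear_oracle <- function(x, h_out, w_out) {
  x <- if (is.matrix(x)) array(x, c(dim(x), 1)) else x
  d <- dim(x)
  out <- array(0, c(h_out, w_out, d[3]))
  for (ch in seq_len(d[3])) {
    for (i in seq_len(h_out)) {
      for (j in seq_len(w_out)) {
        si <- (i - 0.5) * d[1] / h_out - 0.5
        sj <- (j - 0.5) * d[2] / w_out - 0.5
        i0 <- floor(si); ti <- si - i0
        j0 <- floor(sj); tj <- sj - j0
        cl <- function(v, n) min(max(v, 0), n - 1) + 1
        out[i, j, ch] <-
          (1 - ti) * (1 - tj) * x[cl(i0, d[1]), cl(j0, d[2]), ch] +
          (1 - ti) * tj       * x[cl(i0, d[1]), cl(j0 + 1, d[2]), ch] +
          ti       * (1 - tj) * x[cl(i0 + 1, d[1]), cl(j0, d[2]), ch] +
          ti       * tj       * x[cl(i0 + 1, d[1]), cl(j0 + 1, d[2]), ch]
      }
    }
  }
  out
}

# Per-pixel brute-force evaluation of the additive attention gate: for
# every pixel, ReLU(W_x' x_i + up(W_g' g + b_g)_i), project through psi,
# add b_psi, sigmoid, multiply. Written as explicit loops, independent of
# the vectorized implementation.
gate_oracle <- function(x, g, params) {
  dx <- dim(x); dg <- dim(g)
  phi <- array(0, c(dg[1], dg[2], ncol(params$w_g)))
  for (i in seq_len(dg[1])) {
    for (j in seq_len(dg[2])) {
      phi[i, j, ] <- drop(t(params$w_g) %*% g[i, j, ]) + params$b_g
    }
  }
  phi_up <- bilinear_oracle(phi, dx[1], dx[2])
  coef <- matrix(0, dx[1], dx[2])
  gated <- array(0, dx)
  for (i in seq_len(dx[1])) {
    for (j in seq_len(dx[2])) {
      s <- pmax(drop(t(params$w_x) %*% x[i, j, ]) + phi_up[i, j, ], 0)
      a <- drop(t(params$psi) %*% s) + params$b_psi
      coef[i, j] <- 1 / (1 + exp(-a))
      gated[i, j, ] <- x[i, j, ] * coef[i, j]
    }
  }
  list(coefficients = coef, gated = gated)
}

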