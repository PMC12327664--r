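# Minimal convolutional primitives, vectorized as im2col + BLAS gemm.
# Feature maps are H x W x C numeric arrays. "same" padding throughout, so an
# output spatial dim is ceiling(input dim / stride).

conv2d <- function(x, w, b, stride = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  if (dim(w)[3] != Cin) {
    abort(paste0("conv2d: weight expects ", dim(w)[3], " input channels, got ", Cin),
          class = "benthoscan_shape_error")
  }
  Ho <- as.integer(ceiling(H / stride)); Wo <- as.integer(ceiling(W / stride))
  N <- Ho * Wo
  if (kh == 1L && kw == 1L) {
    xm <- matrix(x, H * W, Cin)
    if (stride > 1L) {
      keep <- as.vector(outer(seq.int(1L, by = stride, length.out = Ho),
                              (seq.int(1L, by = stride, length.out = Wo) - 1L) * H, "+"))
      xm <- xm[keep, , drop = FALSE]
    }
    out <- xm %*% matrix(w, Cin, Cout)
  } else {
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    xp <- array(0, c(H + 2L * ph, W + 2L * pw, Cin))
    xp[ph + seq_len(H), pw + seq_len(W), ] <- x
    ii <- seq.int(1L, by = stride, length.out = Ho)
    jj <- seq.int(1L, by = stride, length.out = Wo)
    cols <- vector("list", kh * kw)
    for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
      cols[[dj * kh + di + 1L]] <- matrix(xp[ii + di, jj + dj, ], N, Cin)
    }
    # column blocks are ordered (offset, channel); reorder the kernel to match
    wmat <- matrix(aperm(w, c(3L, 1L, 2L, 4L)), kh * kw * Cin, Cout)
    out <- do.call(cbind, cols) %*% wmat
  }
  out <- out + rep(b, each = N)
  array(out, c(Ho, Wo, Cout))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# 3x3 max pool, stride 2, "same" padding (-Inf pad).
max_pool3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- as.integer(ceiling(H / 2)); Wo <- as.integer(ceiling(W / 2))
  xp <- array(-Inf, c(H + 2L, W + 2L, C))
  xp[1L + seq_len(H), 1L + seq_len(W), ] <- x
  ii <- seq.int(1L, by = 2L, length.out = Ho)
  jj <- seq.int(1L, by = 2L, length.out = Wo)
  out <- array(-Inf, c(Ho, Wo, C))
  for (dj in 0:2) for (di in 0:2) {
    out <- pmax(out, xp[ii + di, jj + dj, , drop = FALSE])
  }
  out
}

# Global average and max pooling: H x W x C -> length-2C vector (avg, max).
global_pool <- function(x) {
  m <- matrix(x, prod(dim(x)[1:2]), dim(x)[3])
  c(colMeans(m), apply(m, 2L, max))
}

# He-normal weight initialisation for a kh x kw x Cin x Cout kernel.
init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout)),
       b = rep(0, cout))
}
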