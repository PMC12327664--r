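# Fully connected classifier head: one hidden ReLU layer, trained with Adam
# under a one-cycle learning-rate schedule. Supports a softmax/cross-entropy
# output (grid-point labels) and an independent sigmoid/binary-cross-entropy
# output (multi-label patch presence). Hand-written backprop; deterministic
# for a fixed seed.

init_mlp <- function(d_in, hidden, d_out) {
  list(w1 = matrix(rnorm(d_in * hidden, sd = sqrt(2 / d_in)), d_in, hidden),
       b1 = rep(0, hidden),
       w2 = matrix(rnorm(hidden * d_out, sd = sqrt(2 / hidden)), hidden, d_out),
       b2 = rep(0, d_out))
}

mlp_logits <- function(par, X) {
  h <- X %*% par$w1
  h <- h + rep(par$b1, each = nrow(X))
  h[h < 0] <- 0
  z <- h %*% par$w2
  list(h = h, z = z + rep(par$b2, each = nrow(X)))
}

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1L, max))
  z / rowSums(z)
}

mlp_scores <- function(par, X, mode) {
  z <- mlp_logits(par, X)$z
  if (mode == "softmax") softmax_rows(z) else stats::plogis(z)
}

# One-cycle schedule: linear warmup over the first 30% of steps, cosine decay
# to 1% of the peak over the rest.
one_cycle <- function(step, total, peak) {
  warm <- max(1, floor(0.3 * total))
  if (step <= warm) return(peak * step / warm)
  t <- (step - warm) / max(1, total - warm)
  peak * (0.01 + 0.99 * 0.5 * (1 + cos(pi * t)))
}

# X: n x d features; y: integer classes (softmax) or n x K 0/1 matrix
# (sigmoid). Returns trained parameters plus a per-epoch loss trace.
train_mlp <- function(X, y, mode = c("softmax", "sigmoid"), hidden = 64L,
                      epochs = 40L, lr = 1e-3, batch = 256L, l2 = 1e-4,
                      seed = 1L, par = NULL, trace_offset = 0L) {
  mode <- match.arg(mode)
  n <- nrow(X)
  d_out <- if (mode == "softmax") max(y) else ncol(y)
  local_seed(seed, {
    if (is.null(par)) par <- init_mlp(ncol(X), hidden, d_out)
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    steps_per_epoch <- ceiling(n / batch)
    total <- epochs * steps_per_epoch
    step <- 0L
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(steps_per_epoch)) {
        idx <- ord[((s - 1L) * batch + 1L):min(s * batch, n)]
        Xb <- X[idx, , drop = FALSE]
        nb <- length(idx)
        fwd <- mlp_logits(par, Xb)
        if (mode == "softmax") {
          p <- softmax_rows(fwd$z)
          yb <- y[idx]
          loss <- -mean(log(pmax(p[cbind(seq_len(nb), yb)], 1e-12)))
          dz <- p
          dz[cbind(seq_len(nb), yb)] <- dz[cbind(seq_len(nb), yb)] - 1
          dz <- dz / nb
        } else {
          p <- stats::plogis(fwd$z)
          yb <- y[idx, , drop = FALSE]
          loss <- -mean(yb * log(pmax(p, 1e-12)) + (1 - yb) * log(pmax(1 - p, 1e-12)))
          dz <- (p - yb) / (nb * ncol(yb))
        }
        dh <- dz %*% t(par$w2)
        dh[fwd$h <= 0] <- 0
        grad <- list(w1 = crossprod(Xb, dh) + l2 * par$w1,
                     b1 = colSums(dh),
                     w2 = crossprod(fwd$h, dz) + l2 * par$w2,
                     b2 = colSums(dz))
        step <- step + 1L
        rate <- one_cycle(step, total, lr)
        for (nm in names(par)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - rate * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + loss * nb
      }
      trace[ep] <- ep_loss / n
    }
    list(par = par,
         trace = tibble(epoch = trace_offset + seq_len(epochs), loss = trace))
  })
}

# Column standardisation: returns centred/scaled matrix plus the statistics,
# which are stored in the model and re-applied at prediction time.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  list(mu = mu, sd = sdv, X = sweep(sweep(X, 2L, mu), 2L, sdv, "/"))
}

standardize_apply <- function(X, stats) {
  sweep(sweep(X, 2L, stats$mu), 2L, stats$sd, "/")
}
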