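# Independent oracles and small utilities shared across the test files.

# Explicit nested-loop Tucker composition: sum of prod(R) scaled outer
# products, written without any of the package's composition machinery.
compose_oracle <- function(core, factors) {
  rank <- dim(core)
  dims <- vapply(factors, nrow, integer(1))
  out <- array(0, dims)
  idx <- as.matrix(expand.grid(lapply(rank, seq_len)))
  for (row in seq_len(nrow(idx))) {
    r <- idx[row, ]
    o <- factors[[1]][, r[1]]
    for (j in seq_along(factors)[-1]) {
      o <- outer(o, factors[[j]][, r[j]])
    }
    out <- out + core[matrix(r, 1)] * o
  }
  out
}

random_tucker <- function(dims, rank) {
  tucker(array(rnorm(prod(rank)), rank),
         lapply(seq_along(dims), function(j) {
           matrix(rnorm(dims[j] * rank[j]), dims[j])
         }))
}

# Central finite differences of a scalar function.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Exact quantile regression on up to a dozen points by enumerating the
# residual-interpolating bases: the optimum of sum rho_tau(y - a - b x)
# passes through two data points (one point for the intercept-only model).
qr_oracle_intercept <- function(y, tau) {
  loss <- vapply(y, function(a) sum(tqreg::check_loss(y - a, tau)),
                 numeric(1))
  y[which.min(loss)]
}

qr_oracle_line <- function(y, x, tau) {
  n <- length(y)
  best <- NULL
  best_loss <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      l <- sum(tqreg::check_loss(y - a - b * x, tau))
      if (l < best_loss) {
        best_loss <- l
        best <- c(a, b)
      }
    }
  }
  best
}

# Dataset with a null tensor covariate (1x1 zero tensor) so a fit reduces
# to scalar quantile regression.
null_tensor_data <- function(y, X = NULL) {
  tqr_data(y, X, matrix(0, length(y), 1), dims = c(1L, 1L))
}

quick_control <- function(rank, ...) {
  tqr_control(rank = rank, n_restarts = 1, ...)
}

# Max objective increase over block updates within each smoothing stage;
# monotone descent means this is <= 0.
max_path_increase <- function(fit) {
  lp <- fit$loss_path
  max(unlist(tapply(lp$objective, lp$nu, function(o) {
    if (length(o) < 2) return(-Inf)
    max(diff(o))
  })))
}
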