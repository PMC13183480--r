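#' Binary two-dimensional signal tensors
#'
#' Deterministic `p x p` masks with values in \{0, 1\}, centered in the
#' grid, used as true tensor effects in simulations: a central square, a
#' plus-shaped cross (a rank-2 tensor), a disk of radius `p/4`, a filled
#' isoceles triangle, and a five-pointed star rasterized from its ten-vertex
#' outline polygon. All shapes occupy between 5 and 40 percent of the grid.
#'
#' @param name one of `"square"`, `"cross"`, `"disk"`, `"triangle"`,
#'   `"star"`.
#' @param p grid side (>= 16).
#' @return `p x p` matrix of 0/1 values.
#' @export
make_signal <- function(name = c("square", "cross", "disk", "triangle",
                                 "star"), p = 64) {
  name <- match.arg(name)
  stopifnot(p >= 16)
  G <- matrix(0, p, p)
  ctr <- (p + 1) / 2
  if (name == "square") {
    idx <- (floor(p / 4) + 1):(floor(p / 4) + floor(p / 2))
    G[idx, idx] <- 1
  } else if (name == "cross") {
    w <- max(1, round(p / 12))
    lo <- floor(p / 8) + 1
    hi <- p - floor(p / 8)
    band <- (floor(ctr) - w + 1):(floor(ctr) + w)
    G[lo:hi, band] <- 1
    G[band, lo:hi] <- 1
  } else if (name == "disk") {
    ij <- expand.grid(i = seq_len(p), j = seq_len(p))
    inside <- (ij$i - ctr)^2 + (ij$j - ctr)^2 <= (p / 4)^2
    G[cbind(ij$i, ij$j)[inside, , drop = FALSE]] <- 1
  } else if (name == "triangle") {
    h <- floor(p / 2)
    lo <- floor(p / 4)
    for (t in seq_len(h)) {
      hw <- (t - 1) / (h - 1) * (p / 4)
      cols <- max(1, ceiling(ctr - hw)):min(p, floor(ctr + hw))
      G[lo + t, cols] <- 1
    }
  } else {
    R <- 0.45 * p
    r <- R * sin(pi / 10) / sin(3 * pi / 10)
    k <- 0:9
    ang <- pi / 2 + k * pi / 5
    rad <- ifelse(k %% 2 == 0, R, r)
    vx <- ctr + rad * cos(ang)
    vy <- ctr + rad * sin(ang)
    ij <- expand.grid(i = seq_len(p), j = seq_len(p))
    G[cbind(ij$i, ij$j)[point_in_polygon(ij$j, ij$i, vx, vy), ,
                        drop = FALSE]] <- 1
  }
  G
}

# even-odd rule crossing test, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Error scale for a target signal-to-noise ratio
#'
#' Returns the scale `s` with `sd(eta) / (s * unit_spread) = snr`, where
#' `unit_spread` is the standard deviation of the unscaled error family
#' (1 for normal, `sqrt(df/(df-2))` for t, `sqrt(2 df)` for chi-squared).
#' The Cauchy has no variance, so its spread is matched through the
#' interquartile range: `IQR_Cauchy / (IQR_normal / sd_normal) = 2 / 1.349`.
#'
#' @param eta numeric linear-predictor vector (its sd sets the signal size).
#' @param family `"normal"`, `"t"`, `"cauchy"`, or `"chisq"`.
#' @param df degrees of freedom for `"t"` and `"chisq"`.
#' @param snr positive target signal-to-noise ratio.
#' @return positive scale.
#' @export
noise_scale <- function(eta, family = c("normal", "t", "cauchy", "chisq"),
                        df = 3, snr = 3) {
  family <- match.arg(family)
  stopifnot(snr > 0)
  spread <- switch(family,
    normal = 1,
    t = {
      if (df <= 2) stop("infinite variance; use robust spread")
      sqrt(df / (df - 2))
    },
    cauchy = 2 / (2 * stats::qnorm(0.75)),
    chisq = sqrt(2 * df)
  )
  stats::sd(eta) / (snr * spread)
}

#' Simulation specification
#'
#' Defaults reproduce the reference simulation design: a 64 x 64 binary
#' signal, `n = 2000` training subjects, five standard-normal scalar
#' covariates with effects `(1, ..., 5)`, tensor entries iid standard
#' normal, and errors scaled to SNR 3. `fit_rank` records the rank intended
#' for fitting (the generator itself does not use it).
#'
#' @param signal signal name for [make_signal()].
#' @param p signal side length.
#' @param fit_rank rank intended for the fitted model.
#' @param n_train,n_test sample sizes.
#' @param p0 number of scalar covariates.
#' @param beta true scalar effects (length `p0`).
#' @param family error family: `"normal"`, `"t"`, `"cauchy"`, `"chisq"`.
#' @param df degrees of freedom where applicable.
#' @param snr target signal-to-noise ratio.
#' @param tau quantile level.
#' @param seed integer seed.
#' @return object of class `"tqr_sim_spec"`.
#' @export
tqr_sim_spec <- function(signal = "square", p = 64, fit_rank = 2,
                         n_train = 2000, n_test = 1000, p0 = 5,
                         beta = seq_len(p0), family = "normal", df = 3,
                         snr = 3, tau = 0.5, seed = 1) {
  stopifnot(n_train > 0, n_test > 0, snr > 0, length(beta) == p0)
  structure(
    list(signal = signal, p = p, fit_rank = fit_rank, n_train = n_train,
         n_test = n_test, p0 = p0, beta = as.numeric(beta), family = family,
         df = df, snr = snr, tau = tau, seed = as.integer(seed)),
    class = "tqr_sim_spec"
  )
}

sim_errors <- function(n, family, df, s) {
  e <- switch(family,
    normal = stats::rnorm(n),
    t = stats::rt(n, df = df),
    cauchy = stats::rcauchy(n),
    chisq = stats::rchisq(n, df = df) - stats::qchisq(0.5, df = df)
  )
  s * e
}

#' Generate a seeded train/test pair from a simulation specification
#'
#' Entries of the tensor covariates and scalar covariates are iid standard
#' normal; `y = alpha + x' beta + <Z, Gamma> + eps` with `alpha = 0`,
#' `Gamma` the binary signal, and `eps` iid from the requested family,
#' median-centered (so the `tau = 0.5` conditional quantile equals the
#' linear predictor) and scaled to the target SNR. The error scale is set
#' from the training linear predictor and shared with the test set.
#'
#' @param spec a [tqr_sim_spec()].
#' @return list with `train` and `test` ([tqr_data()]), `truth` (list with
#'   `alpha`, `beta`, `Gamma`, `tau`), and `scale` (error scale used).
#' @export
simulate_tqr <- function(spec) {
  stopifnot(inherits(spec, "tqr_sim_spec"))
  G <- make_signal(spec$signal, spec$p)
  gvec <- vec(G)
  with_seed(spec$seed, {
    gen <- function(n) {
      X <- matrix(stats::rnorm(n * spec$p0), n, spec$p0)
      Z <- matrix(stats::rnorm(n * length(gvec)), n)
      eta <- as.vector(Z %*% gvec)
      if (spec$p0 > 0) eta <- eta + as.vector(X %*% spec$beta)
      list(X = X, Z = Z, eta = eta)
    }
    tr <- gen(spec$n_train)
    te <- gen(spec$n_test)
    s <- noise_scale(tr$eta, spec$family, spec$df, spec$snr)
    y_tr <- tr$eta + sim_errors(spec$n_train, spec$family, spec$df, s)
    y_te <- te$eta + sim_errors(spec$n_test, spec$family, spec$df, s)
    list(
      train = tqr_data(y_tr, tr$X, tr$Z, dims = dim(G)),
      test = tqr_data(y_te, te$X, te$Z, dims = dim(G)),
      truth = list(alpha = 0, beta = spec$beta, Gamma = G, tau = spec$tau),
      scale = s
    )
  })
}

#' Evaluate a fitted model against the truth on a test set
#'
#' @param fitted a `"tqr_fit"` or [tqr_model()].
#' @param truth true effect tensor, or the `truth` list from
#'   [simulate_tqr()].
#' @param test held-out [tqr_data()].
#' @return list with `test_mae` (mean absolute prediction error) and
#'   `gamma_rmse` (root mean squared error of the composed effect).
#' @export
evaluate_fit <- function(fitted, truth, test) {
  model <- if (inherits(fitted, "tqr_fit")) fitted$model else fitted
  Gtrue <- if (is.list(truth) && !is.null(truth$Gamma)) truth$Gamma else truth
  Ghat <- tucker_compose(model$effect)
  if (!all(tensor_dims(Ghat) == tensor_dims(Gtrue))) stop("dims mismatch")
  list(
    test_mae = mean(abs(test$y - linear_predictor(model, test))),
    gamma_rmse = sqrt(mean((Ghat - Gtrue)^2))
  )
}

#' Order-3 surface-style fixture for the fused-lasso penalty
#'
#' Emulates a reduced two-hemisphere surface grid: covariate tensors of size
#' `2 x p2 x p3` with iid standard-normal entries and a piecewise-constant
#' true effect holding a few contiguous rectangular patches per mode-1
#' block, one of which wraps across the mode-3 seam (the cyclic surface
#' parameterization). Responses are `<Z, Gamma>` plus normal noise at the
#' requested SNR. Suited to fused-lasso regularization with
#' [grid_adjacency()].
#'
#' @param p2,p3 grid sizes of the last two modes (>= 8).
#' @param seed integer seed.
#' @param n number of subjects.
#' @param snr signal-to-noise ratio of the normal errors.
#' @return list with `data` ([tqr_data()]) and `truth` (the effect array).
#' @export
make_surface_fixture <- function(p2 = 75, p3 = 50, seed = 1, n = 400,
                                 snr = 3) {
  stopifnot(p2 >= 8, p3 >= 8)
  dims <- c(2L, p2, p3)
  G <- array(0, dims)
  ri <- function(a, b, p) max(1, round(a * p)):min(p, round(b * p))
  G[1, ri(0.20, 0.45, p2), ri(0.10, 0.35, p3)] <- 1
  G[1, ri(0.60, 0.85, p2), c(ri(0.88, 1, p3), ri(1 / p3, 0.12, p3))] <- -1
  G[2, ri(0.30, 0.55, p2), ri(0.50, 0.75, p3)] <- 1
  gvec <- vec(G)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * length(gvec)), n)
    eta <- as.vector(Z %*% gvec)
    s <- noise_scale(eta, "normal", snr = snr)
    y <- eta + stats::rnorm(n, sd = s)
    list(data = tqr_data(y, NULL, Z, dims = dims), truth = G)
  })
}
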