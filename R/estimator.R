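#' Assemble a tensor-regression dataset
#'
#' Bundles a response vector, an optional scalar-covariate matrix and one
#' tensor covariate per subject. Tensors are stored internally as an
#' `n x prod(dims)` matrix whose rows are the mode-1-fastest vectorizations;
#' they may be supplied as such a matrix (with `dims`), as a list of arrays,
#' or as a single array whose first dimension indexes subjects.
#'
#' @param y numeric response vector of length `n`.
#' @param X optional `n x p0` numeric matrix of scalar covariates.
#' @param Z tensor covariates: `n x prod(dims)` matrix, list of `n` arrays
#'   with common dims, or an `(n, p1, ..., pq)` array.
#' @param dims tensor dims `(p1, ..., pq)`; required when `Z` is a matrix.
#' @return object of class `"tqr_data"`.
#' @export
tqr_data <- function(y, X = NULL, Z, dims = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
  }
  if (is.list(Z)) {
    dims <- tensor_dims(Z[[1]])
    Zm <- t(vapply(Z, function(a) as.vector(a), numeric(prod(dims))))
  } else if (is.array(Z) && !is.matrix(Z)) {
    d <- dim(Z)
    dims <- d[-1]
    Zm <- t(matrix(aperm(Z, c(2:length(d), 1)), nrow = prod(dims)))
  } else {
    if (is.null(dims)) stop("dims must be given when Z is a matrix")
    Zm <- as.matrix(Z)
    if (ncol(Zm) != prod(dims)) stop("ncol(Z) does not match prod(dims)")
  }
  if (nrow(X) != n || nrow(Zm) != n) {
    stop("alignment error: y, X and Z must share n")
  }
  if (anyNA(y) || anyNA(X) || anyNA(Zm) ||
      !all(is.finite(y)) || (length(X) && !all(is.finite(X))) ||
      !all(is.finite(Zm))) {
    stop("invalid data: non-finite values")
  }
  structure(
    list(y = y, X = X, Z = Zm, dims = as.integer(dims),
         n = n, p0 = ncol(X)),
    class = "tqr_data"
  )
}

#' @export
print.tqr_data <- function(x, ...) {
  cat("tqr_data: n =", x$n, ", p0 =", x$p0,
      ", tensor dims (", paste(x$dims, collapse = " x "), ")\n")
  invisible(x)
}

#' Construct a tensor quantile regression model object
#'
#' @param alpha intercept.
#' @param beta scalar-covariate effects (numeric vector, possibly empty).
#' @param effect a [tucker()] factorization of the tensor effect.
#' @param tau quantile level in (0, 1).
#' @return object of class `"tqr_model"`.
#' @export
tqr_model <- function(alpha, beta, effect, tau) {
  stopifnot(inherits(effect, "tucker"), tau > 0, tau < 1)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         effect = effect, tau = tau),
    class = "tqr_model"
  )
}

#' Fit configuration for the block-relaxation estimator
#'
#' @param rank Tucker rank `(R_1, ..., R_q)`; a single integer is recycled
#'   across modes.
#' @param tau quantile level.
#' @param nu0 initial smoothing parameter; `NULL` (default) uses
#'   `max(1, IQR(y - eta0))` at the initial estimate.
#' @param decay geometric decay of the smoothing schedule.
#' @param nu_min final smoothing parameter.
#' @param penalty a [penalty_spec()].
#' @param rel_tol relative objective-change stopping rule per smoothing stage
#'   (`1e-4` is the 0.01 percent rule).
#' @param max_sweeps maximum block-relaxation sweeps per smoothing stage.
#' @param inner_max_iter maximum gradient iterations per block update.
#' @param n_restarts random restarts; the best final objective wins.
#' @param seed integer seed making the fit deterministic.
#' @param loss_family `"quantile"` (smoothed check loss) or `"squared"`
#'   (mean-regression baseline, `u^2/2`).
#' @return object of class `"tqr_control"`.
#' @export
tqr_control <- function(rank, tau = 0.5, nu0 = NULL, decay = 0.1,
                        nu_min = 1e-4, penalty = penalty_spec(),
                        rel_tol = 1e-4, max_sweeps = 50,
                        inner_max_iter = 200, n_restarts = 3, seed = 1,
                        loss_family = c("quantile", "squared")) {
  loss_family <- match.arg(loss_family)
  stopifnot(rel_tol > 0, max_sweeps >= 1, inner_max_iter >= 1,
            n_restarts >= 1, tau > 0, tau < 1)
  structure(
    list(rank = as.integer(rank), tau = tau, nu0 = nu0, decay = decay,
         nu_min = nu_min, penalty = penalty, rel_tol = rel_tol,
         max_sweeps = max_sweeps, inner_max_iter = inner_max_iter,
         n_restarts = n_restarts, seed = as.integer(seed),
         loss_family = loss_family),
    class = "tqr_control"
  )
}

loss_eval <- function(u, tau, nu, loss_family) {
  if (loss_family == "squared") {
    list(value = u^2 / 2, deriv = u)
  } else {
    gen_huber(u, tau, nu)
  }
}

#' Linear predictor of a tensor quantile regression model
#'
#' `eta_i = alpha + x_i' beta + <Z_i, Gamma>` with `Gamma` the composed
#' Tucker effect.
#'
#' @param model a [tqr_model()].
#' @param data a [tqr_data()] (its `X` and `Z` are used).
#' @return numeric vector of length `n`.
#' @export
linear_predictor <- function(model, data) {
  if (length(model$beta) != data$p0) stop("beta length does not match p0")
  if (any(model$effect$dims != data$dims)) stop("effect dims do not match data")
  eta <- rep(model$alpha, data$n)
  if (data$p0 > 0) eta <- eta + as.vector(data$X %*% model$beta)
  g <- vec(tucker_compose(model$effect))
  if (any(g != 0)) eta <- eta + as.vector(data$Z %*% g)
  eta
}

#' Penalized smoothed objective
#'
#' Mean smoothed loss over the observations plus the weighted (smoothed)
#' penalty on the composed effect. This is the quantity the block updates
#' decrease and the stopping rule monitors.
#'
#' @inheritParams linear_predictor
#' @param nu smoothing parameter.
#' @param penalty a [penalty_spec()].
#' @param loss_family `"quantile"` or `"squared"`.
#' @return scalar.
#' @export
tqr_objective <- function(model, data, nu, penalty = penalty_spec(),
                          loss_family = "quantile") {
  r <- data$y - linear_predictor(model, data)
  L <- mean(loss_eval(r, model$tau, nu, loss_family)$value)
  G <- tucker_compose(model$effect)
  L + penalty_eval(penalty, G, nu)$value
}

#' Design matrix of a parameter block
#'
#' With all other blocks held fixed the model is linear in each block; this
#' returns the corresponding design matrix `D` such that the block's
#' contribution to the linear predictor is `D %*% b`:
#' `[1 | X]` for the scalars, rows `t(G_kron) %*% vec(Z_i)` for the core,
#' and rows `vec( Z_i_(j) %*% G_kron_j %*% t(core_(j)) )` for factor `j`.
#'
#' @param data a [tqr_data()].
#' @param model a [tqr_model()].
#' @param block `"scalars"`, `"core"`, or a mode index for a factor block.
#' @return numeric matrix with `n` rows.
#' @export
block_design <- function(data, model, block) {
  F <- model$effect
  if (identical(block, "scalars")) {
    return(cbind(1, data$X))
  }
  if (identical(block, "core")) {
    return(data$Z %*% kron_chain(F))
  }
  j <- block
  q <- length(F$dims)
  if (!(is.numeric(j) && j >= 1 && j <= q)) stop("invalid block")
  pj <- F$dims[j]
  Rj <- F$rank[j]
  W <- kron_chain(F, skip = j) %*% t(matricize(F$core, j))
  perm <- mode_permutation(j, F$dims)$forward
  U <- matrix(data$Z[, perm, drop = FALSE], nrow = data$n * pj)
  matrix(U %*% W, nrow = data$n, ncol = pj * Rj)
}

block_get <- function(model, block) {
  if (identical(block, "scalars")) c(model$alpha, model$beta)
  else if (identical(block, "core")) vec(model$effect$core)
  else vec(model$effect$factors[[block]])
}

block_set <- function(model, block, b) {
  if (identical(block, "scalars")) {
    model$alpha <- b[1]
    model$beta <- b[-1]
  } else if (identical(block, "core")) {
    model$effect$core <- unvec(b, model$effect$rank)
  } else {
    F <- model$effect
    F$factors[[block]] <- matrix(b, nrow = F$dims[block])
    model$effect <- tucker(F$core, F$factors)
  }
  model
}

# Composed-effect map and penalty chain rule for a block, with everything
# that stays fixed within the update precomputed.
block_pen_ops <- function(model, block) {
  F <- model$effect
  if (identical(block, "scalars")) {
    G0 <- tucker_compose(F)
    return(list(compose = function(b) G0, chain = NULL))
  }
  if (identical(block, "core")) {
    Gk <- kron_chain(F)
    dims <- F$dims
    return(list(
      compose = function(b) unvec(as.vector(Gk %*% b), dims),
      chain = function(dJdG) as.vector(crossprod(Gk, vec(dJdG)))
    ))
  }
  j <- block
  W <- kron_chain(F, skip = j) %*% t(matricize(F$core, j))
  dims <- F$dims
  pj <- dims[j]
  list(
    compose = function(b) unmatricize(matrix(b, pj) %*% t(W), j, dims),
    chain = function(dJdG) as.vector(matricize(dJdG, j) %*% W)
  )
}

#' Update one parameter block
#'
#' Minimizes the penalized smoothed objective in the chosen block with all
#' other blocks fixed, by gradient descent with alternating Barzilai-Borwein
#' step sizes and an Armijo backtracking safeguard (every accepted step
#' decreases the objective, so block updates never increase it). Returns the
#' entry state untouched if no descent step is found.
#'
#' @inheritParams block_design
#' @param nu smoothing parameter.
#' @param penalty a [penalty_spec()].
#' @param loss_family `"quantile"` or `"squared"`.
#' @param inner_max_iter iteration cap.
#' @param grad_tol gradient-norm tolerance per parameter (the stopping
#'   threshold is `grad_tol * length(block)`).
#' @return list with the updated `model`, the block-internal final
#'   `objective`, and `iterations` used.
#' @export
block_update <- function(data, model, block, nu, penalty = penalty_spec(),
                         loss_family = "quantile", inner_max_iter = 200,
                         grad_tol = 1e-8, entry_objective = NULL) {
  D <- block_design(data, model, block)
  b0 <- block_get(model, block)
  tau <- model$tau
  n <- data$n
  eta_full <- linear_predictor(model, data)
  offset <- eta_full - as.vector(D %*% b0)
  ops <- block_pen_ops(model, block)
  penalized <- !is.null(ops$chain) && penalty$family != "none" &&
    penalty$lambda > 0
  pen_const <- if (is.null(ops$chain)) {
    penalty_eval(penalty, ops$compose(NULL), nu)$value
  } else 0

  fobj <- function(b) {
    r <- data$y - offset - as.vector(D %*% b)
    val <- mean(loss_eval(r, tau, nu, loss_family)$value)
    if (penalized) {
      val <- val + penalty_eval(penalty, ops$compose(b), nu)$value
    }
    val + pen_const
  }
  fgrad <- function(b) {
    r <- data$y - offset - as.vector(D %*% b)
    g <- -as.vector(crossprod(D, loss_eval(r, tau, nu, loss_family)$deriv)) / n
    if (penalized) {
      pg <- penalty_eval(penalty, ops$compose(b), nu)$grad
      g <- g + ops$chain(pg)
    }
    g
  }

  b <- b0
  f <- fobj(b)
  if (!is.finite(f)) stop("diverged block update: non-finite objective")
  g <- fgrad(b)
  d <- length(b)
  tol <- grad_tol * d
  step <- 1 / max(1, sqrt(sum(g^2)))
  b_prev <- NULL
  g_prev <- NULL
  it <- 0
  while (it < inner_max_iter && sqrt(sum(g^2)) > tol) {
    it <- it + 1
    if (!is.null(b_prev)) {
      s <- b - b_prev
      yk <- g - g_prev
      sy <- sum(s * yk)
      bb <- if (it %% 2 == 0) {
        if (sy > 0) sum(s * s) / sy else NA_real_
      } else {
        yy <- sum(yk * yk)
        if (sy > 0 && yy > 0) sy / yy else NA_real_
      }
      if (is.finite(bb) && bb > 0) step <- bb
    }
    # Armijo backtracking from the BB trial step
    accepted <- FALSE
    t <- step
    gnorm2 <- sum(g^2)
    for (bt in 1:40) {
      b_try <- b - t * g
      f_try <- fobj(b_try)
      if (is.finite(f_try) && f_try <= f - 1e-4 * t * gnorm2) {
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
    b_prev <- b
    g_prev <- g
    b <- b_try
    f <- f_try
    g <- fgrad(b)
  }

  cand <- block_set(model, block, b)
  # Canonical acceptance: never let a block update increase the full
  # objective as computed by the single reference evaluation path.
  f_entry <- if (is.null(entry_objective)) {
    tqr_objective(model, data, nu, penalty, loss_family)
  } else {
    entry_objective
  }
  f_cand <- tqr_objective(cand, data, nu, penalty, loss_family)
  if (!is.finite(f_cand)) stop("diverged block update: non-finite objective")
  if (f_cand <= f_entry) {
    list(model = cand, objective = f_cand, iterations = it)
  } else {
    list(model = model, objective = f_entry, iterations = it)
  }
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit the tensor quantile regression model
#'
#' Cyclic block relaxation over the scalar block `(alpha, beta)`, the Tucker
#' core, and each factor matrix, minimizing the penalized generalized-Huber
#' objective along a vanishing smoothing schedule. Each smoothing stage
#' sweeps the blocks in fixed order until the relative objective change
#' drops below `rel_tol` (the 0.01 percent rule) or `max_sweeps` is reached,
#' and the next stage warm-starts from the current estimates. Multiple
#' seeded random restarts guard against local minima of the nonconvex
#' problem; the restart with the best final objective is kept and its effect
#' canonicalized.
#'
#' @param data a [tqr_data()].
#' @param control a [tqr_control()]; its `rank` must respect the tensor
#'   dims of `data`.
#' @return object of class `"tqr_fit"`: list with `model` (canonicalized
#'   [tqr_model()]), `loss_path` (data frame with columns `nu`, `sweep`,
#'   `block`, `objective`), `converged`, `sweeps_used`, `objective`, and
#'   `control` (config echo).
#' @export
tqr_fit <- function(data, control) {
  stopifnot(inherits(data, "tqr_data"), inherits(control, "tqr_control"))
  q <- length(data$dims)
  rank <- control$rank
  if (length(rank) == 1) rank <- rep(rank, q)
  if (length(rank) != q) stop("rank length does not match tensor order")
  bad <- which(rank > data$dims | rank < 1)
  if (length(bad)) {
    stop("rank exceeds tensor dims in mode ", bad[1])
  }
  if (stats::sd(data$y) == 0) {
    warning("degenerate fit: response is constant")
  }
  best <- NULL
  for (restart in seq_len(control$n_restarts)) {
    res <- with_seed(control$seed + restart - 1L,
                     tqr_fit_once(data, rank, control))
    if (is.null(best) || res$objective < best$objective) {
      best <- res
    }
  }
  best$model$effect <- canonicalize(best$model$effect)
  best$control <- control
  class(best) <- "tqr_fit"
  best
}

tqr_fit_once <- function(data, rank, control) {
  q <- length(data$dims)
  factors <- lapply(seq_len(q), function(j) {
    matrix(stats::rnorm(data$dims[j] * rank[j]) / sqrt(data$dims[j]),
           nrow = data$dims[j])
  })
  core <- array(0, dim = rank)
  alpha0 <- as.numeric(stats::quantile(data$y, control$tau, names = FALSE))
  model <- tqr_model(alpha0, rep(0, data$p0), tucker(core, factors),
                     control$tau)
  resid0 <- data$y - linear_predictor(model, data)
  nu0 <- control$nu0
  if (is.null(nu0)) nu0 <- max(1, stats::IQR(resid0))
  nus <- smoothing_schedule(nu0, control$decay, control$nu_min)
  blocks <- c(list("scalars", "core"), as.list(seq_len(q)))
  block_names <- c("scalars", "core", paste0("factor", seq_len(q)))

  # one core update before the first sweep so the random factors get a
  # data-driven scale
  model <- block_update(data, model, "core", nus[1], control$penalty,
                        control$loss_family, control$inner_max_iter)$model

  path <- list()
  converged <- FALSE
  sweeps_used <- 0
  obj <- tqr_objective(model, data, nus[1], control$penalty,
                       control$loss_family)
  for (nu in nus) {
    obj <- tqr_objective(model, data, nu, control$penalty,
                         control$loss_family)
    for (sweep in seq_len(control$max_sweeps)) {
      obj_start <- obj
      for (bi in seq_along(blocks)) {
        up <- block_update(data, model, blocks[[bi]], nu, control$penalty,
                           control$loss_family, control$inner_max_iter,
                           entry_objective = obj)
        model <- up$model
        obj <- up$objective
        path[[length(path) + 1]] <- data.frame(
          nu = nu, sweep = sweep, block = block_names[bi], objective = obj
        )
      }
      sweeps_used <- sweeps_used + 1
      rel <- abs(obj_start - obj) / max(abs(obj_start), 1e-10)
      if (rel < control$rel_tol) {
        converged <- TRUE
        break
      }
      converged <- FALSE
    }
  }
  list(model = model, loss_path = do.call(rbind, path),
       converged = converged, sweeps_used = sweeps_used, objective = obj)
}

#' @export
print.tqr_fit <- function(x, ...) {
  cat("Tensor quantile regression fit (tau =", x$model$tau, ")\n")
  cat("  rank (", paste(x$model$effect$rank, collapse = ", "),
      "), final objective", format(x$objective, digits = 6), "\n")
  cat("  sweeps:", x$sweeps_used, "; converged:", x$converged, "\n")
  invisible(x)
}

#' Predict conditional quantiles
#'
#' @param object a `"tqr_fit"`.
#' @param newdata a [tqr_data()] (its response, if any, is ignored).
#' @param ... unused.
#' @return numeric vector of fitted conditional `tau`-quantiles.
#' @export
predict.tqr_fit <- function(object, newdata, ...) {
  linear_predictor(object$model, newdata)
}

#' Predict conditional quantiles from a model object
#'
#' @param model a [tqr_model()].
#' @param data a [tqr_data()].
#' @return numeric vector.
#' @export
predict_quantile <- function(model, data) {
  linear_predictor(model, data)
}

# Stacked per-observation parameter-gradient matrix
# [1 | X | core design | factor designs], n x (1 + p0 + prod(R) + sum pj Rj).
theta_design <- function(model, data) {
  q <- length(model$effect$dims)
  parts <- c(list(block_design(data, model, "scalars"),
                  block_design(data, model, "core")),
             lapply(seq_len(q), function(j) block_design(data, model, j)))
  do.call(cbind, parts)
}

#' Score of the smoothed loss
#'
#' Gradient of the total (summed) smoothed loss with respect to the stacked
#' parameter vector `(alpha, beta, vec(core), vec(factor 1), ...,
#' vec(factor q))`:
#' `-sum_i H'_{tau,nu}(y_i - eta_i) d_i` where `d_i` stacks `1`, `x_i`, and
#' the core and factor Jacobian products with `vec(Z_i)`.
#'
#' @inheritParams linear_predictor
#' @param nu positive smoothing parameter.
#' @return numeric vector.
#' @export
tqr_score <- function(model, data, nu) {
  D <- theta_design(model, data)
  r <- data$y - linear_predictor(model, data)
  w <- gen_huber(r, model$tau, nu)$deriv
  -as.vector(crossprod(D, w))
}

#' Empirical Fisher information of the smoothed model
#'
#' Plug-in estimate `I_N = n^{-1} sum_i H'_{tau,nu}(y_i - eta_i)^2 d_i d_i'`
#' over the stacked parameter vector (scalars first, then core, then
#' factors).
#'
#' @inheritParams tqr_score
#' @return symmetric positive semidefinite matrix.
#' @export
tqr_information <- function(model, data, nu) {
  D <- theta_design(model, data)
  r <- data$y - linear_predictor(model, data)
  w <- gen_huber(r, model$tau, nu)$deriv
  crossprod(D * w) / data$n
}

# Tangent directions of the Tucker scale/rotation indeterminacy
# (Gamma^(j) -> Gamma^(j) M, core_(j) -> M^{-1} core_(j)) in the stacked
# parameter coordinates. sum(R_j^2) columns.
indeterminacy_tangent <- function(model, data) {
  F <- model$effect
  q <- length(F$dims)
  rank <- F$rank
  p_scal <- 1 + data$p0
  p_core <- prod(rank)
  p_fact <- F$dims * rank
  d_tot <- p_scal + p_core + sum(p_fact)
  offs_core <- p_scal
  offs_fact <- p_scal + p_core + c(0, cumsum(p_fact))[seq_len(q)]
  cols <- list()
  for (j in seq_len(q)) {
    Lj <- matricize(F$core, j)
    for (a in seq_len(rank[j])) {
      for (b in seq_len(rank[j])) {
        E <- matrix(0, rank[j], rank[j])
        E[a, b] <- 1
        v <- numeric(d_tot)
        v[offs_fact[j] + seq_len(p_fact[j])] <- vec(F$factors[[j]] %*% E)
        v[offs_core + seq_len(p_core)] <-
          -vec(unmatricize(E %*% Lj, j, rank))
        cols[[length(cols) + 1]] <- v
      }
    }
  }
  do.call(cbind, cols)
}

#' Local identifiability check
#'
#' The model is locally identifiable iff the Fisher information is
#' nonsingular on the parameter space with the Tucker indeterminacy removed.
#' The information matrix is projected onto the orthogonal complement of the
#' tangent space of the indeterminacy group (per-mode invertible
#' reparameterizations, `sum(R_j^2)` directions) and the smallest eigenvalue
#' of the restriction is compared to `tol` relative to the largest.
#'
#' @inheritParams tqr_score
#' @param tol relative eigenvalue threshold.
#' @return list with logical `identifiable`, the smallest and largest
#'   restricted eigenvalues, and the full information matrix.
#' @export
is_locally_identifiable <- function(model, data, nu, tol = 1e-8) {
  I_N <- tqr_information(model, data, nu)
  T <- indeterminacy_tangent(model, data)
  qrT <- qr(T)
  r <- qrT$rank
  Qfull <- qr.Q(qrT, complete = TRUE)
  B <- Qfull[, setdiff(seq_len(ncol(Qfull)), seq_len(r)), drop = FALSE]
  M <- crossprod(B, I_N %*% B)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  hi <- max(ev)
  list(identifiable = lo > tol * max(1, hi),
       min_eigenvalue = lo, max_eigenvalue = hi, information = I_N)
}
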