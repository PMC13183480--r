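make_state <- function(seed = 1, dims = c(4, 3), rank = c(2, 2), n = 40,
                       p0 = 2, tau = 0.5) {
  set.seed(seed)
  Z <- matrix(rnorm(n * prod(dims)), n)
  X <- matrix(rnorm(n * p0), n)
  y <- rnorm(n, sd = 2)
  data <- tqr_data(y, X, Z, dims = dims)
  model <- tqr_model(0.3, rnorm(p0), random_tucker(dims, rank), tau)
  list(data = data, model = model)
}

test_that("linear predictor matches both evaluation routes", {
  st <- make_state()
  eta <- linear_predictor(st$model, st$data)
  # route through the Kronecker chain
  eta2 <- st$model$alpha + as.vector(st$data$X %*% st$model$beta) +
    as.vector(st$data$Z %*% kron_chain(st$model$effect) %*%
                vec(st$model$effect$core))
  expect_equal(eta, eta2, tolerance = 1e-10)
  # zero effect and covariates reduce to the intercept
  m0 <- tqr_model(1, rep(0, st$data$p0),
                  tucker(array(0, c(1, 1)),
                         list(matrix(1, 4), matrix(1, 3))), 0.5)
  expect_equal(linear_predictor(m0, st$data), rep(1, st$data$n))
})

test_that("block designs reproduce each block's predictor contribution", {
  st <- make_state(seed = 2)
  model <- st$model
  data <- st$data
  eta <- linear_predictor(model, data)
  Ds <- block_design(data, model, "scalars")
  expect_equal(dim(Ds), c(data$n, 1 + data$p0))
  Dc <- block_design(data, model, "core")
  expect_equal(ncol(Dc), prod(model$effect$rank))
  contrib_tensor <- as.vector(data$Z %*% vec(tucker_compose(model$effect)))
  expect_equal(as.vector(Dc %*% vec(model$effect$core)), contrib_tensor,
               tolerance = 1e-10)
  for (j in 1:2) {
    Dj <- block_design(data, model, j)
    expect_equal(ncol(Dj), model$effect$dims[j] * model$effect$rank[j])
    expect_equal(as.vector(Dj %*% vec(model$effect$factors[[j]])),
                 contrib_tensor, tolerance = 1e-10)
  }
  expect_equal(as.vector(Ds %*% c(model$alpha, model$beta)) + contrib_tensor,
               eta, tolerance = 1e-10)
  expect_error(block_design(data, model, "bogus"), "invalid block")
})

test_that("rank-(1,1) unit-vector factors make the core design a cell pick", {
  n <- 15
  set.seed(3)
  Z <- matrix(rnorm(n * 6), n)
  data <- tqr_data(rnorm(n), NULL, Z, dims = c(2, 3))
  e1 <- function(p) { v <- matrix(0, p, 1); v[1, 1] <- 1; v }
  model <- tqr_model(0, numeric(0),
                     tucker(array(1, c(1, 1)), list(e1(2), e1(3))), 0.5)
  D <- block_design(data, model, "core")
  expect_equal(as.vector(D), Z[, 1]) # the (1,1) cell of each Z_i
})

test_that("block updates never increase the objective", {
  st <- make_state(seed = 4)
  model <- st$model
  for (rep in 1:20) {
    nu <- c(1, 0.1, 0.01)[(rep %% 3) + 1]
    for (block in list("scalars", "core", 1, 2)) {
      before <- tqr_objective(model, st$data, nu)
      up <- block_update(st$data, model, block, nu)
      expect_lte(up$objective, before)
      model <- up$model
    }
  }
})

test_that("scalars block recovers the sample median and OLS limits", {
  y <- c(1, 2, 3, 4, 5)
  data <- null_tensor_data(y)
  model <- tqr_model(5, numeric(0),
                     tucker(array(0, c(1, 1)),
                            list(matrix(1, 1), matrix(1, 1))), 0.5)
  for (nu in smoothing_schedule(1, 0.1, 1e-5)) {
    model <- block_update(data, model, "scalars", nu,
                          inner_max_iter = 500)$model
  }
  expect_equal(model$alpha, 3, tolerance = 1e-3)

  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 2), n)
  yr <- 1 + X %*% c(2, -1) + rnorm(n)
  d2 <- tqr_data(yr, X, matrix(0, n, 1), dims = c(1, 1))
  m2 <- tqr_model(0, c(0, 0),
                  tucker(array(0, c(1, 1)),
                         list(matrix(1, 1), matrix(1, 1))), 0.5)
  for (k in 1:3) {
    m2 <- block_update(d2, m2, "scalars", nu = 1, loss_family = "squared",
                       inner_max_iter = 2000, grad_tol = 1e-12)$model
  }
  ols <- coef(lm(yr ~ X))
  expect_equal(c(m2$alpha, m2$beta), unname(ols), tolerance = 1e-6)
})

test_that("fit recovers a rank-1 signal and beats the zero estimate", {
  spec <- tqr_sim_spec(signal = "square", p = 16, n_train = 200,
                       n_test = 100, snr = 3, seed = 6)
  sim <- simulate_tqr(spec)
  fit <- tqr_fit(sim$train, quick_control(rank = c(1, 1), seed = 7))
  ev <- evaluate_fit(fit, sim$truth, sim$test)
  null_rmse <- sqrt(mean(sim$truth$Gamma^2))
  expect_lt(ev$gamma_rmse, null_rmse)
  expect_lte(max_path_increase(fit), 0)
  # squared-loss fit on the same symmetric-noise data performs similarly
  fit_sq <- tqr_fit(sim$train, quick_control(rank = c(1, 1), seed = 7,
                                             loss_family = "squared"))
  ev_sq <- evaluate_fit(fit_sq, sim$truth, sim$test)
  expect_lt(abs(ev$gamma_rmse - ev_sq$gamma_rmse) / ev_sq$gamma_rmse, 0.4)
})

test_that("fits are deterministic given the seed and validate the rank", {
  spec <- tqr_sim_spec(signal = "square", p = 16, n_train = 80, n_test = 20,
                       seed = 8)
  sim <- simulate_tqr(spec)
  ctl <- quick_control(rank = c(1, 1), seed = 9, max_sweeps = 10)
  f1 <- tqr_fit(sim$train, ctl)
  f2 <- tqr_fit(sim$train, ctl)
  expect_identical(f1$objective, f2$objective)
  expect_identical(tucker_compose(f1$model$effect),
                   tucker_compose(f2$model$effect))
  expect_error(tqr_fit(sim$train, quick_control(rank = c(20, 1))),
               "mode 1")
  expect_warning(
    tqr_fit(tqr_data(rep(1, 20), NULL, matrix(rnorm(20 * 4), 20),
                     dims = c(2, 2)),
            quick_control(rank = c(1, 1), max_sweeps = 2)),
    "degenerate"
  )
})

test_that("about half the training residuals are negative at tau = 0.5", {
  spec <- tqr_sim_spec(signal = "square", p = 16, n_train = 400,
                       n_test = 50, snr = 2, seed = 10)
  sim <- simulate_tqr(spec)
  fit <- tqr_fit(sim$train, quick_control(rank = c(1, 1), seed = 11))
  r <- sim$train$y - predict(fit, sim$train)
  frac_neg <- mean(r < 0)
  expect_lt(abs(frac_neg - 0.5), 2 / sqrt(sim$train$n))
  # predictions shift with the intercept
  m <- fit$model
  m$alpha <- m$alpha + 2.5
  expect_equal(predict_quantile(m, sim$test),
               predict(fit, sim$test) + 2.5, tolerance = 1e-12)
})

test_that("score matches finite differences and vanishes at an optimum", {
  st <- make_state(seed = 12, dims = c(3, 2, 2), rank = c(2, 1, 1), n = 30)
  nu <- 0.3
  sc <- tqr_score(st$model, st$data, nu)
  pack <- function(model) {
    c(model$alpha, model$beta, vec(model$effect$core),
      unlist(lapply(model$effect$factors, vec)))
  }
  unpack <- function(v) {
    m <- st$model
    q <- length(m$effect$dims)
    i <- 1
    m$alpha <- v[i]; i <- i + 1
    m$beta <- v[i:(i + st$data$p0 - 1)]; i <- i + st$data$p0
    nc <- prod(m$effect$rank)
    m$effect$core <- unvec(v[i:(i + nc - 1)], m$effect$rank); i <- i + nc
    for (j in seq_len(q)) {
      nj <- m$effect$dims[j] * m$effect$rank[j]
      m$effect$factors[[j]] <- matrix(v[i:(i + nj - 1)], m$effect$dims[j])
      i <- i + nj
    }
    m
  }
  total_loss <- function(v) {
    m <- unpack(v)
    r <- st$data$y - linear_predictor(m, st$data)
    sum(gen_huber(r, m$tau, nu)$value)
  }
  fd <- num_grad(total_loss, pack(st$model))
  expect_equal(sc, fd, tolerance = 1e-5)

  # zero residuals sit at the flat bottom of the Huber middle piece
  st0 <- st
  st0$data$y <- linear_predictor(st$model, st$data)
  expect_equal(tqr_score(st$model, st0$data, nu),
               rep(0, length(sc)))

  # at an (unpenalized) optimum the score of the smoothed problem vanishes;
  # checked at the smoothing level the fit actually terminated at
  set.seed(13)
  n <- 100
  dims <- c(8, 8)
  Zm <- matrix(rnorm(n * prod(dims)), n)
  Gt <- tucker_compose(random_tucker(dims, c(1, 1)))
  yb <- as.vector(Zm %*% vec(Gt)) + rnorm(n, sd = 0.5)
  db <- tqr_data(yb, NULL, Zm, dims = dims)
  fit <- tqr_fit(db, quick_control(rank = c(1, 1), seed = 14,
                                   rel_tol = 1e-10, nu_min = 0.1,
                                   max_sweeps = 500))
  sc_opt <- tqr_score(fit$model, db, nu = 0.1)
  expect_lt(sqrt(sum(sc_opt^2)), 1e-3 * n)
})

test_that("information is PSD and reduces to a weighted Gram for scalars", {
  st <- make_state(seed = 15)
  nu <- 0.2
  I_N <- tqr_information(st$model, st$data, nu)
  expect_equal(I_N, t(I_N))
  ev <- eigen(I_N, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # scalars-only: null tensor covariate
  y <- st$data$y
  X <- st$data$X
  d0 <- tqr_data(y, X, matrix(0, length(y), 1), dims = c(1, 1))
  m0 <- tqr_model(0.1, c(0.5, -0.2),
                  tucker(array(0.7, c(1, 1)),
                         list(matrix(1, 1), matrix(1, 1))), 0.5)
  I0 <- tqr_information(m0, d0, nu)
  w <- gen_huber(y - linear_predictor(m0, d0), 0.5, nu)$deriv
  G <- crossprod(cbind(1, X) * w) / length(y)
  expect_equal(I0[1:3, 1:3], G, tolerance = 1e-10)
})

test_that("identifiability flags singular and generic information", {
  set.seed(16)
  n <- 120
  dims <- c(4, 3)
  Z <- matrix(rnorm(n * prod(dims)), n)
  data <- tqr_data(rnorm(n), NULL, Z, dims = dims)
  generic <- tqr_model(0, numeric(0), random_tucker(dims, c(1, 1)), 0.5)
  expect_true(is_locally_identifiable(generic, data, nu = 0.5)$identifiable)
  # duplicate factor columns give a rank-deficient Jacobian
  dup <- random_tucker(dims, c(2, 2))
  dup$factors[[1]][, 2] <- dup$factors[[1]][, 1]
  degenerate <- tqr_model(0, numeric(0), dup, 0.5)
  expect_false(is_locally_identifiable(degenerate, data,
                                       nu = 0.5)$identifiable)
})
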