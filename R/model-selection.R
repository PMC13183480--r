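#' Bayesian information criterion for a fitted model
#'
#' `BIC = 2 n Lbar + df log(n)` where `Lbar` is the mean *unsmoothed* check
#' loss at the final estimate and the effective degrees of freedom count the
#' Tucker parameters net of their rotational indeterminacy:
#' `df = 1 + p0 + prod(R_j) + sum(p_j R_j) - sum(R_j^2)`.
#' Intended for unpenalized (or fixed-penalty) fits; rank selection uses it,
#' penalty weights are tuned by cross-validation instead.
#'
#' @param fit a `"tqr_fit"`.
#' @param data the [tqr_data()] the model was fitted to.
#' @return scalar BIC.
#' @export
tqr_bic <- function(fit, data) {
  model <- fit$model
  r <- data$y - linear_predictor(model, data)
  lbar <- if (fit$control$loss_family == "squared") {
    mean(r^2 / 2)
  } else {
    mean(check_loss(r, model$tau))
  }
  rank <- model$effect$rank
  dims <- model$effect$dims
  df <- 1 + data$p0 + prod(rank) + sum(dims * rank) - sum(rank^2)
  2 * data$n * lbar + df * log(data$n)
}

#' Select the Tucker rank by BIC
#'
#' Fits every candidate rank with a shared seed and returns the BIC
#' minimizer together with the full grid. When a test set (and optionally
#' the true effect) is supplied, held-out mean absolute error and effect
#' root-mean-squared error are reported per candidate.
#'
#' @param data training [tqr_data()].
#' @param candidates list of rank vectors (or a vector of scalar ranks,
#'   recycled over modes).
#' @param control a [tqr_control()]; its `rank` is overridden per candidate.
#' @param test optional held-out [tqr_data()].
#' @param truth optional true effect tensor.
#' @return list with `best_rank`, `best_fit`, and data frame `grid`
#'   (columns `rank`, `bic`, and when available `test_mae`, `gamma_rmse`).
#' @export
select_rank <- function(data, candidates, control, test = NULL,
                        truth = NULL) {
  if (!is.list(candidates)) candidates <- as.list(candidates)
  if (length(candidates) == 0) stop("empty candidate set")
  q <- length(data$dims)
  rows <- list()
  fits <- list()
  for (i in seq_along(candidates)) {
    rk <- candidates[[i]]
    if (length(rk) == 1) rk <- rep(rk, q)
    ctl <- control
    ctl$rank <- as.integer(rk)
    fit <- tqr_fit(data, ctl)
    fits[[i]] <- fit
    row <- data.frame(rank = paste(rk, collapse = "x"),
                      bic = tqr_bic(fit, data))
    if (!is.null(test)) {
      row$test_mae <- mean(abs(test$y - predict(fit, test)))
    }
    if (!is.null(truth)) {
      Ghat <- tucker_compose(fit$model$effect)
      row$gamma_rmse <- sqrt(mean((Ghat - truth)^2))
    }
    rows[[i]] <- row
  }
  grid <- do.call(rbind, rows)
  best <- which.min(grid$bic)
  list(best_rank = candidates[[best]], best_fit = fits[[best]], grid = grid)
}

#' Tune the penalty weight by K-fold cross-validation
#'
#' Seeded K-fold split; for each `lambda`, the model is refitted on each
#' training fold and scored by the mean check loss at `tau` on the held-out
#' fold (the quantity the model optimizes). Ties go to the smaller
#' `lambda`.
#'
#' @param data a [tqr_data()].
#' @param lambdas nonnegative penalty weights to try.
#' @param K number of folds (default 5).
#' @param control a [tqr_control()] whose `penalty` supplies the family and
#'   adjacency; its `lambda` is overridden per candidate.
#' @return list with `best_lambda` and data frame `grid` (columns `lambda`,
#'   `cv_loss`).
#' @export
cv_lambda <- function(data, lambdas, K = 5, control) {
  if (length(lambdas) == 0) stop("empty lambda grid")
  if (K > data$n) stop("K exceeds n")
  if (length(lambdas) == 1) {
    return(list(best_lambda = lambdas,
                grid = data.frame(lambda = lambdas, cv_loss = NA_real_)))
  }
  folds <- with_seed(control$seed,
                     sample(rep(seq_len(K), length.out = data$n)))
  cv_loss <- numeric(length(lambdas))
  for (li in seq_along(lambdas)) {
    ctl <- control
    ctl$penalty$lambda <- lambdas[li]
    fold_loss <- numeric(K)
    for (k in seq_len(K)) {
      tr <- folds != k
      dtr <- tqr_data(data$y[tr], data$X[tr, , drop = FALSE],
                      data$Z[tr, , drop = FALSE], dims = data$dims)
      dte <- tqr_data(data$y[!tr], data$X[!tr, , drop = FALSE],
                      data$Z[!tr, , drop = FALSE], dims = data$dims)
      fit <- tqr_fit(dtr, ctl)
      r <- dte$y - predict(fit, dte)
      fold_loss[k] <- mean(check_loss(r, ctl$tau))
    }
    cv_loss[li] <- mean(fold_loss)
  }
  best <- which(cv_loss == min(cv_loss))
  best <- best[which.min(lambdas[best])]
  list(best_lambda = lambdas[best],
       grid = data.frame(lambda = lambdas, cv_loss = cv_loss))
}
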