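#' Penalty specification
#'
#' Describes the penalty applied to the composed tensor effect. Penalties act
#' on the full effect tensor, never on the core or factor matrices and never
#' on the intercept or scalar effects. The absolute value inside each penalty
#' is smoothed by `2 * H_{0.5, nu}`; with `smooth_with_nu = TRUE` (the
#' default) the smoothing parameter is the one currently used by the loss, so
#' the penalized objective converges uniformly as the schedule anneals.
#'
#' @param family one of `"none"`, `"lasso"`, `"fused_lasso"`.
#' @param lambda nonnegative penalty weight.
#' @param adjacency an object from [grid_adjacency()] (or with the same
#'   structure), required for `"fused_lasso"`.
#' @param smooth_with_nu if `TRUE`, the penalty smoothing tracks the loss
#'   smoothing parameter; otherwise `nu_pen` is used throughout.
#' @param nu_pen fixed smoothing parameter for the penalty when
#'   `smooth_with_nu = FALSE`.
#' @return object of class `"penalty_spec"`.
#' @export
penalty_spec <- function(family = c("none", "lasso", "fused_lasso"),
                         lambda = 0,
                         adjacency = NULL,
                         smooth_with_nu = TRUE,
                         nu_pen = 1e-4) {
  family <- match.arg(family)
  stopifnot(lambda >= 0, nu_pen > 0)
  if (family == "fused_lasso" && is.null(adjacency)) {
    stop("fused_lasso requires an adjacency graph")
  }
  structure(
    list(family = family, lambda = lambda, adjacency = adjacency,
         smooth_with_nu = smooth_with_nu, nu_pen = nu_pen),
    class = "penalty_spec"
  )
}

#' Smoothed lasso penalty on a tensor effect
#'
#' Evaluates `sum_cells 2 * H_{0.5, nu}(g)` together with its elementwise
#' gradient. Since `2 * rho_{0.5}(u) = |u|`, the value converges to the
#' elementwise L1 norm of `G` as `nu -> 0`.
#'
#' @param G numeric array (the composed tensor effect).
#' @param nu positive smoothing parameter.
#' @return list with scalar `value` and array `grad` shaped like `G`.
#' @export
lasso_penalty <- function(G, nu) {
  h <- gen_huber(as.vector(G), tau = 0.5, nu = nu)
  list(value = 2 * sum(h$value),
       grad = unvec(2 * h$deriv, tensor_dims(G)))
}

#' Grid adjacency for an order-3 tensor effect
#'
#' Builds the neighbour structure used by the fused-lasso penalty on a
#' `p1 x p2 x p3` grid: within every mode-1 slice `k`, vertical terms join
#' `(i, j)` to `(i + 1, j)` and horizontal terms join `(i, j)` to
#' `(i, j + 1)`, with the column index wrapping `p3 -> 1` when `wrap_mode3`
#' (a cyclic surface parameterization in the last mode). No terms ever cross
#' mode-1 slices when `block_mode1`, so disjoint structures (e.g. left and
#' right hippocampi stacked along mode 1) are never fused together.
#'
#' The `terms` matrix lists every term of the defining double sum, including
#' wrap terms that duplicate a cell pair (possible when `p3 = 2`); `edges`
#' is the deduplicated undirected edge list.
#'
#' @param dims length-3 integer vector `(p1, p2, p3)`.
#' @param wrap_mode3 wrap the last mode cyclically.
#' @param block_mode1 keep mode-1 slices unconnected (the default; currently
#'   no cross-slice terms are generated in either case, the flag documents
#'   the intent and reserves the extension).
#' @return object of class `"adjacency_graph"`: list with `dims`, integer
#'   matrices `terms` and `edges` (two columns of linear cell indices).
#' @export
grid_adjacency <- function(dims, wrap_mode3 = TRUE, block_mode1 = TRUE) {
  if (length(dims) != 3) {
    stop("grid adjacency requires order-3")
  }
  p1 <- dims[1]; p2 <- dims[2]; p3 <- dims[3]
  idx <- function(k, i, j) k + p1 * (i - 1) + p1 * p2 * (j - 1)
  a <- integer(0); b <- integer(0)
  for (k in seq_len(p1)) {
    for (j in seq_len(p3)) {
      if (p2 > 1) {
        i <- seq_len(p2 - 1)
        a <- c(a, idx(k, i, j)); b <- c(b, idx(k, i + 1, j))
      }
      jn <- if (j < p3) j + 1 else if (wrap_mode3) 1L else NA_integer_
      if (!is.na(jn)) {
        i <- seq_len(p2)
        a <- c(a, idx(k, i, j)); b <- c(b, idx(k, i, jn))
      }
    }
  }
  terms <- cbind(a, b, deparse.level = 0)
  terms <- terms[terms[, 1] != terms[, 2], , drop = FALSE]
  key <- paste(pmin(terms[, 1], terms[, 2]), pmax(terms[, 1], terms[, 2]))
  edges <- terms[!duplicated(key), , drop = FALSE]
  structure(list(dims = dims, terms = terms, edges = edges),
            class = "adjacency_graph")
}

#' Smoothed fused-lasso penalty on a tensor effect
#'
#' Evaluates the sum of smoothed absolute differences
#' `sum_terms 2 * H_{0.5, nu}(g_a - g_b)` over the adjacency terms, with the
#' gradient accumulated as `+/- 2 H'` per term. Every term of the defining
#' sum is counted, including wrap terms that repeat a cell pair, so the
#' value reproduces the grid formula literally.
#'
#' @param G numeric array.
#' @param adj adjacency from [grid_adjacency()] (dims must match `G`).
#' @param nu positive smoothing parameter.
#' @return list with scalar `value` and array `grad` shaped like `G`.
#' @export
fused_lasso_penalty <- function(G, adj, nu) {
  dims <- tensor_dims(G)
  if (length(dims) != length(adj$dims) || any(dims != adj$dims)) {
    stop("dims mismatch between tensor and adjacency graph")
  }
  g <- as.vector(G)
  d <- g[adj$terms[, 1]] - g[adj$terms[, 2]]
  h <- gen_huber(d, tau = 0.5, nu = nu)
  grad <- numeric(length(g))
  gpos <- 2 * h$deriv
  grad_a <- tapply(gpos, adj$terms[, 1], sum)
  grad_b <- tapply(gpos, adj$terms[, 2], sum)
  grad[as.integer(names(grad_a))] <- grad[as.integer(names(grad_a))] + grad_a
  grad[as.integer(names(grad_b))] <- grad[as.integer(names(grad_b))] - grad_b
  list(value = 2 * sum(h$value), grad = unvec(grad, dims))
}

#' Evaluate a penalty specification on a composed effect
#'
#' Dispatches to the penalty family and returns the (smoothed) penalty value
#' and its elementwise gradient with respect to the composed tensor. The
#' returned value and gradient already include the weight `lambda`.
#'
#' @param spec a [penalty_spec()].
#' @param G numeric array (composed tensor effect).
#' @param nu current loss smoothing parameter (used when `smooth_with_nu`).
#' @return list with `value` and `grad` (array; `NULL` grad when family is
#'   `"none"` or `lambda = 0`).
#' @export
penalty_eval <- function(spec, G, nu) {
  if (spec$family == "none" || spec$lambda == 0) {
    return(list(value = 0, grad = NULL))
  }
  nu_pen <- if (isTRUE(spec$smooth_with_nu)) nu else spec$nu_pen
  raw <- switch(spec$family,
    lasso = lasso_penalty(G, nu_pen),
    fused_lasso = fused_lasso_penalty(G, spec$adjacency, nu_pen)
  )
  list(value = spec$lambda * raw$value, grad = spec$lambda * raw$grad)
}

#' Chain-rule gradient of a penalty with respect to the core tensor
#'
#' Given the elementwise gradient `dJdG` of a penalty evaluated at the
#' composed effect, returns the gradient with respect to `vec(core)`:
#' `t(G_kron) %*% vec(dJdG)` where `G_kron` is the full Kronecker chain of
#' the factors.
#'
#' @param dJdG numeric array with the composed dims of `F`.
#' @param F object of class `"tucker"`.
#' @return numeric vector of length `prod(rank)`.
#' @export
grad_wrt_core <- function(dJdG, F) {
  dims <- tensor_dims(dJdG)
  if (length(dims) != length(F$dims) || any(dims != F$dims)) {
    stop("dims mismatch")
  }
  as.vector(crossprod(kron_chain(F), vec(dJdG)))
}

#' Chain-rule gradient of a penalty with respect to a factor matrix
#'
#' Returns `vec( matricize(dJdG, j) %*% G_kron_j %*% t(matricize(core, j)) )`
#' where `G_kron_j` is the Kronecker chain skipping mode `j` - the gradient
#' of the penalty with respect to `vec(Gamma^(j))`.
#'
#' @param dJdG numeric array with the composed dims of `F`.
#' @param F object of class `"tucker"`.
#' @param j mode.
#' @return numeric vector of length `p_j * R_j`.
#' @export
grad_wrt_factor <- function(dJdG, F, j) {
  dims <- tensor_dims(dJdG)
  if (length(dims) != length(F$dims) || any(dims != F$dims)) {
    stop("dims mismatch")
  }
  W <- kron_chain(F, skip = j) %*% t(matricize(F$core, j))
  as.vector(matricize(dJdG, j) %*% W)
}
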