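#' Vectorize a dense tensor
#'
#' Flattens an array into a vector with the mode-1 index varying fastest
#' (the column-major layout native to R), so that for a matrix `A`,
#' `vec(A)` stacks the columns of `A`.
#'
#' @param A numeric array (a plain vector counts as a 1-way tensor).
#' @return numeric vector of length `prod(dim(A))`.
#' @seealso [unvec()], [matricize()]
#' @export
vec <- function(A) {
  as.vector(A)
}

#' Restore a tensor from its vectorization
#'
#' @param v numeric vector.
#' @param dims integer vector of mode sizes; `prod(dims)` must equal
#'   `length(v)`.
#' @return numeric array with `dim = dims`.
#' @export
unvec <- function(v, dims) {
  if (length(v) != prod(dims)) {
    stop("length of v does not match prod(dims)")
  }
  array(v, dim = dims)
}

#' Mode-j matricization (unfolding)
#'
#' Unfolds a tensor into a `p_j x prod(p_k, k != j)` matrix whose rows are
#' indexed by mode j and whose columns run over the remaining modes with the
#' lower-numbered modes varying fastest (the Kolda-Bader convention).
#'
#' @param A numeric array.
#' @param j mode along which to unfold (1-based).
#' @return numeric matrix.
#' @export
matricize <- function(A, j) {
  dims <- tensor_dims(A)
  q <- length(dims)
  if (!(j >= 1 && j <= q)) {
    stop("mode out of range")
  }
  if (q == 1) {
    return(matrix(A, nrow = dims, ncol = 1))
  }
  perm <- c(j, setdiff(seq_len(q), j))
  matrix(aperm(array(A, dims), perm), nrow = dims[j])
}

#' Invert a mode-j matricization
#'
#' @param M matrix produced by [matricize()] with the same `j` and `dims`.
#' @param j mode that indexes the rows of `M`.
#' @param dims mode sizes of the original tensor.
#' @return numeric array with `dim = dims`.
#' @export
unmatricize <- function(M, j, dims) {
  q <- length(dims)
  if (!(j >= 1 && j <= q)) {
    stop("mode out of range")
  }
  if (length(M) != prod(dims)) {
    stop("element count does not match dims")
  }
  if (q == 1) {
    return(array(as.vector(M), dims))
  }
  perm <- c(j, setdiff(seq_len(q), j))
  aperm(array(as.vector(M), dims[perm]), order(perm))
}

#' Permutation map between vec(A) and vec(A[j])
#'
#' Returns the index maps realizing the row permutation that carries the
#' vectorization of a tensor to the vectorization of its mode-j unfolding.
#' The permutation is never materialized as a dense matrix: `forward` and
#' `backward` are integer vectors with `vec(A[j]) = vec(A)[forward]` and
#' `vec(A) = vec(A[j])[backward]`.
#'
#' @param j mode.
#' @param dims mode sizes.
#' @return list with integer vectors `forward` and `backward`.
#' @export
mode_permutation <- function(j, dims) {
  q <- length(dims)
  if (!(j >= 1 && j <= q)) {
    stop("mode out of range")
  }
  forward <- as.vector(matricize(array(seq_len(prod(dims)), dims), j))
  backward <- integer(length(forward))
  backward[forward] <- seq_along(forward)
  list(forward = forward, backward = backward)
}

tensor_dims <- function(A) {
  d <- dim(A)
  if (is.null(d)) length(A) else d
}

#' Tucker factorization of a tensor effect
#'
#' Bundles a core tensor `Lambda` of size `R_1 x ... x R_q` with factor
#' matrices `Gamma^(j)` of size `p_j x R_j`. The composed effect is the
#' multilinear product of the core with the factors, i.e. the sum of
#' `prod(R_j)` scaled outer products of factor columns.
#'
#' @param core numeric array (the core tensor; a scalar is a 1x...x1 core).
#' @param factors list of `q` numeric matrices; the j-th must have
#'   `R_j = dim(core)[j]` columns.
#' @return object of class `"tucker"` with elements `core`, `factors`,
#'   `dims` (composed sizes `p_j`) and `rank` (`R_j`).
#' @export
tucker <- function(core, factors) {
  if (!is.list(factors) || length(factors) == 0) {
    stop("factors must be a non-empty list of matrices")
  }
  factors <- lapply(factors, as.matrix)
  rank <- vapply(factors, ncol, integer(1))
  if (length(core) != prod(rank)) {
    stop("inconsistent factorization: core size does not match factor ranks")
  }
  core <- array(as.numeric(core), dim = rank)
  dims <- vapply(factors, nrow, integer(1))
  if (any(rank < 1) || any(rank > dims)) {
    stop("inconsistent factorization: need 1 <= R_j <= p_j for every mode")
  }
  structure(
    list(core = core, factors = factors, dims = dims, rank = rank),
    class = "tucker"
  )
}

#' @export
print.tucker <- function(x, ...) {
  cat("Tucker factorization: dims (", paste(x$dims, collapse = " x "),
      "), rank (", paste(x$rank, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Compose the tensor represented by a Tucker factorization
#'
#' @param F object of class `"tucker"`.
#' @return numeric array of size `p_1 x ... x p_q`.
#' @export
tucker_compose <- function(F) {
  stopifnot(inherits(F, "tucker"))
  v <- kron_chain(F) %*% vec(F$core)
  unvec(as.vector(v), F$dims)
}

#' Kronecker chain of Tucker factors
#'
#' Returns the Kronecker product of the factor matrices taken in the order
#' mode q down to mode 1, optionally omitting one mode. With the full chain
#' `G`, the composition identity `vec(compose(F)) = G %*% vec(core)` holds
#' under the mode-1-fastest vectorization.
#'
#' @param F object of class `"tucker"`.
#' @param skip optional mode to omit from the chain.
#' @return numeric matrix.
#' @export
kron_chain <- function(F, skip = NULL) {
  stopifnot(inherits(F, "tucker"))
  q <- length(F$factors)
  modes <- rev(seq_len(q))
  if (!is.null(skip)) {
    if (!(skip >= 1 && skip <= q)) stop("mode out of range")
    modes <- modes[modes != skip]
  }
  if (length(modes) == 0) {
    return(matrix(1, 1, 1))
  }
  out <- F$factors[[modes[1]]]
  for (k in modes[-1]) {
    out <- kronecker(out, F$factors[[k]])
  }
  out
}

#' Tensor inner product
#'
#' Dot product of the vectorizations of two equally sized tensors.
#'
#' @param Z,G numeric arrays with identical dims.
#' @return scalar.
#' @export
tensor_inner <- function(Z, G) {
  dz <- tensor_dims(Z)
  dg <- tensor_dims(G)
  if (length(dz) != length(dg) || any(dz != dg)) {
    stop("dims mismatch")
  }
  sum(as.vector(Z) * as.vector(G))
}

#' Canonicalize a Tucker factorization
#'
#' Rescales every factor column to unit Euclidean norm, fixes its sign so the
#' largest-magnitude entry is positive, and absorbs the scales and signs into
#' the core. The composed tensor is unchanged. This restricted parameter
#' space removes the scale part of the Tucker indeterminacy and is the form
#' in which fitted models are reported.
#'
#' @param F object of class `"tucker"`.
#' @return canonicalized `"tucker"` object.
#' @export
canonicalize <- function(F) {
  stopifnot(inherits(F, "tucker"))
  core <- F$core
  factors <- F$factors
  q <- length(factors)
  for (j in seq_len(q)) {
    Gj <- factors[[j]]
    nrm <- sqrt(colSums(Gj^2))
    if (any(nrm == 0)) {
      stop("degenerate factor: zero column in mode ", j)
    }
    sgn <- vapply(seq_len(ncol(Gj)), function(k) {
      col <- Gj[, k]
      s <- sign(col[which.max(abs(col))])
      if (s == 0) 1 else s
    }, numeric(1))
    scl <- nrm * sgn
    factors[[j]] <- sweep(Gj, 2, scl, "/")
    Cj <- matricize(core, j)
    core <- unmatricize(scl * Cj, j, dim(core))
  }
  tucker(core, factors)
}
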