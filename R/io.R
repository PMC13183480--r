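#' Write a single tensor as delimited text
#'
#' Plain-text container: comment header with the dims, then one
#' `p1 x p2` matrix block per index of the remaining modes (mode 3 varying
#' fastest), blocks separated by blank lines, values space-delimited.
#'
#' @param A numeric array.
#' @param path output file.
#' @export
write_tensor_text <- function(A, path) {
  dims <- tensor_dims(A)
  q <- length(dims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# dims:", paste(dims, collapse = " ")), con)
  if (q == 1) {
    writeLines(paste(format(A, digits = 17), collapse = " "), con)
    return(invisible(path))
  }
  rest <- if (q > 2) prod(dims[-(1:2)]) else 1L
  M <- matrix(as.vector(A), nrow = dims[1] * dims[2])
  for (b in seq_len(rest)) {
    slab <- matrix(M[, b], nrow = dims[1])
    writeLines(apply(slab, 1, function(r) {
      paste(format(r, digits = 17), collapse = " ")
    }), con)
    if (b < rest) writeLines("", con)
  }
  invisible(path)
}

#' Read a tensor written by [write_tensor_text()]
#'
#' @param path input file.
#' @return numeric array.
#' @export
read_tensor_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# dims:", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing dims header")
  dims <- as.integer(strsplit(sub("^# dims:\\s*", "", hdr), "\\s+")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  if (length(vals) != prod(dims)) stop("value count does not match dims")
  if (length(dims) == 1) return(array(vals, dims))
  # rows within a block are mode-1 slices: value order is (i2 fastest within
  # a line, i1 per line, higher modes per block)
  rest <- if (length(dims) > 2) prod(dims[-(1:2)]) else 1L
  out <- array(0, dims)
  M <- matrix(vals, ncol = dims[2], byrow = TRUE)
  for (b in seq_len(rest)) {
    rows <- (b - 1) * dims[1] + seq_len(dims[1])
    idx <- (b - 1) * dims[1] * dims[2] + seq_len(dims[1] * dims[2])
    out[idx] <- as.vector(M[rows, , drop = FALSE])
  }
  out
}

#' Write a dataset as covariate CSV plus tensor text container
#'
#' The covariate file holds `y` and the scalar covariates, one row per
#' subject. The tensor file holds a `# dims:` header and one comma-separated
#' row per subject with the mode-1-fastest vectorization of that subject's
#' tensor.
#'
#' @param data a [tqr_data()].
#' @param cov_path covariate CSV path.
#' @param tensor_path tensor container path.
#' @export
write_tqr_data <- function(data, cov_path, tensor_path) {
  df <- data.frame(y = data$y)
  if (data$p0 > 0) {
    Xd <- as.data.frame(data$X)
    names(Xd) <- paste0("x", seq_len(data$p0))
    df <- cbind(df, Xd)
  }
  utils::write.csv(df, cov_path, row.names = FALSE)
  con <- file(tensor_path, "w")
  on.exit(close(con))
  writeLines(paste("# dims:", paste(data$dims, collapse = " ")), con)
  writeLines(paste("# n:", data$n), con)
  utils::write.table(data$Z, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(data)
}

#' Load a dataset from covariate CSV plus tensor container
#'
#' @param cov_path covariate CSV written by [write_tqr_data()] (column `y`
#'   plus optional `x*` columns).
#' @param tensor_path tensor container path.
#' @return a validated [tqr_data()].
#' @export
read_tqr_data <- function(cov_path, tensor_path) {
  df <- utils::read.csv(cov_path)
  if (!"y" %in% names(df)) stop("covariate file must contain a y column")
  lines <- readLines(tensor_path)
  hdr <- grep("^# dims:", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing dims header")
  dims <- as.integer(strsplit(sub("^# dims:\\s*", "", hdr), "\\s+")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  Z <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  if (nrow(Z) != nrow(df)) {
    stop("alignment error: covariate rows and tensor rows differ")
  }
  Xcols <- grep("^x", names(df), value = TRUE)
  X <- if (length(Xcols)) as.matrix(df[Xcols]) else NULL
  tqr_data(df$y, X, Z, dims = dims)
}

#' Serialize a fitted model (or model object) to JSON
#'
#' Stores the intercept, scalar effects, quantile level, Tucker core and
#' factors, and, for fits, the config echo and seed.
#'
#' @param x a `"tqr_fit"` or [tqr_model()].
#' @param path output JSON path.
#' @export
write_tqr_model <- function(x, path) {
  model <- if (inherits(x, "tqr_fit")) x$model else x
  obj <- list(
    alpha = model$alpha, beta = model$beta, tau = model$tau,
    dims = model$effect$dims, rank = model$effect$rank,
    core = as.vector(model$effect$core),
    factors = lapply(model$effect$factors, function(m) {
      list(nrow = nrow(m), values = as.vector(m))
    })
  )
  if (inherits(x, "tqr_fit")) {
    ctl <- unclass(x$control)
    ctl$penalty <- unclass(ctl$penalty)
    ctl$penalty$adjacency <- NULL # geometry is re-derivable; keep JSON small
    obj$config <- ctl
    obj$seed <- ctl$seed
    obj$objective <- x$objective
    obj$converged <- x$converged
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_tqr_model()]
#'
#' @param path JSON path.
#' @return a [tqr_model()].
#' @export
read_tqr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- lapply(
    if (is.data.frame(obj$factors)) seq_len(nrow(obj$factors))
    else seq_along(obj$factors),
    function(i) {
      f <- if (is.data.frame(obj$factors)) {
        list(nrow = obj$factors$nrow[i], values = obj$factors$values[[i]])
      } else obj$factors[[i]]
      matrix(as.numeric(unlist(f$values)), nrow = f$nrow)
    }
  )
  core <- array(as.numeric(obj$core), dim = as.integer(obj$rank))
  tqr_model(obj$alpha, as.numeric(unlist(obj$beta)),
            tucker(core, factors), obj$tau)
}

#' Read an adjacency edge list from CSV
#'
#' Two-column CSV of linear cell indices defining undirected fusion edges
#' over a tensor with the given dims; used to supply custom geometries to
#' the fused-lasso penalty.
#'
#' @param path CSV path with columns `a` and `b`.
#' @param dims tensor dims the indices refer to.
#' @return an `"adjacency_graph"`.
#' @export
read_adjacency_csv <- function(path, dims) {
  df <- utils::read.csv(path)
  edges <- cbind(as.integer(df$a), as.integer(df$b))
  if (any(edges < 1) || any(edges > prod(dims))) {
    stop("edge indices outside tensor")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-edges not allowed")
  structure(list(dims = dims, terms = edges, edges = edges),
            class = "adjacency_graph")
}
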