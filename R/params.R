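#' Parameter sets
#'
#' A parameter set is the ordered collection of one model's trainable tensors:
#' a named list of numeric arrays. The order of entries defines the row-major
#' flattening used by the spectral aggregation machinery, so it must be
#' identical across clients that share an architecture.
#'
#' @param entries Named list of finite numeric vectors/arrays.
#' @return For [parameter_set()], the validated named list (invisibly classed
#'   `rfed_params`); [param_total_len()] returns the total scalar count.
#' @examples
#' p <- parameter_set(list(a = matrix(1:4, 2), b = c(0.5, -0.5)))
#' param_total_len(p)
#' @export
parameter_set <- function(entries) {
  if (!is.list(entries) || length(entries) == 0)
    stop("parameter set must be a non-empty named list of numeric arrays")
  nm <- names(entries)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("parameter set entries must have unique non-empty names")
  for (n in nm) {
    v <- entries[[n]]
    if (!is.numeric(v))
      stop(sprintf("entry '%s' is not numeric", n))
    if (!all(is.finite(v)))
      stop(sprintf("entry '%s' contains non-finite values", n))
  }
  structure(entries, class = "rfed_params")
}

#' @rdname parameter_set
#' @param params A parameter set.
#' @export
param_total_len <- function(params) {
  sum(vapply(params, length, 1L))
}

#' Flatten a parameter set to a single vector
#'
#' Concatenates every tensor (in entry order, column-major within each array)
#' into one numeric vector and records a shape registry sufficient for exact
#' inversion by [unflatten_params()].
#'
#' @param params A [parameter_set()] (or plain named list of numeric arrays).
#' @return List with `vector` (numeric) and `shapes` (named list of integer
#'   dimension vectors; scalar-vector entries record their length).
#' @examples
#' fl <- flatten_params(list(a = c(1, 2), b = 3))
#' fl$vector
#' @export
flatten_params <- function(params) {
  params <- parameter_set(params)
  shapes <- lapply(params, function(v) {
    d <- dim(v)
    if (is.null(d)) length(v) else d
  })
  list(vector = unlist(lapply(params, as.numeric), use.names = FALSE),
       shapes = shapes)
}

#' @rdname flatten_params
#' @param vector Numeric vector produced by [flatten_params()].
#' @param shapes Shape registry produced by [flatten_params()].
#' @export
unflatten_params <- function(vector, shapes) {
  sizes <- vapply(shapes, prod, 1)
  if (length(vector) != sum(sizes))
    stop("vector length does not match shape registry")
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  off <- 0L
  for (i in seq_along(shapes)) {
    n <- as.integer(sizes[[i]])
    v <- vector[(off + 1L):(off + n)]
    if (length(shapes[[i]]) > 1L) dim(v) <- shapes[[i]]
    out[[i]] <- v
    off <- off + n
  }
  structure(out, class = "rfed_params")
}

# Check that all parameter sets share names and shapes (same architecture).
check_same_architecture <- function(param_list) {
  if (length(param_list) == 0) stop("no parameter sets given")
  ref <- lapply(param_list[[1]], function(v) if (is.null(dim(v))) length(v) else dim(v))
  for (k in seq_along(param_list)) {
    p <- param_list[[k]]
    if (!identical(names(p), names(param_list[[1]])))
      stop(sprintf("client %d: tensor names differ from client 1", k))
    shp <- lapply(p, function(v) if (is.null(dim(v))) length(v) else dim(v))
    if (!identical(shp, ref))
      stop(sprintf("client %d: tensor shapes differ from client 1", k))
  }
  invisible(TRUE)
}
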