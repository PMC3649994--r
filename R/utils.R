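# Internal helpers shared across modules.

# Abort with a classed condition so callers/tests can distinguish
# configuration errors from invalid data.
stop_invalid <- function(msg, class = "netrack_invalid_config") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         min = NULL, max = NULL, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop_invalid(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_invalid(sprintf("'%s' must be >= 0", name))
  if (!is.null(min) && x < min)
    stop_invalid(sprintf("'%s' must be >= %s", name, format(min)))
  if (!is.null(max) && x > max)
    stop_invalid(sprintf("'%s' must be <= %s", name, format(max)))
  if (integer && x != round(x))
    stop_invalid(sprintf("'%s' must be an integer", name))
  invisible(x)
}

# Gaussian blur by explicit row/column weight matrices. Weights are
# renormalised at the borders, so constants are preserved exactly and
# kernels larger than the image remain well defined.
gaussian_weight_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  w <- exp(-(d * d) / (2 * sigma * sigma))
  w / rowSums(w)
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  ky <- gaussian_weight_matrix(nrow(mat), sigma)
  kx <- gaussian_weight_matrix(ncol(mat), sigma)
  ky %*% mat %*% t(kx)
}

# Derive independent substream seeds from one root seed (kept < 2^31).
derive_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(root_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
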