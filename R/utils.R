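#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov cor rbinom rlnorm rnorm runif sd setNames
#'   TukeyHSD var
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `expr` under `seed` when one is given, without touching the caller's
# RNG stream; with seed = NULL the current stream is used (and advanced).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Symmetric, zero-diagonal, non-negative distance matrix with labels.
check_distance_matrix <- function(d, name = "dist", zero_diag = TRUE) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(name, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop(name, " must have row and column labels", call. = FALSE)
  if (!identical(rownames(d), colnames(d)))
    stop(name, " row and column labels differ", call. = FALSE)
  if (any(!is.finite(d))) stop(name, " contains non-finite values", call. = FALSE)
  if (any(d < 0)) stop(name, " contains negative distances", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop(name, " is not symmetric", call. = FALSE)
  if (zero_diag && any(abs(diag(d)) > 1e-12))
    stop(name, " has a nonzero diagonal", call. = FALSE)
  invisible(d)
}

# Lower-triangle vector of a square matrix, in a fixed (column-major) order.
lower_vec <- function(m) m[lower.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
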