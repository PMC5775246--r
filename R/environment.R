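default_windows <- function() {
  list(MAT  = 1:12,            # mean annual temperature
       MAuT = 9:11,            # autumn: Sep-Nov
       MWT  = c(12, 1, 2),     # winter: Dec-Feb
       MST  = 3:5,             # spring: Mar-May
       ATF  = 1:12,            # annual fluctuation
       AWTF = c(9:12, 1, 2),   # autumn-winter: Sep-Feb
       WTF  = c(12, 1, 2),     # winter fluctuation
       WSTF = c(12, 1:5))      # winter-spring: Dec-May
}

#' Derive the eight temperature predictors from monthly means
#'
#' Four seasonal mean-temperature predictors (MAT, MAuT, MWT, MST: annual,
#' autumn, winter and spring means) and four temperature-fluctuation
#' predictors (ATF, AWTF, WTF, WSTF: variability of the monthly means over
#' the annual, autumn-winter, winter and winter-spring windows).
#' Fluctuation is the sample standard deviation of the window's monthly
#' means by default; `fluctuation = "range"` uses max - min instead.
#'
#' @param climate Numeric matrix, sites in rows, 12 monthly mean
#'   temperatures (degrees C) in columns (Jan..Dec).
#' @param fluctuation `"sd"` (default) or `"range"`.
#' @param windows Named list of month-index windows; see
#'   `commstruct:::default_windows()` for the Northern-Hemisphere defaults.
#' @return Numeric matrix, sites in rows, the 8 predictors in columns.
#' @export
temperature_predictors <- function(climate, fluctuation = c("sd", "range"),
                                   windows = default_windows()) {
  fluctuation <- match.arg(fluctuation)
  if (ncol(climate) != 12) stop("climate needs 12 monthly columns", call. = FALSE)
  bad <- vapply(windows, function(w) any(w < 1 | w > 12), TRUE)
  if (any(bad))
    stop("window(s) referencing a missing month: ",
         paste(names(windows)[bad], collapse = ", "), call. = FALSE)
  fl <- if (fluctuation == "sd") stats::sd else function(x) diff(range(x))
  mean_vars <- c("MAT", "MAuT", "MWT", "MST")
  fluct_vars <- c("ATF", "AWTF", "WTF", "WSTF")
  vars <- c(mean_vars, fluct_vars)
  out <- matrix(0, nrow(climate), length(vars),
                dimnames = list(rownames(climate), vars))
  for (v in vars) {
    w <- climate[, windows[[v]], drop = FALSE]
    out[, v] <- if (v %in% mean_vars) rowMeans(w) else apply(w, 1, fl)
  }
  out
}

#' Two-dimensional NMDS ordination of a site dissimilarity matrix
#'
#' Nonmetric multidimensional scaling by Kruskal stress minimization with
#' multiple random starts, delegated to [vegan::metaMDS()] (no community
#' transformation is applied: the input is already a dissimilarity).
#' Coordinates are centered.
#'
#' @param d Site-by-site symmetric dissimilarity matrix.
#' @param k Ordination dimension (default 2).
#' @param n_starts Maximum number of random starts (default 20).
#' @param seed Optional integer seed; fixed seed gives identical coordinates.
#' @return A list: `points` (site-by-k coordinates), `stress`, `converged`,
#'   `n_starts`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = NULL) {
  # beta matrices may carry a nonzero self-comparison diagonal; as.dist
  # drops it, so only symmetry/non-negativity are required here
  check_distance_matrix(d, zero_diag = FALSE)
  if (all(d[lower.tri(d)] == 0)) stop("all distances are zero", call. = FALSE)
  with_seed_or_not(seed, {
    fit <- vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts,
                          trace = 0, autotransform = FALSE, wascores = FALSE)
    pts <- vegan::scores(fit, display = "sites")
    pts <- sweep(pts, 2, colMeans(pts))
    rownames(pts) <- rownames(d)
    list(points = pts, stress = fit$stress, converged = isTRUE(fit$converged),
         n_starts = n_starts)
  })
}

#' Fit environmental vectors onto an ordination
#'
#' Each predictor is regressed on the (centered) ordination coordinates;
#' the fitted direction cosines are the unit vector of regression
#' coefficients, r2 is the squared multiple correlation, and the
#' permutation p-value counts permutations of the predictor across sites
#' whose r2 reaches the observed one. Arrow coordinates are the direction
#' scaled by `sqrt(r2)`, so weak predictors get short arrows.
#'
#' @param ord Result of [nmds_ordination()] (or a site-by-k coordinate
#'   matrix).
#' @param predictors Numeric matrix, sites in rows, predictors in columns
#'   (same sites as the ordination).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A data.frame, one row per predictor: `variable`, `dx`, `dy`
#'   (direction cosines), `arrow_x`, `arrow_y`, `r2`, `p`. Zero-variance
#'   predictors are flagged with `NA` results and skipped.
#' @export
envfit_vectors <- function(ord, predictors, n_perm = 999, seed = NULL) {
  X <- if (is.list(ord)) ord$points else ord
  if (nrow(predictors) != nrow(X))
    stop("predictors and ordination cover different site counts", call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(predictors)) &&
      !identical(rownames(X), rownames(predictors)))
    predictors <- predictors[rownames(X), , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  xtx_inv <- solve(crossprod(X))
  with_seed_or_not(seed, {
    rows <- lapply(colnames(predictors), function(v) {
      y <- predictors[, v]
      if (stats::var(y) == 0) {
        warning("zero-variance predictor skipped: ", v)
        return(data.frame(variable = v, dx = NA_real_, dy = NA_real_,
                          arrow_x = NA_real_, arrow_y = NA_real_,
                          r2 = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      yc <- y - mean(y)
      b <- drop(xtx_inv %*% crossprod(X, yc))
      r2 <- sum((X %*% b)^2) / sum(yc^2)
      dir <- b / sqrt(sum(b^2))
      Y <- vapply(seq_len(n_perm), function(i) sample(yc), numeric(n))
      Fhat <- X %*% (xtx_inv %*% crossprod(X, Y))
      r2_perm <- colSums(Fhat^2) / colSums(Y^2)
      data.frame(variable = v, dx = dir[1], dy = dir[2],
                 arrow_x = dir[1] * sqrt(r2), arrow_y = dir[2] * sqrt(r2),
                 r2 = r2, p = (sum(r2_perm >= r2) + 1) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
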