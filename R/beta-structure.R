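#' Abundance-weighted pairwise beta diversity (Dpw) between two communities
#'
#' The double sum over species `i` of community `k1` and species `j` of
#' community `k2` of `d_ij * f_i * f_j`, where `f` are within-community
#' relative abundances (renormalized internally). Species shared by both
#' communities contribute their zero self-distance terms; the sum is
#' unrestricted. With relative abundances the weights sum to one, so this
#' is the abundance-weighted mean pairwise between-community distance.
#'
#' @param k1,k2 Named numeric abundance vectors.
#' @param dist Species-by-species distance matrix.
#' @return A single numeric value.
#' @export
dpw <- function(k1, k2, dist) {
  f1 <- beta_relabund(k1, dist)
  f2 <- beta_relabund(k2, dist)
  drop(f1 %*% dist[names(f1), names(f2), drop = FALSE] %*% f2)
}

#' Abundance-weighted nearest neighbour beta diversity (Dnn)
#'
#' For each species of one community, the distance to its nearest neighbour
#' in the other community, abundance-weighted and summed over both
#' directions:
#' `(sum_i min_d(i -> k2) f_i + sum_j min_d(j -> k1) f_j) / (sum_i f_i * sum_j f_j)`.
#' With relative abundances the denominator is one, so the two directional
#' terms are added — the `"literal"` convention. `convention = "halved"`
#' divides by two, giving the average of the two directions as computed by
#' common implementations (e.g. `picante::comdistnt`); the two conventions
#' differ by an exact factor of two.
#'
#' @inheritParams dpw
#' @param convention `"literal"` (sum of the two directions, default) or
#'   `"halved"` (their mean).
#' @return A single numeric value.
#' @export
dnn <- function(k1, k2, dist, convention = c("literal", "halved")) {
  convention <- match.arg(convention)
  f1 <- beta_relabund(k1, dist)
  f2 <- beta_relabund(k2, dist)
  d <- dist[names(f1), names(f2), drop = FALSE]
  min1 <- apply(d, 1, min)
  min2 <- apply(d, 2, min)
  val <- sum(min1 * f1) + sum(min2 * f2)
  if (convention == "halved") val / 2 else val
}

beta_relabund <- function(k, dist) {
  k <- k[k > 0]
  if (!length(k)) stop("empty community", call. = FALSE)
  miss <- setdiff(names(k), rownames(dist))
  if (length(miss))
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  k / sum(k)
}

#' All pairwise beta diversity values between sites
#'
#' @param comm Site-by-species abundance matrix.
#' @param dist Species-by-species distance matrix.
#' @param metric `"dpw"` or `"dnn"`.
#' @param convention Dnn convention, see [dnn()].
#' @return Site-by-site matrix. The Dpw diagonal holds each community's
#'   self-comparison (its abundance-weighted MPD including self-pairs); the
#'   Dnn diagonal is zero.
#' @export
beta_matrix <- function(comm, dist, metric = c("dpw", "dnn"),
                        convention = c("literal", "halved")) {
  metric <- match.arg(metric)
  convention <- match.arg(convention)
  sp <- colnames(comm)
  miss <- setdiff(sp[colSums(comm) > 0], rownames(dist))
  if (length(miss))
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  f <- comm / rowSums(comm)
  if (metric == "dpw")
    return(f %*% dist[sp, sp] %*% t(f))
  n_site <- nrow(comm)
  out <- matrix(0, n_site, n_site, dimnames = list(rownames(comm), rownames(comm)))
  present <- apply(comm > 0, 1, which, simplify = FALSE)
  d <- dist[sp, sp]
  for (a in seq_len(n_site - 1)) for (b in (a + 1):n_site) {
    ia <- present[[a]]; ib <- present[[b]]
    dab <- d[ia, ib, drop = FALSE]
    min1 <- dab[cbind(seq_along(ia), max.col(-dab, ties.method = "first"))]
    min2 <- dab[cbind(max.col(-t(dab), ties.method = "first"), seq_along(ib))]
    val <- sum(min1 * f[a, ia]) + sum(min2 * f[b, ib])
    out[a, b] <- out[b, a] <- if (convention == "halved") val / 2 else val
  }
  out
}

#' Null-standardized beta diversity (tip-shuffle null)
#'
#' Standardizes every pairwise beta value against a null built by shuffling
#' species identities across the tips of the phylogeny (or the rows of the
#' trait matrix) — implemented, exactly equivalently, as a joint
#' permutation of the distance-matrix labels — and recomputing all pairwise
#' values. Per-pair SES is `(obs - mean(null)) / sd(null)`; pairs with a
#' degenerate null (`sd = 0`) get `NA` and are flagged.
#'
#' @inheritParams beta_matrix
#' @param n_null Number of label shuffles (default 999).
#' @param seed Optional integer seed; fixed seed gives a bit-identical result.
#' @return A list of class `beta_ses`: `obs`, `null_mean`, `null_sd`, `ses`
#'   (site-by-site matrices), plus `metric`, `convention`, `n_null`,
#'   `n_degenerate`.
#' @export
beta_null_standardize <- function(comm, dist, metric = c("dpw", "dnn"),
                                  convention = c("literal", "halved"),
                                  n_null = 999, seed = NULL) {
  metric <- match.arg(metric)
  convention <- match.arg(convention)
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  check_distance_matrix(dist)
  obs <- beta_matrix(comm, dist, metric, convention)
  n_sp <- nrow(dist)
  with_seed_or_not(seed, {
    reps <- vapply(seq_len(n_null), function(r) {
      perm <- sample.int(n_sp)
      dnull <- dist[perm, perm]
      dimnames(dnull) <- dimnames(dist)
      beta_matrix(comm, dnull, metric, convention)
    }, obs)
    mu <- rowMeans(reps, dims = 2)
    sdv <- if (n_null > 1)
      sqrt(rowSums((reps - c(mu))^2, dims = 2) / (n_null - 1))
    else matrix(0, nrow(obs), ncol(obs))
    dimnames(mu) <- dimnames(sdv) <- dimnames(obs)
    degenerate <- sdv <= 1e-10 * max(obs)
    ses <- (obs - mu) / sdv
    ses[degenerate] <- NA_real_
    structure(list(obs = obs, null_mean = mu, null_sd = sdv, ses = ses,
                   metric = metric, convention = convention, n_null = n_null,
                   n_degenerate = sum(degenerate[lower.tri(degenerate)])),
              class = "beta_ses")
  })
}

#' Compare beta diversity between geographic region pairs
#'
#' Groups all site-pair beta values by region pair (within-west,
#' within-center, within-east and the between-region combinations), then
#' tests for group differences with one-way ANOVA followed by Tukey HSD
#' adjusted pairwise comparisons.
#'
#' @param beta Site-by-site beta diversity matrix.
#' @param regions Named character vector mapping each site to its region
#'   (see [assign_regions()]).
#' @return A list: `values` (long data.frame of pairs), `group_means`,
#'   `anova_p`, and `tukey` (data.frame with Tukey-adjusted `p_adj`).
#' @export
region_contrast <- function(beta, regions) {
  sites <- rownames(beta)
  miss <- setdiff(sites, names(regions))
  if (length(miss))
    stop("sites without region assignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(regions[sites])) < 2)
    stop("need at least 2 regions to contrast", call. = FALSE)
  small <- names(which(table(regions[sites]) < 2))
  if (length(small))
    warning("region(s) with < 2 sites, within-region group omitted: ",
            paste(small, collapse = ", "))
  idx <- which(lower.tri(beta), arr.ind = TRUE)
  r1 <- regions[sites[idx[, 1]]]
  r2 <- regions[sites[idx[, 2]]]
  grp <- ifelse(r1 == r2, paste0("within_", r1),
                paste0("between_", pmin(r1, r2), "_", pmax(r1, r2)))
  vals <- data.frame(site1 = sites[idx[, 1]], site2 = sites[idx[, 2]],
                     value = beta[idx], group = grp, stringsAsFactors = FALSE)
  vals <- vals[!(vals$group %in% paste0("within_", small)), ]
  if (stats::var(vals$value) == 0) {
    groups <- sort(unique(vals$group))
    combs <- utils::combn(groups, 2)
    tukey <- data.frame(contrast = paste(combs[2, ], combs[1, ], sep = "-"),
                        diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(values = vals,
                group_means = tapply(vals$value, vals$group, mean),
                anova_p = 1, tukey = tukey))
  }
  fit <- stats::aov(value ~ group, data = vals)
  tk <- stats::TukeyHSD(fit)$group
  list(values = vals,
       group_means = tapply(vals$value, vals$group, mean),
       anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Mantel and partial Mantel test
#'
#' Pearson correlation of the lower-triangle vectors of two site distance
#' matrices; with a `control` matrix both vectors are first residualized on
#' the control's vector (partial Mantel). Significance comes from jointly
#' permuting the row/column labels of `m1` `n_perm` times; the one-tailed
#' p-value is `(number of permuted r >= observed + 1) / (n_perm + 1)`.
#' When the control explains one matrix completely (zero residual variance,
#' e.g. `control` equal to `m2`), the partial correlation is returned as 0
#' with p = 1 rather than an undefined 0/0.
#'
#' @param m1,m2 Site-by-site symmetric distance matrices, same site order.
#' @param control Optional third matrix to partial out.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A list: `r`, `p`, `n_perm`.
#' @export
partial_mantel <- function(m1, m2, control = NULL, n_perm = 999, seed = NULL) {
  n <- nrow(m1)
  if (!all(dim(m2) == n) || (!is.null(control) && !all(dim(control) == n)))
    stop("matrix size mismatch", call. = FALSE)
  lt <- which(lower.tri(m1))
  ii <- row(m1)[lt]
  jj <- col(m1)[lt]
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (!is.null(control)) {
    xc <- cbind(1, control[lt])
    proj <- xc %*% solve(crossprod(xc), t(xc))
    v2_raw_var <- stats::var(v2)
    v2 <- v2 - drop(proj %*% v2)
    # control explains m2 (or m1) completely: nothing left to correlate
    if (stats::var(v2) <= 1e-20 * v2_raw_var)
      return(list(r = 0, p = 1, n_perm = n_perm))
    resid_fun <- function(v) v - proj %*% v
  } else {
    resid_fun <- identity
  }
  v1r <- drop(resid_fun(v1))
  if (!is.null(control) && stats::var(v1r) <= 1e-20 * stats::var(v1))
    return(list(r = 0, p = 1, n_perm = n_perm))
  r_obs <- stats::cor(v1r, v2)
  with_seed_or_not(seed, {
    perm_v1 <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      m1[cbind(p[ii], p[jj])]
    }, numeric(length(lt)))
    perm_v1 <- resid_fun(perm_v1)
    r_perm <- suppressWarnings(drop(stats::cor(perm_v1, v2)))
    list(r = r_obs, p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
         n_perm = n_perm)
  })
}
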