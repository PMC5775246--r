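#' Mean pairwise distance within a community
#'
#' Unweighted: the mean of the pairwise distances over distinct unordered
#' pairs of species present. Abundance-weighted: the relative-abundance
#' weighted mean over ordered pairs with self-pairs excluded,
#' `sum(d_ij f_i f_j) / sum(f_i f_j)` over `i != j`, which reduces to the
#' unweighted value when abundances are equal.
#'
#' @param community Named numeric vector of abundances; species with
#'   abundance > 0 are "present".
#' @param dist Species-by-species distance matrix (symmetric, zero diagonal).
#' @param weighted Use abundance weighting (default `TRUE`).
#' @return A single numeric value, or `NA` (with a warning) when fewer than
#'   two species are present: the metric is then undefined, not an error.
#' @export
mpd <- function(community, dist, weighted = TRUE) {
  sp <- names(community)[community > 0]
  miss <- setdiff(sp, rownames(dist))
  if (length(miss))
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(sp) < 2) {
    warning("fewer than 2 species present; MPD undefined")
    return(NA_real_)
  }
  d <- dist[sp, sp]
  if (!weighted) return(mean(d[lower.tri(d)]))
  f <- community[sp] / sum(community[sp])
  num <- drop(f %*% d %*% f)      # diagonal terms are zero by construction
  den <- 1 - sum(f^2)             # sum over i != j of f_i f_j
  num / den
}

#' Mean nearest taxon distance within a community
#'
#' For each species present, the distance to its nearest other present
#' species; the community value is the plain or relative-abundance weighted
#' mean of these nearest-neighbour distances.
#'
#' @inheritParams mpd
#' @return A single numeric value, or `NA` (with a warning) for
#'   single-species communities.
#' @export
mntd <- function(community, dist, weighted = TRUE) {
  sp <- names(community)[community > 0]
  miss <- setdiff(sp, rownames(dist))
  if (length(miss))
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(sp) < 2) {
    warning("fewer than 2 species present; MNTD undefined")
    return(NA_real_)
  }
  d <- dist[sp, sp]
  diag(d) <- Inf
  mins <- d[cbind(seq_along(sp), max.col(-d, ties.method = "first"))]
  if (!weighted) return(mean(mins))
  f <- community[sp] / sum(community[sp])
  sum(f * mins)
}

#' Richness-preserving null community
#'
#' Draws, without replacement, as many species from the pool as the
#' observed community holds, and reassigns the observed abundance vector to
#' the drawn species in random order. This randomizes species identity
#' while preserving both richness and the site's abundance distribution.
#'
#' @param community Named numeric abundance vector.
#' @param pool Character vector of pool species (must be at least as large
#'   as the community's richness).
#' @param seed Optional integer seed.
#' @return Named numeric abundance vector over the drawn species.
#' @export
null_richness <- function(community, pool, seed = NULL) {
  present <- community[community > 0]
  k <- length(present)
  if (length(pool) < k)
    stop("pool (", length(pool), ") smaller than community richness (", k, ")",
         call. = FALSE)
  with_seed_or_not(seed, {
    sp <- sample(pool, k)
    setNames(as.numeric(sample(present)), sp)
  })
}

#' Standardized effect size of alpha community structure
#'
#' For each site, compares the observed MPD or MNTD against a null
#' distribution built by redrawing the community's species (richness held
#' fixed) from the whole species pool — every species with nonzero total
#' abundance across the matrix. The standardized effect size is
#' `(obs - mean(null)) / sd(null)`; positive values indicate phylogenetic
#' or functional overdispersion, negative values clustering. SES(MPD) and
#' SES(MNTD) equal -NRI and -NTI respectively. The rank-based p-value is
#' `(number of null values <= obs + 1) / (n_null + 1)`.
#'
#' Sites where the null distribution is degenerate (`sd = 0`, e.g. a
#' community containing the entire pool) get `ses = NA` and are flagged in
#' the `flag` column; the run continues.
#'
#' @param comm Site-by-species abundance matrix (see [as_community_matrix()]).
#' @param dist Species-by-species distance matrix covering all pool species.
#' @param metric `"mpd"` or `"mntd"`.
#' @param weighted Abundance-weighted metric (default `TRUE`).
#' @param n_null Number of null communities per site (default 999).
#' @param seed Optional integer seed; fixed seed gives a bit-identical table.
#' @param metric_label Label written to the `metric` column (defaults to
#'   upper-case `metric`; use e.g. `"traitMPD"` for trait-space runs).
#' @return A data.frame with one row per site: `site`, `metric`, `ntaxa`,
#'   `obs`, `null_mean`, `null_sd`, `ses`, `p`, `n_null`, `flag`.
#' @export
ses_alpha <- function(comm, dist, metric = c("mpd", "mntd"), weighted = TRUE,
                      n_null = 999, seed = NULL,
                      metric_label = toupper(metric)) {
  metric <- match.arg(metric)
  metric_label <- metric_label[1]
  fun <- if (metric == "mpd") mpd else mntd
  check_distance_matrix(dist)
  pool <- colnames(comm)[colSums(comm) > 0]
  miss <- setdiff(pool, rownames(dist))
  if (length(miss))
    stop("pool species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  with_seed_or_not(seed, {
    rows <- lapply(rownames(comm), function(s) {
      cm <- comm[s, ]
      cm <- cm[cm > 0]
      obs <- suppressWarnings(fun(cm, dist, weighted))
      nulls <- vapply(seq_len(n_null), function(i)
        suppressWarnings(fun(null_richness(cm, pool), dist, weighted)),
        0)
      mu <- mean(nulls); sdv <- stats::sd(nulls)
      degenerate <- !is.finite(obs) || !is.finite(sdv) || sdv == 0
      data.frame(site = s, metric = metric_label, ntaxa = length(cm),
                 obs = obs, null_mean = mu, null_sd = sdv,
                 ses = if (degenerate) NA_real_ else (obs - mu) / sdv,
                 p = (sum(nulls <= obs) + 1) / (n_null + 1),
                 n_null = n_null,
                 flag = if (degenerate) "degenerate_null" else "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
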