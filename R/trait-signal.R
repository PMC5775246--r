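#' Blomberg's K statistic
#'
#' Strength of phylogenetic signal relative to Brownian-motion expectation:
#' the ratio of (mean squared error of tip values around the phylogenetic
#' mean) to (mean squared error under the phylogenetic variance-covariance
#' structure), divided by the same ratio expected under Brownian motion on
#' the given tree. K near 1 is consistent with Brownian evolution, K > 1
#' indicates trait conservatism (close relatives more similar than Brownian
#' expectation), K < 1 lability.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named numeric vector covering all tips; must not be constant.
#' @return A single non-negative numeric value.
#' @export
blomberg_k <- function(tree, trait) {
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("missing trait value for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.numeric(trait[tree$tip.label])
  if (stats::var(x) == 0) stop("constant trait: K undefined", call. = FALSE)
  V <- ape::vcv(tree)
  k_from_vcv(V, matrix(x, ncol = 1))[1]
}

# K for each column of X given the phylogenetic VCV; vectorized so the
# randomization p-value of K costs one pass.
k_from_vcv <- function(V, X) {
  n <- nrow(V)
  Vi <- solve(V)
  sum_vi <- sum(Vi)
  col_w <- colSums(Vi)                 # t(1) %*% Vi
  ahat <- drop(col_w %*% X) / sum_vi   # phylogenetic (GLS) mean per column
  E <- sweep(X, 2, ahat)
  mse0 <- colSums(E * E) / (n - 1)
  mse <- colSums(E * (Vi %*% E)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_vi) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test of phylogenetic signal
#'
#' The observed variance of the standardized independent contrasts of a
#' trait is compared with its distribution over `n_rand` random shuffles of
#' the trait values among the tips. A trait with phylogenetic signal has a
#' contrast variance in the low tail; one with antisignal, in the high
#' tail; the test is two-tailed at the extreme 2.5% ranks on each side
#' (25 ranks per tail at `n_rand = 1000`). Blomberg's K is reported for the
#' same trait, together with its own randomization p-value (upper tail:
#' shuffles rarely reach a high K).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named numeric vector over the tips; must not be constant.
#' @param n_rand Number of trait shuffles (default 1000).
#' @param seed Optional integer seed; fixed seed is bit-reproducible.
#' @return A one-row data.frame: `trait`, `K`, `p_K`, `pic_var_obs`,
#'   `pic_var_null_mean`, `p_rand` (rank of observed variance in the null,
#'   low tail), `n_rand`, `significant`.
#' @export
phylosignal_randomization <- function(tree, trait, n_rand = 1000, seed = NULL) {
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("missing trait value for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  btree <- resolve_polytomies(tree)
  x <- as.numeric(trait[btree$tip.label])
  if (stats::var(x) == 0)
    stop("constant trait: contrast variance degenerate", call. = FALSE)
  n <- length(x)
  with_seed_or_not(seed, {
    X <- cbind(x, vapply(seq_len(n_rand), function(i) sample(x), numeric(n)))
    cc <- pic_engine(btree, X)
    vars <- apply(cc, 2, stats::var)
    obs <- vars[1]
    null <- vars[-1]
    ks <- k_from_vcv(ape::vcv(btree), X)
    k_tail <- max(1L, round(0.025 * n_rand))
    rank_low <- sum(null < obs) + 1
    rank_high <- sum(null > obs) + 1
    data.frame(trait = "trait", K = ks[1],
               p_K = (sum(ks[-1] >= ks[1]) + 1) / (n_rand + 1),
               pic_var_obs = obs, pic_var_null_mean = mean(null),
               p_rand = (sum(null <= obs) + 1) / (n_rand + 1),
               n_rand = n_rand,
               significant = rank_low <= k_tail || rank_high <= k_tail,
               stringsAsFactors = FALSE)
  })
}

#' Phylogenetic signal for every column of a trait table
#'
#' @param tree A `phylo` object.
#' @param traits Numeric matrix, species in rows, traits in columns.
#' @param n_rand Number of shuffles per trait.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per trait (see
#'   [phylosignal_randomization()]).
#' @export
phylosignal_table <- function(tree, traits, n_rand = 1000, seed = NULL) {
  with_seed_or_not(seed, {
    rows <- lapply(colnames(traits), function(tr) {
      res <- phylosignal_randomization(tree, setNames(traits[, tr],
                                                      rownames(traits)),
                                       n_rand = n_rand)
      res$trait <- tr
      res
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
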