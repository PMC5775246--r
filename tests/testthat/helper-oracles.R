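# Naive loop-based oracles, kept deliberately independent of the package's
# vectorized implementations.

oracle_mpd <- function(community, d, weighted = TRUE) {
  sp <- names(community)[community > 0]
  if (!weighted) {
    tot <- 0; k <- 0
    for (a in seq_along(sp)) for (b in seq_along(sp)) if (a < b) {
      tot <- tot + d[sp[a], sp[b]]; k <- k + 1
    }
    return(tot / k)
  }
  f <- community[sp] / sum(community[sp])
  num <- 0; den <- 0
  for (a in seq_along(sp)) for (b in seq_along(sp)) if (a != b) {
    num <- num + d[sp[a], sp[b]] * f[a] * f[b]
    den <- den + f[a] * f[b]
  }
  unname(num / den)
}

oracle_mntd <- function(community, d, weighted = TRUE) {
  sp <- names(community)[community > 0]
  mins <- vapply(sp, function(a) min(d[a, setdiff(sp, a)]), 0)
  if (!weighted) return(mean(mins))
  f <- community[sp] / sum(community[sp])
  unname(sum(f * mins))
}

oracle_dpw <- function(k1, k2, d) {
  k1 <- k1[k1 > 0]; k2 <- k2[k2 > 0]
  f1 <- k1 / sum(k1); f2 <- k2 / sum(k2)
  tot <- 0
  for (a in names(f1)) for (b in names(f2))
    tot <- tot + d[a, b] * f1[a] * f2[b]
  unname(tot)
}

oracle_dnn <- function(k1, k2, d, halved = FALSE) {
  k1 <- k1[k1 > 0]; k2 <- k2[k2 > 0]
  f1 <- k1 / sum(k1); f2 <- k2 / sum(k2)
  t1 <- sum(vapply(names(f1), function(a) min(d[a, names(f2)]), 0) * f1)
  t2 <- sum(vapply(names(f2), function(b) min(d[names(f1), b]), 0) * f2)
  val <- (t1 + t2) / (sum(f1) * sum(f2))
  if (halved) val / 2 else val
}

# Brute-force patristic distance: sum edge lengths along the tip-to-tip
# node path.
oracle_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  tot <- 0
  for (k in seq_len(length(path) - 1)) {
    hit <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1]))
    tot <- tot + tree$edge.length[hit]
  }
  tot
}

# A random species pool with a distance matrix and a set of communities.
random_instance <- function(n_sp, n_site, seed = NULL) {
  gen <- function() {
    sp <- sprintf("s%02d", seq_len(n_sp))
    pts <- matrix(stats::rnorm(n_sp * 3), n_sp)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(sp, sp)
    comm <- matrix(stats::rpois(n_site * n_sp, 1), n_site, n_sp,
                   dimnames = list(sprintf("site%02d", seq_len(n_site)), sp))
    for (s in seq_len(n_site))
      while (sum(comm[s, ] > 0) < 2) comm[s, sample(n_sp, 2)] <- 1
    list(sp = sp, d = d, comm = comm)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

write_csv_tmp <- function(df, ...) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, f, row.names = FALSE, ...)
  f
}
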