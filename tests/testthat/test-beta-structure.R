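test_that("dpw and dnn match hand evaluations of the defining formulas", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 6
  d6 <- d; d6["A", "B"] <- d6["B", "A"] <- 6

  expect_equal(dpw(c(A = 1), c(B = 1), d6), 6)
  expect_equal(dpw(c(A = 1), c(B = 0.5, C = 0.5), d), 3)   # 2*.5 + 4*.5
  expect_equal(dpw(c(A = 1), c(A = 1), d), 0)

  expect_equal(dnn(c(A = 1), c(B = 1), d6), 12)
  expect_equal(dnn(c(A = 1), c(B = 1), d6, convention = "halved"), 6)
  # (min_A * 1) + (min_B * .5 + min_C * .5) = 2 + (2*.5 + 4*.5)
  expect_equal(dnn(c(A = 1), c(B = 0.5, C = 0.5), d), 5)
  expect_equal(dnn(c(A = 2, B = 1), c(A = 2, B = 1), d), 0)
  expect_equal(dnn(c(A = 2, B = 1), c(A = 2, B = 1), d, convention = "halved"), 0)
})

test_that("beta metrics are symmetric, scale with distances, and halved dnn is half of literal", {
  withr::with_seed(161, {
    for (i in 1:10) {
      inst <- random_instance(12, 2)
      k1 <- inst$comm[1, ]; k2 <- inst$comm[2, ]
      expect_equal(dpw(k1, k2, inst$d), dpw(k2, k1, inst$d))
      expect_equal(dnn(k1, k2, inst$d), dnn(k2, k1, inst$d))
      expect_equal(dpw(k1, k2, inst$d * 2.5), 2.5 * dpw(k1, k2, inst$d))
      expect_equal(dnn(k1, k2, inst$d * 2.5), 2.5 * dnn(k1, k2, inst$d))
      expect_equal(dnn(k1, k2, inst$d), 2 * dnn(k1, k2, inst$d, "halved"))
    }
  })
})

test_that("pairwise beta values equal the naive-loop oracles", {
  withr::with_seed(171, {
    for (i in 1:10) {
      inst <- random_instance(15, 2)
      k1 <- inst$comm[1, ]; k2 <- inst$comm[2, ]
      expect_equal(dpw(k1, k2, inst$d), oracle_dpw(k1, k2, inst$d),
                   tolerance = 1e-12)
      expect_equal(dnn(k1, k2, inst$d), oracle_dnn(k1, k2, inst$d),
                   tolerance = 1e-12)
    }
  })
})

test_that("beta_matrix agrees with per-pair calls and with picante", {
  withr::with_seed(181, {
    inst <- random_instance(14, 5)
    bp <- beta_matrix(inst$comm, inst$d, "dpw")
    bn <- beta_matrix(inst$comm, inst$d, "dnn", "halved")
    for (a in 1:4) for (b in (a + 1):5) {
      expect_equal(bp[a, b], dpw(inst$comm[a, ], inst$comm[b, ], inst$d))
      expect_equal(bn[a, b],
                   dnn(inst$comm[a, ], inst$comm[b, ], inst$d, "halved"))
    }
    skip_if_not_installed("picante")
    ref_pw <- as.matrix(picante::comdist(inst$comm, inst$d,
                                         abundance.weighted = TRUE))
    ref_nt <- as.matrix(picante::comdistnt(inst$comm, inst$d,
                                           abundance.weighted = TRUE))
    expect_equal(bp[lower.tri(bp)], ref_pw[lower.tri(ref_pw)],
                 tolerance = 1e-12)
    expect_equal(bn[lower.tri(bn)], ref_nt[lower.tri(ref_nt)],
                 tolerance = 1e-12)
  })
})

test_that("tip-shuffle null standardization is deterministic and flags exchangeable distances", {
  withr::with_seed(191, {
    inst <- random_instance(10, 4)
    b1 <- beta_null_standardize(inst$comm, inst$d, "dpw", n_null = 29, seed = 5)
    b2 <- beta_null_standardize(inst$comm, inst$d, "dpw", n_null = 29, seed = 5)
    expect_identical(b1, b2)
    ok <- is.finite(b1$ses)
    expect_equal(b1$ses[ok],
                 ((b1$obs - b1$null_mean) / b1$null_sd)[ok])

    # all off-diagonal distances equal: every shuffle reproduces the observed
    dflat <- matrix(1, 10, 10, dimnames = dimnames(inst$d))
    diag(dflat) <- 0
    bf <- beta_null_standardize(inst$comm, dflat, "dnn", n_null = 19, seed = 1)
    expect_true(all(is.na(bf$ses[lower.tri(bf$ses)])))
    expect_equal(bf$n_degenerate, 6)
    expect_error(beta_null_standardize(inst$comm, inst$d, "dpw", n_null = 0),
                 "n_null")
  })
})

test_that("per-pair beta SES self-calibrates on pool-draw communities", {
  # the SES deviations of all pairs within one dataset are strongly
  # correlated (they share one tree and one shuffle stream), so the
  # calibration property is assessed as a grand mean over independent
  # dataset draws
  withr::with_seed(201, {
    ms <- vapply(1:8, function(i) {
      tr <- simulate_tree(25)
      d <- cophenetic_matrix(tr)
      comm <- matrix(0, 30, 25, dimnames = list(sprintf("s%02d", 1:30),
                                                tr$tip.label))
      for (s in 1:30) {
        draw <- null_richness(setNames(rpois(8, 2) + 1,
                                       sample(tr$tip.label, 8)), tr$tip.label)
        comm[s, names(draw)] <- draw
      }
      b <- beta_null_standardize(comm, d, "dpw", n_null = 99)
      mean(b$ses[lower.tri(b$ses)], na.rm = TRUE)
    }, 0)
    expect_gt(mean(ms), -0.2)
    expect_lt(mean(ms), 0.2)
  })
})

test_that("region contrasts run ANOVA + Tukey HSD on region-pair groups", {
  withr::with_seed(211, {
    inst <- random_instance(10, 9)
    regions <- setNames(rep(c("west", "center", "east"), each = 3),
                        rownames(inst$comm))
    # two groups shifted by ~10 SDs must come out significant
    b <- matrix(0, 9, 9, dimnames = list(rownames(inst$comm),
                                         rownames(inst$comm)))
    base <- matrix(rnorm(81, 5, 0.1), 9)
    b[] <- (base + t(base)) / 2
    b[regions == "west", regions == "west"] <- 1   # far below everything else
    diag(b) <- 0
    rc <- region_contrast(b, regions)
    ww <- grepl("within_west", rc$tukey$contrast)
    expect_true(all(rc$tukey$p_adj[ww] < 0.001))
    expect_lt(rc$anova_p, 0.001)

    # no variation at all: no differences, adjusted p driven to 1
    flat <- matrix(1, 9, 9, dimnames = dimnames(b)); diag(flat) <- 0
    rcf <- region_contrast(flat, regions)
    expect_true(all(rcf$tukey$p_adj == 1))

    expect_error(region_contrast(b, setNames(rep("west", 9), rownames(b))),
                 "2 regions")
    expect_warning(
      region_contrast(b, setNames(c("west", rep(c("center", "east"), each = 4)),
                                  rownames(b))), "west")
  })
})

test_that("partial Mantel recovers exact self-correlation and residual-zero cases", {
  withr::with_seed(221, {
    m1 <- as.matrix(dist(matrix(rnorm(30), 15)))
    m2 <- as.matrix(dist(matrix(rnorm(30), 15)))
    self <- partial_mantel(m1, m1, n_perm = 99, seed = 2)
    expect_equal(self$r, 1)
    expect_equal(self$p, 1 / 100)
    ctrl <- partial_mantel(m1, m2, control = m2, n_perm = 99, seed = 2)
    expect_lt(abs(ctrl$r), 1e-10)
    expect_error(partial_mantel(m1, m2[1:10, 1:10]), "mismatch")
  })
})

test_that("Mantel statistics agree with vegan", {
  skip_if_not_installed("vegan")
  withr::with_seed(231, {
    m1 <- as.matrix(dist(matrix(rnorm(40), 20)))
    m2 <- as.matrix(dist(matrix(rnorm(40), 20)))
    m3 <- as.matrix(dist(matrix(rnorm(40), 20)))
    expect_equal(partial_mantel(m1, m2, n_perm = 9, seed = 1)$r,
                 unname(vegan::mantel(as.dist(m1), as.dist(m2),
                                      permutations = 9)$statistic),
                 tolerance = 1e-12)
    expect_equal(partial_mantel(m1, m2, control = m3, n_perm = 9, seed = 1)$r,
                 unname(vegan::mantel.partial(as.dist(m1), as.dist(m2),
                                              as.dist(m3),
                                              permutations = 9)$statistic),
                 tolerance = 1e-12)
  })
})
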