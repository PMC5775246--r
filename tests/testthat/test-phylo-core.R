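test_that("read_newick preserves minimal trees and rejects bad input", {
  t2 <- read_newick("(A:1,B:1);")
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(1, 1))

  t3 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 2)

  expect_error(read_newick("(A:1,A:1);"), "duplicate tip")
  expect_error(read_newick("((A:1,B:1:1,C:2);"), "position")
  expect_error(read_newick("(A:1,B:1));"), "position 10")
})

test_that("cophenetic distances equal the brute-force path-sum oracle", {
  t3 <- read_newick("((A:1,B:1):1,C:2);")
  d <- cophenetic_matrix(t3)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["A", "B"], 2)
  expect_error(cophenetic_matrix(read_newick("(A:1);")), "2 tips")

  withr::with_seed(21, {
    tr <- ape::rtree(20)
    d <- cophenetic_matrix(tr)
    for (pair in list(c(1, 2), c(3, 17), c(5, 20), c(9, 10), c(1, 20))) {
      a <- tr$tip.label[pair[1]]; b <- tr$tip.label[pair[2]]
      expect_lt(abs(d[a, b] - oracle_patristic(tr, a, b)), 1e-10)
    }
  })
})

test_that("cophenetic matrices are symmetric, zero-diagonal and ultrametric trees satisfy the three-point condition", {
  withr::with_seed(31, {
    for (i in 1:5) {
      tr <- ape::rcoal(12)
      d <- cophenetic_matrix(tr)
      expect_equal(d, t(d))
      expect_equal(unname(diag(d)), rep(0, 12))
      combs <- utils::combn(12, 3)
      for (k in seq_len(ncol(combs))) {
        trio <- sort(c(d[combs[1, k], combs[2, k]], d[combs[1, k], combs[3, k]],
                       d[combs[2, k], combs[3, k]]), decreasing = TRUE)
        expect_lt(trio[1] - trio[2], 1e-9)
      }
    }
  })
})

test_that("independent contrasts follow Felsenstein's algorithm", {
  ic <- independent_contrasts(read_newick("(A:1,B:1);"), c(A = 3, B = 5))
  expect_equal(abs(unname(ic$contrasts)), 2 / sqrt(2))

  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(unname(independent_contrasts(tr, c(A = 7, B = 7, C = 7))$contrasts),
               c(0, 0))
  expect_error(independent_contrasts(tr, c(A = 1, B = 2)), "C")

  # matches the reference implementation on random trees and traits
  withr::with_seed(41, {
    for (i in 1:5) {
      rt <- ape::rtree(15)
      x <- setNames(rnorm(15), rt$tip.label)
      mine <- sort(abs(unname(independent_contrasts(rt, x)$contrasts)))
      ref <- sort(abs(unname(ape::pic(x[rt$tip.label], rt))))
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  })
})

test_that("polytomies are resolved to give n - 1 contrasts", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  ic <- independent_contrasts(star, c(A = 1, B = 2, C = 3, D = 4, E = 5))
  expect_length(ic$contrasts, 4)
  expect_true(all(is.finite(ic$contrasts)))
})

test_that("correctly standardized contrasts show no trend with node height", {
  withr::with_seed(51, {
    ok <- 0
    for (i in 1:100) {
      tr <- ape::rcoal(50)
      x <- setNames(drop(simulate_bm_traits(tr, sigma2 = 1)), tr$tip.label)
      ic <- independent_contrasts(tr, x)
      depth <- ape::node.depth.edgelength(tr)
      h <- max(depth[1:50]) - depth[as.integer(names(ic$contrasts))]
      p <- summary(lm(abs(ic$contrasts) ~ h))$coefficients[2, 4]
      ok <- ok + (p > 0.05)
    }
    expect_gte(ok, 90)
  })
})

test_that("mcc_tree picks the topology maximizing the clade credibility product", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")

  same <- mcc_tree(list(t1, t1, t1, t1))
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(same, t1))), 0)
  expect_equal(ape::node.depth.edgelength(same), ape::node.depth.edgelength(t1))
  expect_equal(unique(same$node.label), 1)

  # 3 T1 + 1 T2: T1 score (3/4)^2 beats T2 score (1/4)^2
  pick <- mcc_tree(list(t1, t1, t2, t1))
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(pick, t1))), 0)

  # tie in the credibility product returns the first tree
  tie <- mcc_tree(list(t2, t1))
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(tie, t2))), 0)

  expect_error(mcc_tree(list(t1, read_newick("((A:1,B:1):1,(C:1,E:1):1);"))),
               "mismatched tip sets")
})

test_that("mcc_tree of a singleton list returns the input tree", {
  withr::with_seed(61, {
    tr <- ape::rcoal(10)
    out <- mcc_tree(list(tr))
    expect_equal(as.numeric(suppressWarnings(ape::dist.topo(out, tr))), 0)
    expect_equal(ape::node.depth.edgelength(out), ape::node.depth.edgelength(tr),
                 tolerance = 1e-12)
  })
})

test_that("mcc_tree agrees with phangorn's maximum clade credibility topology", {
  skip_if_not_installed("phangorn")
  withr::with_seed(71, {
    topos <- lapply(1:5, function(i) ape::rcoal(8, tip.label = paste0("t", 1:8)))
    trees <- topos[sample(1:5, 25, replace = TRUE, prob = c(8, 6, 5, 4, 2))]
    class(trees) <- "multiPhylo"
    mine <- mcc_tree(trees)
    ref <- phangorn::maxCladeCred(trees, rooted = TRUE)
    expect_equal(unname(phangorn::RF.dist(mine, ref)), 0)
  })
})
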