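test_that("Newick parsing validates and reports root age", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(attr(tr, "root_age"), 3)
  expect_true(attr(tr, "ultrametric"))
  expect_error(parse_newick("((A:1,B:1):2,C:3;"), "malformed")
  expect_error(parse_newick("((A:1,A:1):2,C:3);"), "duplicate")
  expect_error(parse_newick("((A:1,B):2,C:3);"), "branch length")
  expect_warning(as_dated_tree(ape::read.tree(text = "((A:1,B:2):2,C:3);")),
                 "not ultrametric")
})

test_that("tree serialization round-trips a simulated 49-tip tree", {
  tr <- simulate_tree(49, root_age = 340, seed = 11)
  txt <- ape::write.tree(tr)
  back <- parse_newick(txt)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(attr(back, "root_age"), 340, tolerance = 1e-6)
  D1 <- divergence_matrix(tr)
  D2 <- divergence_matrix(back)
  expect_equal(D1[rownames(D2), colnames(D2)], D2, tolerance = 1e-6)
})

test_that("MRCA ages match direct reading and the half-patristic oracle", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  expect_equal(mrca_age(tr, "A", "B"), 1)
  expect_equal(mrca_age(tr, "A", "C"), 3)
  expect_equal(mrca_age(tr, "C", "A"), 3)   # symmetry
  expect_error(mrca_age(tr, "A", "Z"), "unknown tip")

  # oracle: on an ultrametric tree the MRCA age is half the patristic
  # (sum-of-branch-lengths) distance between the tips
  set.seed(5)
  rt <- simulate_tree(24, root_age = 100, seed = 5)
  patristic <- stats::cophenetic(rt)
  tips <- rt$tip.label
  for (i in 1:12) {
    ab <- sample(tips, 2)
    expect_equal(mrca_age(rt, ab[1], ab[2]),
                 patristic[ab[1], ab[2]] / 2, tolerance = 1e-9)
  }
  D <- divergence_matrix(rt)
  expect_equal(D[tips, tips], patristic[tips, tips] / 2, tolerance = 1e-9)
})

test_that("pairwise-age overrides take precedence over the tree", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  ov <- data.frame(host_a = "A", host_b = "C", divergence_mya = 42)
  expect_equal(mrca_age(tr, "A", "C", overrides = ov), 42)
  expect_equal(mrca_age(tr, "C", "A", overrides = ov), 42)  # unordered
  expect_equal(mrca_age(tr, "A", "B", overrides = ov), 1)
})

test_that("closest native host minimizes divergence with declared tie-break", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  res <- closest_native_host(tr, "A", c("B", "C"))
  expect_equal(res$native_host, "B")
  expect_equal(res$divergence_mya, 1)
  expect_false(res$conspecific)

  consp <- closest_native_host(tr, "A", c("A", "C"))
  expect_equal(consp$native_host, "A")
  expect_equal(consp$divergence_mya, 0)
  expect_true(consp$conspecific)

  tie <- parse_newick("((B:1,(A:0.5,Z:0.5):0.5):2,C:3);")
  res <- closest_native_host(tie, "B", c("Z", "A"))  # both at age 1
  expect_equal(res$native_host, "A")                 # lexicographic
  expect_error(closest_native_host(tr, "A", character(0)), "native hosts")

  # monotone under host-list growth
  r12 <- closest_native_host(tr, "A", c("B", "C"))
  r1 <- closest_native_host(tr, "A", "B")
  r2 <- closest_native_host(tr, "A", "C")
  expect_lte(r12$divergence_mya, min(r1$divergence_mya, r2$divergence_mya))
})

test_that("Blomberg's K is 1 on star phylogenies and affine-invariant", {
  star <- parse_newick("(A:2,B:2,C:2,D:2,E:2);")
  x <- c(A = 0.3, B = -1, C = 2.2, D = 0, E = 5)
  expect_equal(blomberg_k(star, x), 1, tolerance = 1e-10)
  # affine invariance on a structured tree
  tr <- simulate_tree(16, root_age = 50, seed = 3)
  y <- simulate_bm_traits(tr, sigma2 = 1, seed = 3)
  expect_equal(blomberg_k(tr, 10 - 3.7 * y), blomberg_k(tr, y),
               tolerance = 1e-10)
  expect_error(blomberg_k(tr, rep(1, 16)), "constant")
  expect_error(blomberg_k(parse_newick("((A:1,B:1):1,C:2);"), c(1, 2, 3)),
               "at least 4")
})

test_that("K agrees with the independent picante implementation", {
  tr <- simulate_tree(32, root_age = 120, seed = 9)
  for (s in 1:5) {
    x <- simulate_bm_traits(tr, sigma2 = 0.5, seed = 100 + s)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-6)
  }
})

test_that("K is near 1 under Brownian motion and small after permutation", {
  tr <- simulate_tree(64, root_age = 200, seed = 21)
  set.seed(77)
  ks <- replicate(150, blomberg_k(tr, simulate_bm_traits(tr, 1)))
  expect_gt(mean(ks), 0.9)
  expect_lt(mean(ks), 1.1)
  # permuting tip values across a deep-nested tree destroys signal
  x <- simulate_bm_traits(tr, 1, seed = 8)
  set.seed(9)
  kp <- replicate(100, blomberg_k(tr, setNames(sample(x), names(x))))
  expect_lt(median(kp), 0.5)
})

test_that("randomization test detects signal and bounds its p-value", {
  tr <- simulate_tree(48, root_age = 150, seed = 13)
  x <- simulate_bm_traits(tr, 1, seed = 13)
  res <- k_randomization_test(tr, x, n_rand = 199, seed = 1)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / (res$n_randomizations + 1))
  expect_lte(res$p_value, 1)
  # n_rand = 1 gives p = 1 when the permuted K beats the observed
  r1 <- k_randomization_test(tr, x, n_rand = 1, seed = 2)
  expect_true(r1$p_value %in% c(0.5, 1))
})

test_that("randomization test is calibrated under the null", {
  tr <- simulate_tree(32, root_age = 100, seed = 31)
  set.seed(123)
  rej <- replicate(200, {
    x <- stats::rnorm(32)                 # independent of the phylogeny
    names(x) <- tr$tip.label
    k_randomization_test(tr, x, n_rand = 99)$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("ordinal tolerance levels code as consecutive integers", {
  expect_identical(encode_ordinal(c("none", "low", "moderate", "high")),
                   0:3)
  expect_identical(encode_ordinal("medium"), 2L)   # synonym of moderate
  expect_identical(encode_ordinal("high"), 3L)
  expect_identical(encode_ordinal("none"), 0L)
  expect_identical(encode_ordinal(c("low", "high"),
                                  levels = c("low", "moderate", "high")),
                   c(0L, 2L))
  expect_error(encode_ordinal("extreme"), "unknown ordinal")
})
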