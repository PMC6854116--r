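# closed-form oracle for a single binary predictor: the MLE reproduces
# the group log-odds exactly
group_logodds_oracle <- function(n0, s0, n1, s1) {
  c(intercept = log(s0 / (n0 - s0)),
    slope = log(s1 / (n1 - s1)) - log(s0 / (n0 - s0)))
}

two_group_data <- function(n0, s0, n1, s1) {
  data.frame(y = c(rep(1, s0), rep(0, n0 - s0), rep(1, s1), rep(0, n1 - s1)),
             g = rep(c(0, 1), c(n0, n1)))
}

test_that("logistic MLE equals the group log-odds closed form", {
  # the congener-model configuration: 128 pairs without a congener (13
  # high impact), 75 with (1 high impact)
  d <- two_group_data(128, 13, 75, 1)
  fit <- fit_logistic(y ~ g, d)
  expect_equal(unname(round(coef(fit), 3)), c(-2.180, -2.124))
  oracle <- group_logodds_oracle(128, 13, 75, 1)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-7)

  # every small two-group configuration with nonzero cells
  for (n0 in 3:5) for (n1 in 3:5) for (s0 in 1:(n0 - 1)) for (s1 in 1:(n1 - 1)) {
    f <- fit_logistic(y ~ g, two_group_data(n0, s0, n1, s1))
    o <- group_logodds_oracle(n0, s0, n1, s1)
    expect_equal(unname(coef(f)), unname(o), tolerance = 1e-6)
  }
})

test_that("intercept-only fit equals the log prevalence odds", {
  d <- data.frame(y = rep(c(1, 0), c(14, 189)))
  fit <- fit_logistic(y ~ 1, d)
  expect_equal(unname(coef(fit)), log(14 / 189), tolerance = 1e-8)
  expect_equal(fit$K, 1)
  expect_equal(fit$n, 203)
})

test_that("degenerate and deficient designs are refused with clear errors", {
  expect_error(fit_logistic(y ~ x, data.frame(y = rep(0, 10), x = rnorm(10))),
               "single-class")
  d <- data.frame(y = rep(c(0, 1), 10), a = rep(c(0, 1), 10))
  d$b <- d$a * 2                              # aliased
  expect_error(fit_logistic(y ~ a + b, d), "aliased")
})

test_that("separation is flagged, not silently penalized", {
  d <- data.frame(y = rep(c(0, 1), each = 20), x = c(rnorm(20), rnorm(20) + 50))
  fit <- suppressWarnings(fit_logistic(y ~ x, d))
  expect_true(fit$separation)
  rid <- suppressWarnings(fit_logistic(y ~ x, d, ridge = 1e-6))
  expect_s3_class(rid, "risk_fit")          # ridge path stays available
})

test_that("AICc matches the published congener table and its limit", {
  d <- two_group_data(128, 13, 75, 1)
  f1 <- fit_logistic(y ~ g, d)
  f0 <- fit_logistic(y ~ 1, d)
  expect_equal(aicc(f1), 98.778, tolerance = 5e-4)
  expect_equal(aicc(f0), 103.908, tolerance = 5e-4)
  # AICc -> AIC as n grows with K fixed
  ll <- -50; K <- 3
  expect_equal(aicc(ll, K, 1e8), -2 * ll + 2 * K, tolerance = 1e-5)
  expect_error(aicc(ll, K, 4), "n")
})

test_that("Akaike weights reproduce the published top weights", {
  w4 <- akaike_weights(c(98.778, 103.908, 104.958))
  expect_equal(round(w4[1], 2), 0.89)
  t3 <- published_rankings()$host_traits
  w3 <- akaike_weights(t3$AICc)
  expect_equal(round(w3[1], 2), 0.79)
  expect_equal(sum(w3), 1, tolerance = 1e-9)
  # invariance to score shifts; single model gets weight 1
  expect_equal(akaike_weights(c(10, 12) + 57), akaike_weights(c(10, 12)))
  expect_equal(akaike_weights(42), 1)
})

test_that("model ranking sorts, weights, and forms the confidence set", {
  set.seed(1)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-2 + 1.5 * d$x))
  rk <- rank_models(list(null = y ~ 1, x = y ~ x, z = y ~ z,
                         xz = y ~ x + z), d)
  tab <- rk$table
  expect_equal(tab$delta_AICc[1], 0)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true("x" %in% confidence_set(rk))
  expect_false("null" %in% confidence_set(rk))
  # two identical designs share the weight equally
  rk2 <- rank_models(list(a = y ~ x, b = y ~ x), d)
  expect_equal(rk2$table$weight, c(0.5, 0.5), tolerance = 1e-9)
  # failing candidates are dropped with a warning, not fatal
  expect_warning(
    rk3 <- rank_models(list(ok = y ~ x, bad = y ~ I(x * 0)), d),
    "dropped")
  expect_equal(nrow(rk3$table), 1)
})

test_that("published confidence sets follow from the printed AICc columns", {
  pr <- published_rankings()
  in_set <- function(tab) tab$model[tab$AICc - min(tab$AICc) <= 2]
  expect_identical(in_set(pr$insect_evolution), "shared_genus")
  expect_setequal(in_set(pr$insect_traits),
                  c("voltinism",
                    "voltinism + reproductive_strategy + dispersal",
                    "reproductive_strategy", "null"))
  expect_identical(in_set(pr$host_traits),
                   "shade_tolerance + drought_tolerance")
})

test_that("Nagelkerke R2 matches the congener value and its bounds", {
  d <- two_group_data(128, 13, 75, 1)
  f1 <- fit_logistic(y ~ g, d)
  f0 <- fit_logistic(y ~ 1, d)
  expect_equal(round(nagelkerke_r2(f1, f0), 2), 0.09)
  expect_equal(nagelkerke_r2(f0, f0), 0)
  # near-perfect separation pushes R2 towards 1
  set.seed(2)
  dd <- data.frame(y = rep(c(0, 1), each = 50),
                   x = c(rnorm(50), rnorm(50) + 30))
  fs <- suppressWarnings(fit_logistic(y ~ x, dd))
  expect_gt(nagelkerke_r2(fs), 0.95)
})

test_that("G2 likelihood-ratio test: identity, power, nesting checks", {
  set.seed(3)
  d <- data.frame(x = rnorm(100))
  d$y <- rbinom(100, 1, plogis(d$x))
  f <- fit_logistic(y ~ x, d)
  same <- lr_test(f, f)
  expect_equal(same$G2, 0)
  expect_equal(same$p_value, 1)
  expect_error(lr_test(fit_logistic(y ~ x, d),
                       fit_logistic(y ~ I(2 * x), d)), "not nested")

  # power against a strong interaction (generating coefficient 2)
  set.seed(4)
  rej <- replicate(100, {
    n <- 500
    dd <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.5))
    dd$y <- rbinom(n, 1, plogis(-1 + 0.5 * dd$x + 2 * dd$x * dd$g))
    full <- fit_logistic(y ~ x * g, dd)
    nested <- fit_logistic(y ~ x + g, dd)
    lr_test(nested, full)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("predictions invert the logit at the published coefficients", {
  d <- two_group_data(128, 13, 75, 1)
  f1 <- fit_logistic(y ~ g, d)
  expect_equal(round(predict_prob(f1, data.frame(g = 0)), 3), 0.102)
  expect_equal(round(predict_prob(f1, data.frame(g = 1)), 3), 0.013)
  expect_equal(inv_logit(0), 0.5)
  # logit / inverse logit are mutual inverses
  p <- c(1e-12, 1e-6, 0.072, 0.5, 0.93, 1 - 1e-12)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
  x <- c(-700, -30, -5, 0, 5, 15)
  expect_equal(logit(inv_logit(x)), x, tolerance = 1e-6)
})

test_that("coefficients are recovered within 3 SE from simulated data", {
  set.seed(6)
  truth <- c(-2.5, 1.2, -0.8)
  hit <- replicate(100, {
    n <- 2000
    d <- data.frame(x = rnorm(n), w = rbinom(n, 1, 0.4))
    d$y <- rbinom(n, 1, plogis(truth[1] + truth[2] * d$x + truth[3] * d$w))
    f <- fit_logistic(y ~ x + w, d)
    all(abs(coef(f) - truth) <= 3 * f$se)
  })
  expect_gte(mean(hit), 0.95)
})
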