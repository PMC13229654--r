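test_that("Price equation: weighted-mean and covariance forms agree", {
  expect_equal(price_change(c(0, 1), c(1, 3)), 0.25)
  # covariance form, population moments
  covp <- function(a, b) mean(a * b) - mean(a) * mean(b)
  set.seed(4)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    th <- rnorm(n, 0, 3)
    mu <- rexp(n)
    expect_equal(price_change(th, mu), covp(th, mu) / mean(mu),
                 tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(price_change(rep(2, 5), rexp(5)), 0)
  expect_equal(price_change(rnorm(5), rep(1.7, 5)), 0, tolerance = 1e-15)
  expect_error(price_change(c(1, 2), c(0, 0)), "positive")
})

test_that("selection change is var/mean, nonnegative, scale equivariant", {
  expect_equal(selection_change(c(1, 2, 3))$estimate, 1 / 3)
  expect_equal(selection_change(c(0, 4))$estimate, 2)
  expect_equal(selection_change(rep(5, 4))$estimate, 0)
  # matches the weighted-mean form of the Price equation with trait = fitness
  set.seed(9)
  for (i in 1:100) {
    mu <- rexp(sample(2:30, 1))
    sel <- selection_change(mu)$estimate
    expect_equal(sel, price_change(mu, mu), tolerance = 1e-12)
    expect_gte(sel, 0)
    c_ <- runif(1, 0.1, 10)
    expect_equal(selection_change(c_ * mu)$estimate, c_ * sel,
                 tolerance = 1e-10)
  }
  expect_error(selection_change(c(-1, 2)), "nonnegative")
})

test_that("before + selection = after, and after >= before", {
  expect_equal(after_selection_mean(c(1, 2, 3))$estimate, 14 / 6)
  expect_equal(after_selection_mean(rep(2.5, 3))$estimate, 2.5)
  set.seed(10)
  for (i in 1:100) {
    mu <- rexp(sample(1:30, 1)) + 1e-6
    before <- mean(mu)
    after <- after_selection_mean(mu)$estimate
    expect_equal(before + selection_change(mu)$estimate, after,
                 tolerance = 1e-12)
    expect_gte(after, before)
  }
})

test_that("environmental change is the difference of replicate-cohort means", {
  pr <- cohort_pair(c(a = 1, b = 3), c(a = 2, b = 2), c(a = 1, b = 1))
  expect_equal(environmental_change(pr)$estimate, 0)
  pr <- cohort_pair(c(a = 1, b = 1), c(a = 3, b = 5), c(a = 1, b = 1))
  expect_equal(environmental_change(pr)$estimate, 3)
  # independent cohorts: squared SEs add
  v1 <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  mu1 <- c(a = 1, b = 2); attr(mu1, "cov") <- v1
  mu2 <- c(a = 2, b = 3); attr(mu2, "cov") <- 2 * v1
  pr <- cohort_pair(mu1, mu2, mu1)
  expect_equal(environmental_change(pr)$se,
               sqrt(sum(v1) / 4 + sum(2 * v1) / 4), tolerance = 1e-12)
})

test_that("total change corrects family representation and collapses to selection", {
  pr <- cohort_pair(c(a = 1, b = 3), c(a = 1, b = 3), c(a = 2, b = 1))
  expect_equal(total_change(pr)$estimate, -0.75)
  # mu_off = mu_prev collapses exactly to the selection change
  mu <- c(a = 1, b = 2, c = 3)
  pr <- cohort_pair(mu, mu, mu)
  expect_identical(total_change(pr)$estimate,
                   selection_change(mu)$estimate)
  # constant offspring fitness: weights average to one
  set.seed(12)
  mu_prev <- rexp(8); names(mu_prev) <- letters[1:8]
  cc <- 2.2
  pr <- cohort_pair(mu_prev, mu_prev, stats::setNames(rep(cc, 8), letters[1:8]))
  expect_equal(total_change(pr)$estimate, cc - mean(mu_prev),
               tolerance = 1e-12)
})

test_that("the partition sums exactly and aligns lineages", {
  pr <- cohort_pair(c(a = 1, b = 3), c(a = 2, b = 2), c(a = 2, b = 1))
  expect_equal(residual_change(pr)$estimate, -1.25)
  part <- partition_change(pr)
  expect_identical(part$estimate[part$component == "total"],
                   sum(part$estimate[part$component != "total"]))
  # misaligned lineages are dropped with a message, then partition still sums
  expect_message(
    pr2 <- cohort_pair(c(a = 1, b = 3, z = 2), c(a = 2, b = 2),
                       c(a = 2, b = 1, q = 5)),
    "dropping")
  expect_identical(pr2$lineages, c("a", "b"))
  expect_error(cohort_pair(c(a = 1), c(x = 1), c(y = 1)), "common")
})

test_that("partition SEs propagate the joint within-cohort covariance", {
  set.seed(17)
  n <- 12
  mk <- function() {
    A <- matrix(rnorm(n * n, 0, 0.05), n)
    V <- crossprod(A)
    mu <- rexp(n) + 0.2
    names(mu) <- paste0("s", 1:n)
    attr(mu, "cov") <- V
    mu
  }
  pr <- cohort_pair(mk(), mk(), mk())
  part <- partition_change(pr)
  expect_true(all(is.finite(part$se)) && all(part$se > 0))
  # residual SE from the joint gradient differs from naive subtraction and
  # is checked against a Monte-Carlo delta: simulate Gaussian perturbations
  mu_p <- pr$prev$mu; mu_r <- pr$par$mu; mu_o <- pr$off$mu
  chol_p <- chol(pr$prev$cov); chol_r <- chol(pr$par$cov)
  chol_o <- chol(pr$off$cov)
  res_fun <- function(p, r, o) {
    tot <- mean(o * p / mean(p)) - mean(p)
    sel <- (mean(p^2) - mean(p)^2) / mean(p)
    env <- mean(r) - mean(p)
    tot - sel - env
  }
  set.seed(18)
  sims <- replicate(4000, {
    res_fun(mu_p + drop(rnorm(n) %*% chol_p),
            mu_r + drop(rnorm(n) %*% chol_r),
            mu_o + drop(rnorm(n) %*% chol_o))
  })
  mc_se <- sd(sims)
  expect_equal(part$se[part$component == "residual"], mc_se,
               tolerance = 0.1)
})

test_that("FTNS prediction is Va(W)/mean and matches selection on familial fitness", {
  expect_equal(ftns_prediction(2, 4), 0.5)
  expect_equal(ftns_prediction(0, 3), 0)
  expect_error(ftns_prediction(1, 0), "positive")
  expect_error(ftns_prediction(-1, 1), "nonnegative")
  # with familial fitnesses as the trait, var/mean is the same formula
  mu <- c(1.1, 0.4, 2.3, 1.7)
  expect_equal(ftns_prediction(mean(mu^2) - mean(mu)^2, mean(mu)),
               selection_change(mu)$estimate)
})

test_that("confidence intervals use the requested normal quantile", {
  mu <- c(a = 1, b = 2, c = 4); attr(mu, "cov") <- diag(0.01, 3)
  pr <- cohort_pair(mu, mu, mu)
  p95 <- partition_change(pr, conf = 0.95)
  expect_equal(p95$ci_hi - p95$estimate, qnorm(0.975) * p95$se,
               tolerance = 1e-12)
  expect_error(partition_change(pr, conf = 1.2))
})
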