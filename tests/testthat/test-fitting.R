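test_that("fixed fit solves closed-form single-node problems", {
  d <- data.frame(y = rep(c(1L, 0L), c(7, 3)), sire = "a")
  f <- fit_aster(bern_graph(), d, aster_spec(random = NULL))
  expect_equal(unname(f$beta), log(7 / 3), tolerance = 1e-8)
  expect_equal(plogis(unname(f$beta)), 0.7, tolerance = 1e-8)
  expect_true(f$converged)

  # 12 seeds on 4 unit predecessors -> conditional mean 3
  d <- data.frame(y = c(3L, 4L, 2L, 3L), sire = "a")
  f <- fit_aster(pois_graph(), d, aster_spec(random = NULL))
  expect_equal(exp(unname(f$beta)), 3, tolerance = 1e-8)
})

test_that("fixed fit is invariant to row order and recovers truth", {
  set.seed(5)
  design <- small_design()
  truth <- plain_truth(sigma2_sire = 0)
  dat <- simulate_cohort(design, truth, year = 1)
  g <- default_fitness_graph()
  f1 <- fit_aster(g, dat, aster_spec(random = NULL))
  f2 <- fit_aster(g, dat[sample(nrow(dat)), ], aster_spec(random = NULL))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  # consistency: with n = 800 per node the saturated estimates sit near truth
  th_true <- truth$theta0[["1"]]
  phi_true <- theta_to_phi(g, th_true)
  se_ok <- sqrt(diag(solve(f1$fisher_info)))
  est <- unname(f1$beta)
  expect_true(all(abs(est - unname(phi_true)) < 4 * se_ok + 0.05))
})

test_that("mixed fit degenerates to the fixed fit at the boundary", {
  set.seed(8)
  design <- small_design()
  truth <- plain_truth(sigma2_sire = 0)
  dat <- simulate_cohort(design, truth, year = 1)
  g <- default_fitness_graph()
  fr <- fit_aster(g, dat)
  ff <- fit_aster(g, dat, aster_spec(random = NULL))
  if (fr$sigma2 == 0) {
    expect_equal(unname(fr$beta), unname(ff$beta), tolerance = 1e-6)
    expect_true(all(fr$b == 0))
    expect_equal(fr$loglik, ff$loglik, tolerance = 1e-8)
  } else {
    # small positive estimates can occur by sampling noise
    expect_lt(fr$sigma2, 0.05)
  }
})

test_that("mixed fit recovers the sire variance component", {
  # 50 sires x 60 offspring at sigma2 = 0.25; average over replicates
  design <- crossing_design(n_sires = 50, dams_per_sire = 3,
                            seeds_per_family = 20, locations_per_family = 4,
                            seeds_per_location = 5)
  truth <- plain_truth(sigma2_sire = 0.25)
  g <- default_fitness_graph()
  set.seed(21)
  s2 <- replicate(8, fit_aster(g, simulate_cohort(design, truth, year = 1))$sigma2)
  expect_lt(abs(mean(s2) - 0.25) / 0.25, 0.25)
})

test_that("mixed fit is invariant to permuting sire labels", {
  set.seed(13)
  dat <- simulate_cohort(small_design(), plain_truth(), year = 1)
  g <- default_fitness_graph()
  f1 <- fit_aster(g, dat)
  perm <- sample(unique(dat$sire))
  names(perm) <- unique(dat$sire)
  dat2 <- dat
  dat2$sire <- unname(perm[dat$sire])
  f2 <- fit_aster(g, dat2)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-5)
  expect_equal(sort(unname(f1$b)), sort(unname(f2$b)), tolerance = 1e-5)
})

test_that("mixed fit agrees with an independent Poisson GLMM fit", {
  skip_if_not_installed("lme4")
  # the seed node subproblem is exactly a Poisson mixed regression with
  # the sampled pod count as exposure; lme4 is the independent route
  set.seed(99)
  design <- crossing_design(n_sires = 50, dams_per_sire = 3,
                            seeds_per_family = 20, locations_per_family = 4,
                            seeds_per_location = 5)
  dat <- simulate_cohort(design, plain_truth(sigma2_sire = 0.25), year = 1)
  fit <- fit_aster(default_fitness_graph(), dat)
  sub <- dat[dat$sample_pods > 0, ]
  gm <- lme4::glmer(seeds ~ 1 + (1 | sire), offset = log(sub$sample_pods),
                    family = poisson, data = sub)
  expect_equal(unname(fit$beta["Seeds:(Intercept)"]),
               unname(lme4::fixef(gm)), tolerance = 0.02)
  expect_equal(fit$sigma2, unname(lme4::VarCorr(gm)$sire[1]),
               tolerance = 0.05)
})

test_that("familial fitness maps random effects through the mean-value scale", {
  # two sires at b = -log 2, +log 2 on a Poisson fitness node with theta0 = 0
  fit <- manual_pois_fit(0, c(a = -log(2), b = log(2)))
  ffs <- familial_fitness(fit)
  expect_equal(ffs$mu, c(0.5, 2.0), tolerance = 1e-8)
  # no familial spread: all b = 0 gives equal fitness = cell fitted mean
  fit0 <- manual_pois_fit(0.3, c(a = 0, b = 0, c = 0))
  ffs0 <- familial_fitness(fit0)
  expect_equal(ffs0$mu, rep(exp(0.3), 3), tolerance = 1e-8)
  # monotone: sorting by b sorts mu identically
  set.seed(2)
  b <- stats::setNames(rnorm(10), paste0("s", 1:10))
  ffs <- familial_fitness(manual_pois_fit(0.1, b, diag(11)))
  expect_identical(order(ffs$mu), order(b))
})

test_that("familial fitness covariance is PSD and drives cohort SE", {
  set.seed(31)
  dat <- simulate_cohort(small_design(), plain_truth(), year = 1)
  fit <- fit_aster(default_fitness_graph(), dat)
  ffs <- familial_fitness(fit)
  expect_true(all(ffs$mu >= 0))
  V <- attr(ffs, "cov")
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  cm <- cohort_mean_fitness(ffs)
  expect_equal(cm$estimate, mean(ffs$mu))
  expect_equal(cm$se, sqrt(sum(V)) / nrow(ffs), tolerance = 1e-10)
})

test_that("delta method reproduces the binomial standard error", {
  d <- data.frame(y = rep(c(1L, 0L), c(7, 3)), sire = "a")
  f <- fit_aster(bern_graph(), d, aster_spec(random = NULL))
  p <- plogis(unname(f$beta))
  se <- delta_method_se(f$fisher_info, p * (1 - p))
  expect_equal(se, sqrt(0.7 * 0.3 / 10), tolerance = 1e-6)
  # zero gradient -> zero SE; homogeneity in the gradient
  expect_equal(delta_method_se(f$fisher_info, 0), 0)
  expect_equal(delta_method_se(f$fisher_info, 3 * p * (1 - p)), 3 * se,
               tolerance = 1e-10)
  expect_error(delta_method_se(matrix(0, 1, 1), 1))
})

test_that("Va(W) quadrature matches the lognormal closed form", {
  # exp(Z), Z ~ N(0, s2) has variance exp(2 s2) - exp(s2)
  expect_equal(4 * va_quadrature(0.04, exp),
               4 * (exp(0.08) - exp(0.04)), tolerance = 1e-6)
  expect_equal(va_quadrature(0, exp), 0)
  fit <- manual_pois_fit(0, c(a = 0, b = 0))
  fit$sigma2 <- 0.04
  expect_equal(estimate_va(fit)$va_w, 4 * (exp(0.08) - exp(0.04)),
               tolerance = 1e-6)
  fit$sigma2 <- 0
  expect_equal(estimate_va(fit)$va_w, 0)
})

test_that("selection SE from one cohort is below the two-cohort environmental SE", {
  set.seed(77)
  design <- small_design()
  truth <- plain_truth(sigma2_sire = 0.2)
  g <- default_fitness_graph()
  d1 <- simulate_cohort(design, truth, year = 1)
  d2 <- simulate_cohort(design, truth, year = 2,
                        sire_effects = attr(d1, "sire_effects"))
  f1 <- familial_fitness(fit_aster(g, d1))
  f2 <- familial_fitness(fit_aster(g, d2))
  sel <- selection_change(f1$mu, attr(f1, "cov"))
  env <- environmental_change(stats::setNames(f2$mu, f2$sire),
                              stats::setNames(f1$mu, f1$sire),
                              attr(f2, "cov"), attr(f1, "cov"))
  expect_lt(sel$se, env$se)
})
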