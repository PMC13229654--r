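## Price-equation partition of the intergenerational change in mean
## fitness: selection (within-generation), environmental (between replicate
## pedigreed cohorts across years), subsampling-corrected total change, and
## the residual remainder, each with delta-method standard errors treating
## distinct cohorts as independent. Population (divisor n) moments are used
## throughout so the weighted-mean and covariance forms agree exactly.

.varp <- function(x) mean(x^2) - mean(x)^2
.covp <- function(x, y) mean(x * y) - mean(x) * mean(y)

.check_mu <- function(mu) {
  if (length(mu) == 0 || any(!is.finite(mu)) || any(mu < 0))
    stop("fitness vector must be nonnegative and finite")
  if (all(mu == 0)) stop("fitness vector must have a positive entry")
}

#' Change in a trait mean due to selection (Price equation)
#'
#' The difference between the fitness-weighted and unweighted means of a
#' trait: `mean(trait * fitness / mean(fitness)) - mean(trait)`, which
#' equals `cov(trait, fitness) / mean(fitness)` with population moments.
#'
#' @param trait Numeric vector of per-family trait values.
#' @param fitness Nonnegative numeric vector of per-family fitnesses, same
#'   length, not all zero.
#' @return Scalar change in the trait mean.
#' @export
price_change <- function(trait, fitness) {
  stopifnot(length(trait) == length(fitness))
  .check_mu(fitness)
  mean(trait * fitness / mean(fitness)) - mean(trait)
}

## gradient of selection change wrt mu, population moments
.grad_selection <- function(mu) {
  n <- length(mu); m <- mean(mu); m2 <- mean(mu^2)
  (2 * mu / n) / m - m2 / (m^2 * n) - 1 / n
}

#' Within-generation change in mean fitness due to selection
#'
#' The Price equation with the trait taken to be fitness itself:
#' `var(mu) / mean(mu)` (population variance), always nonnegative and zero
#' exactly when the familial fitnesses are constant.
#'
#' @param mu Nonnegative vector of familial mean fitnesses (the parental
#'   cohort in its own year).
#' @param cov Optional covariance matrix of `mu` for a delta-method
#'   standard error.
#' @return List with `estimate` and `se` (`NA` if `cov` is missing).
#' @export
selection_change <- function(mu, cov = NULL) {
  .check_mu(mu)
  ## weighted-minus-unweighted-mean form, the same expression the total
  ## change evaluates, so the two collapse bitwise when mu_off = mu_prev;
  ## round-off on constant input is clamped to the exact zero it represents
  est <- mean(mu * mu / mean(mu)) - mean(mu)
  if (est < 0) est <- 0
  se <- if (is.null(cov)) NA_real_ else {
    g <- .grad_selection(mu)
    sqrt(max(drop(crossprod(g, cov %*% g)), 0))
  }
  list(estimate = est, se = se)
}

#' Fitness-weighted ("after selection") cohort mean fitness
#'
#' `mean(mu * mu / mean(mu))`, the weighted average of familial fitnesses
#' with weights proportional to fitness; never below the unweighted mean,
#' and the unweighted mean plus [selection_change()] exactly.
#'
#' @inheritParams selection_change
#' @return List with `estimate` and `se`.
#' @export
after_selection_mean <- function(mu, cov = NULL) {
  .check_mu(mu)
  n <- length(mu); m <- mean(mu)
  est <- mean(mu^2) / m
  se <- if (is.null(cov)) NA_real_ else {
    g <- (2 * mu / n) / m - mean(mu^2) / (m^2 * n)
    sqrt(max(drop(crossprod(g, cov %*% g)), 0))
  }
  list(estimate = est, se = se)
}

#' Pair familial fitness sets for partitioning
#'
#' Aligns, by sire lineage, the familial fitnesses of the parental cohort
#' in year 1 (`prev`), the replicate pedigreed cohort grown in year 2
#' (`par`), and the offspring cohort in year 2 (`off`, indexed by maternal
#' grandsire). Lineages absent from any cohort are dropped with a message.
#'
#' @param prev,par,off `"familial_fitness"` objects, or named numeric
#'   vectors (optionally carrying a covariance matrix in `attr(, "cov")`).
#' @return An object of class `"cohort_pair"` with aligned `mu_prev`,
#'   `mu_par`, `mu_off` and covariance blocks.
#' @export
cohort_pair <- function(prev, par, off) {
  unpack <- function(x) {
    if (inherits(x, "familial_fitness")) {
      list(mu = stats::setNames(x$mu, x$sire), cov = attr(x, "cov"),
           cohort = attr(x, "cohort"))
    } else {
      if (is.null(names(x))) stop("fitness vectors must be named by lineage")
      list(mu = x, cov = attr(x, "cov"), cohort = NULL)
    }
  }
  a <- unpack(prev); b <- unpack(par); c <- unpack(off)
  common <- Reduce(intersect, list(names(a$mu), names(b$mu), names(c$mu)))
  if (length(common) == 0) stop("no common lineages across cohorts")
  dropped <- setdiff(unique(c(names(a$mu), names(b$mu), names(c$mu))), common)
  if (length(dropped) > 0)
    message("dropping lineages absent from some cohort: ",
            paste(dropped, collapse = ", "))
  sub <- function(u, keep) {
    idx <- match(keep, names(u$mu))
    V <- u$cov
    if (!is.null(V)) V <- V[idx, idx, drop = FALSE]
    list(mu = u$mu[idx], cov = V, cohort = u$cohort)
  }
  structure(list(prev = sub(a, common), par = sub(b, common),
                 off = sub(c, common), lineages = common),
            class = "cohort_pair")
}

#' Change in mean fitness due to environmental difference between years
#'
#' `mean(mu_par) - mean(mu_prev)`, the difference between the mean
#' fitnesses of genetically replicate pedigreed cohorts grown in successive
#' years. Cohorts are treated as independent, so the squared standard
#' errors add.
#'
#' @param pair A `"cohort_pair"`, or the `mu_par` vector (then supply
#'   `mu_prev` and optionally `cov_par`, `cov_prev`).
#' @param mu_prev,cov_par,cov_prev See above.
#' @return List with `estimate` and `se`.
#' @export
environmental_change <- function(pair, mu_prev = NULL, cov_par = NULL,
                                 cov_prev = NULL) {
  if (inherits(pair, "cohort_pair")) {
    mu_par <- pair$par$mu; mu_prev <- pair$prev$mu
    cov_par <- pair$par$cov; cov_prev <- pair$prev$cov
  } else mu_par <- pair
  stopifnot(length(mu_par) == length(mu_prev))
  n <- length(mu_par)
  est <- mean(mu_par) - mean(mu_prev)
  vsum <- 0; have <- FALSE
  if (!is.null(cov_par)) { vsum <- vsum + sum(cov_par) / n^2; have <- TRUE }
  if (!is.null(cov_prev)) { vsum <- vsum + sum(cov_prev) / n^2; have <- TRUE }
  list(estimate = est, se = if (have) sqrt(max(vsum, 0)) else NA_real_)
}

## gradients of the total change wrt (mu_off, mu_prev)
.grad_total <- function(mu_off, mu_prev) {
  n <- length(mu_prev); m <- mean(mu_prev); A <- mean(mu_off * mu_prev)
  list(off = mu_prev / (n * m),
       prev = mu_off / (n * m) - A / (m^2 * n) - 1 / n)
}

#' Total intergenerational change in mean fitness
#'
#' `mean(mu_off * mu_prev / mean(mu_prev)) - mean(mu_prev)`. The weights
#' `mu_prev / mean(mu_prev)` correct the offspring cohort for the
#' experimental subsampling of families at planting: families are restored
#' to the frequencies at which their seed was actually produced. When
#' `mu_off` equals `mu_prev` this collapses exactly to [selection_change()].
#'
#' @param pair A `"cohort_pair"`, or the `mu_off` vector (then supply
#'   `mu_prev` and optionally covariance blocks).
#' @param mu_prev,cov_off,cov_prev See above.
#' @return List with `estimate` and `se`.
#' @export
total_change <- function(pair, mu_prev = NULL, cov_off = NULL,
                         cov_prev = NULL) {
  if (inherits(pair, "cohort_pair")) {
    mu_off <- pair$off$mu; mu_prev <- pair$prev$mu
    cov_off <- pair$off$cov; cov_prev <- pair$prev$cov
  } else mu_off <- pair
  stopifnot(length(mu_off) == length(mu_prev))
  .check_mu(mu_prev)
  est <- mean(mu_off * mu_prev / mean(mu_prev)) - mean(mu_prev)
  g <- .grad_total(mu_off, mu_prev)
  vsum <- 0; have <- FALSE
  if (!is.null(cov_off)) {
    vsum <- vsum + drop(crossprod(g$off, cov_off %*% g$off)); have <- TRUE
  }
  if (!is.null(cov_prev)) {
    vsum <- vsum + drop(crossprod(g$prev, cov_prev %*% g$prev)); have <- TRUE
  }
  list(estimate = est, se = if (have) sqrt(max(vsum, 0)) else NA_real_)
}

#' Residual component of the change in mean fitness
#'
#' Defined as the remainder `total - selection - environmental`. The
#' standard error propagates the joint gradient of the three components
#' through each cohort's familial-fitness covariance (cohorts independent),
#' not a naive combination of the component standard errors.
#'
#' @param pair A `"cohort_pair"`.
#' @return List with `estimate` and `se`.
#' @export
residual_change <- function(pair) {
  stopifnot(inherits(pair, "cohort_pair"))
  tot <- total_change(pair)
  sel <- selection_change(pair$prev$mu, pair$prev$cov)
  env <- environmental_change(pair)
  est <- tot$estimate - sel$estimate - env$estimate
  n <- length(pair$prev$mu)
  gt <- .grad_total(pair$off$mu, pair$prev$mu)
  g_prev <- gt$prev - .grad_selection(pair$prev$mu) + rep(1 / n, n)
  g_par <- rep(-1 / n, n)
  g_off <- gt$off
  vsum <- 0; have <- FALSE
  add <- function(g, V) {
    if (!is.null(V)) {
      vsum <<- vsum + drop(crossprod(g, V %*% g)); have <<- TRUE
    }
  }
  add(g_prev, pair$prev$cov); add(g_par, pair$par$cov); add(g_off, pair$off$cov)
  list(estimate = est, se = if (have) sqrt(max(vsum, 0)) else NA_real_)
}

#' Predicted change in mean fitness from the fundamental theorem
#'
#' The quantitative-genetic form of Fisher's fundamental theorem of natural
#' selection: predicted per-generation change in mean fitness is the
#' additive genetic variance for fitness divided by mean fitness.
#'
#' @param va_w Additive genetic variance for fitness (nonnegative).
#' @param mean_w Mean fitness (positive).
#' @return Scalar predicted change.
#' @export
ftns_prediction <- function(va_w, mean_w) {
  if (va_w < 0) stop("va_w must be nonnegative")
  if (mean_w <= 0) stop("mean_w must be positive")
  va_w / mean_w
}

#' Partition the intergenerational change in mean fitness
#'
#' Computes the four components for a cohort pair: the total
#' subsampling-corrected change from parents to offspring, the change due
#' to selection within the parental generation, the change due to
#' environmental difference between years, and the residual remainder (so
#' the components sum to the total by construction). Confidence intervals
#' use the normal approximation.
#'
#' @param pair A `"cohort_pair"`.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return A `"partition_result"` data frame with columns `component`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
partition_change <- function(pair, conf = 0.95) {
  stopifnot(inherits(pair, "cohort_pair"), conf > 0, conf < 1)
  comps <- list(
    total = total_change(pair),
    selection = selection_change(pair$prev$mu, pair$prev$cov),
    environmental = environmental_change(pair),
    residual = residual_change(pair)
  )
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(
    component = names(comps),
    estimate = vapply(comps, `[[`, numeric(1), "estimate"),
    se = vapply(comps, `[[`, numeric(1), "se"),
    row.names = NULL
  )
  out$ci_lo <- out$estimate - z * out$se
  out$ci_hi <- out$estimate + z * out$se
  structure(out, conf = conf, lineages = pair$lineages,
            class = c("partition_result", "data.frame"))
}
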