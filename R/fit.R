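## Maximum-likelihood fitting of the life-history model: fixed design
## effects on the unconditional canonical scale, optional Gaussian sire
## random effect fitted by Laplace approximation (penalized Fisher scoring
## inner solve, 1-D outer search over the variance component), familial
## fitness mapping with delta-method covariance, and the quadrature mapping
## of the canonical variance component to Va(W).

#' Model specification for an aster fit
#'
#' @param fixed A one-sided formula for the fixed design, applied to every
#'   modeled node on the unconditional canonical scale (each node gets its
#'   own coefficients). Default `~ 1`: one intercept per node, i.e. a
#'   saturated cell-means fit for a single-cohort data set.
#' @param random Named character vector mapping a grouping column in the
#'   data to the node whose unconditional canonical parameter its random
#'   intercept perturbs, e.g. `c(sire = "Seeds")` (the default). Use `NULL`
#'   for a fixed-effects-only fit. A single random term is supported; an
#'   optional dam component can be requested as a second element but is off
#'   by default.
#' @return An object of class `"aster_spec"`.
#' @export
aster_spec <- function(fixed = ~1, random = c(sire = "Seeds")) {
  stopifnot(inherits(fixed, "formula"))
  if (!is.null(random)) {
    if (is.null(names(random)) || any(names(random) == ""))
      stop("random terms must be named by their grouping column")
    if (length(random) > 1)
      stop("a single random term is supported")
  }
  structure(list(fixed = fixed, random = random), class = "aster_spec")
}

## per-node linear predictor phi, theta, mu and variance recursion ----------

.fit_env <- function(graph, data, spec) {
  mn <- .modeled_nodes(graph)
  X <- stats::model.matrix(spec$fixed, data)
  if (qr(X)$rank < ncol(X)) stop("fixed design is rank deficient")
  env <- list(
    graph = graph, data = data, mn = mn, X = X, p = ncol(X), J = length(mn),
    x = .node_obs(graph, data), pr = .pred_obs(graph, data), n = nrow(data)
  )
  if (!is.null(spec$random)) {
    group <- names(spec$random)[1]
    rnode <- unname(spec$random[[1]])
    if (!group %in% names(data))
      stop("random grouping column '", group, "' not in data")
    if (!rnode %in% mn)
      stop("random-effect node '", rnode, "' is not a modeled node")
    f <- factor(data[[group]])
    env$group <- group
    env$rnode <- rnode
    env$gidx <- as.integer(f)
    env$glevels <- levels(f)
    env$q <- nlevels(f)
    if (env$q < 2) stop("need at least 2 levels of '", group, "'")
  } else {
    env$q <- 0
  }
  ## predecessor kind per modeled node: "root", "fixed", or modeled name
  pk <- character(env$J); names(pk) <- mn
  for (nd in mn) {
    p <- graph$pred[[nd]]
    pk[nd] <- if (p == "1") "root"
      else if (graph$family[[p]] == "fixed") "fixed" else p
  }
  env$predkind <- pk
  ## observed values of fixed predecessors (exposure for e.g. the seed node)
  env$fixed_pred <- lapply(stats::setNames(mn, mn), function(nd) {
    p <- graph$pred[[nd]]
    if (p != "1" && graph$family[[p]] == "fixed")
      data[[graph$columns[[p]]]] else NULL
  })
  env
}

.phi_of_pars <- function(env, pars) {
  mn <- env$mn; p <- env$p
  phi <- matrix(0, env$n, env$J, dimnames = list(NULL, mn))
  for (j in seq_along(mn))
    phi[, j] <- drop(env$X %*% pars[((j - 1) * p + 1):(j * p)])
  if (env$q > 0) {
    b <- pars[env$J * p + seq_len(env$q)]
    phi[, env$rnode] <- phi[, env$rnode] + b[env$gidx]
  }
  phi
}

## mu and the full per-individual covariance recursion of the node vector,
## conditioned on observed fixed-node predecessors
.moments_of_theta <- function(env, theta) {
  graph <- env$graph; mn <- env$mn; n <- env$n; J <- env$J
  xi <- v <- mu <- matrix(0, n, J, dimnames = list(NULL, mn))
  for (nd in mn) {
    fam <- graph$family[[nd]]
    xi[, nd] <- .cumulant1(theta[, nd], fam)
    v[, nd] <- .cumulant2(theta[, nd], fam)
  }
  W <- array(0, c(n, J, J), dimnames = list(NULL, mn, mn))
  for (j in seq_along(mn)) {
    nd <- mn[j]
    pk <- env$predkind[[nd]]
    mupred <- switch(pk, root = rep(1, n), fixed = env$fixed_pred[[nd]],
                     mu[, pk])
    mu[, nd] <- xi[, nd] * mupred
    if (pk %in% c("root", "fixed")) {
      W[, j, j] <- v[, nd] * mupred
    } else {
      jp <- match(pk, mn)
      W[, j, j] <- v[, nd] * mupred + xi[, nd]^2 * W[, jp, jp]
      for (a in seq_len(j - 1)) {           # covariance with earlier nodes
        W[, j, a] <- W[, a, j] <- xi[, nd] * W[, jp, a]
      }
    }
  }
  list(xi = xi, mu = mu, W = W)
}

.condll <- function(env, theta) {
  ll <- 0
  for (nd in env$mn)
    ll <- ll + sum(env$x[, nd] * theta[, nd] -
                     env$pr[, nd] * .cumulant(theta[, nd],
                                              env$graph$family[[nd]]))
  ll
}

## score and expected information in the model parameters
.score_info <- function(env, pars, want_info = TRUE) {
  phi <- .phi_of_pars(env, pars)
  theta <- phi_to_theta(env$graph, phi)
  mom <- .moments_of_theta(env, theta)
  S <- env$x - mom$mu                      # score on the phi scale
  p <- env$p; J <- env$J; P <- J * p + env$q
  g <- numeric(P)
  for (j in seq_len(J))
    g[((j - 1) * p + 1):(j * p)] <- crossprod(env$X, S[, j])
  if (env$q > 0) {
    jr <- match(env$rnode, env$mn)
    g[J * p + seq_len(env$q)] <-
      rowsum(S[, jr], env$gidx, reorder = TRUE)[, 1]
  }
  out <- list(loglik = .condll(env, theta), score = g, theta = theta,
              boundary = any(abs(theta) >= THETA_CLIP - 1e-6))
  if (want_info) {
    I <- matrix(0, P, P)
    for (j in seq_len(J)) for (k in seq_len(j)) {
      blk <- crossprod(env$X * mom$W[, j, k], env$X)
      rj <- ((j - 1) * p + 1):(j * p); rk <- ((k - 1) * p + 1):(k * p)
      I[rj, rk] <- blk
      if (j != k) I[rk, rj] <- t(blk)
    }
    if (env$q > 0) {
      jr <- match(env$rnode, env$mn)
      bcols <- J * p + seq_len(env$q)
      for (j in seq_len(J)) {
        XB <- rowsum(env$X * mom$W[, j, jr], env$gidx, reorder = TRUE)
        rj <- ((j - 1) * p + 1):(j * p)
        I[rj, bcols] <- t(XB)
        I[bcols, rj] <- XB
      }
      dbb <- rowsum(mom$W[, jr, jr], env$gidx, reorder = TRUE)[, 1]
      I[cbind(bcols, bcols)] <- dbb
    }
    out$info <- I
  }
  out
}

## penalized Fisher scoring over (beta, b) for fixed sigma2
.newton <- function(env, pars, sigma2, tol_grad = 1e-8, tol_step = 1e-10,
                    maxit = 200) {
  P <- length(pars)
  bidx <- if (env$q > 0) env$J * env$p + seq_len(env$q) else integer(0)
  pars_cur <- pars
  si <- .score_info(env, pars_cur)
  f_cur <- si$loglik -
    (if (env$q > 0 && sigma2 > 0) sum(pars_cur[bidx]^2) / (2 * sigma2) else 0)
  iter <- 0; converged <- FALSE; boundary <- si$boundary
  repeat {
    iter <- iter + 1
    g <- si$score
    H <- si$info
    if (env$q > 0 && sigma2 > 0) {
      g[bidx] <- g[bidx] - pars_cur[bidx] / sigma2
      H[cbind(bidx, bidx)] <- H[cbind(bidx, bidx)] + 1 / sigma2
    }
    if (max(abs(g)) < tol_grad) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * (1 + mean(diag(H))), nrow(H)), g)
    })
    ## backtracking line search on the penalized log likelihood
    alpha <- 1; improved <- FALSE
    for (ls in 1:40) {
      pars_new <- pars_cur + alpha * step
      si_new <- .score_info(env, pars_new)
      f_new <- si_new$loglik -
        (if (env$q > 0 && sigma2 > 0) sum(pars_new[bidx]^2) / (2 * sigma2)
         else 0)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) { improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) break
    moved <- max(abs(alpha * step))
    pars_cur <- pars_new; si <- si_new; f_cur <- f_new
    boundary <- boundary || si$boundary
    if (moved < tol_step) {
      converged <- max(abs(si$score -
        (if (env$q > 0 && sigma2 > 0)
           c(numeric(env$J * env$p), pars_cur[bidx] / sigma2) else 0))) < 1e-6
      break
    }
    if (iter >= maxit) break
  }
  list(pars = pars_cur, si = si, penll = f_cur, iter = iter,
       converged = converged || boundary, boundary = boundary)
}

#' Fit the life-history model
#'
#' Maximum likelihood for the joint exponential-family life-history model
#' with fixed design effects on the unconditional canonical scale and,
#' optionally, a Gaussian random intercept (default: sire lineage on the
#' terminal seed node). The fixed-effects problem is solved by damped
#' Fisher scoring on the concave log-likelihood. With a random term, the
#' marginal likelihood is approximated by Laplace's method: the penalized
#' log-likelihood is maximized jointly over fixed effects and random-effect
#' values for a trial variance, a log-determinant correction is added, and
#' the variance component is found by a one-dimensional search on the log
#' scale. A variance estimate below `1e-8` is mapped to an exact boundary
#' zero, at which the fit reproduces the fixed-effects estimates.
#'
#' @param graph An `"lh_graph"`.
#' @param data A cohort data frame (validated internally).
#' @param spec An [aster_spec()]; default has a sire random effect on the
#'   `Seeds` node.
#' @param sigma2_init Starting value for the variance component search.
#' @return An object of class `"aster_fit"` with components `beta`
#'   (named fixed effects, canonical scale), `b` (random-effect point
#'   estimates), `sigma2` (variance component; `NULL` for fixed-only fits),
#'   `sigma2_se`, `fisher_info` (approximate observed information for
#'   `(beta, b)`, penalized), `loglik`, `laplace` (marginal criterion),
#'   `converged`, `boundary`, `n_iter`, and bookkeeping fields used by
#'   [familial_fitness()] and [estimate_va()].
#' @export
fit_aster <- function(graph, data, spec = aster_spec(), sigma2_init = 0.1) {
  validate_cohort(graph, data)
  env <- .fit_env(graph, data, spec)
  p <- env$p; J <- env$J
  beta_names <- as.vector(outer(colnames(env$X), env$mn,
                                function(cf, nd) paste(nd, cf, sep = ":")))
  beta_names <- as.vector(t(matrix(beta_names, ncol = J)))
  ## fit_fixed: no random term, or the substrate for starting values
  env_fix <- env; env_fix$q <- 0
  fix <- .newton(env_fix, numeric(J * p), sigma2 = 0)
  total_iter <- fix$iter

  mk_fit <- function(pars, sigma2, sigma2_se, info, loglik, laplace,
                     converged, boundary, n_iter) {
    beta <- stats::setNames(pars[seq_len(J * p)], beta_names)
    b <- if (env$q > 0)
      stats::setNames(pars[J * p + seq_len(env$q)], env$glevels) else NULL
    dn <- c(beta_names, if (env$q > 0) paste0("b:", env$glevels))
    dimnames(info) <- list(dn, dn)
    cohort <- list(
      site = if ("site" %in% names(data)) as.character(unique(data$site)) else NA,
      year = if ("year" %in% names(data)) unique(data$year) else NA,
      gen = if ("gen" %in% names(data)) as.character(unique(data$gen)) else NA)
    ## realized conditional mean of each fixed node (e.g. pod subsample rate)
    fixed_nodes <- graph$nodes[graph$family == "fixed"]
    fixed_xi <- vapply(fixed_nodes, function(nd) {
      pp <- graph$pred[[nd]]
      num <- sum(data[[graph$columns[[nd]]]])
      den <- if (pp == "1") nrow(data) else sum(data[[graph$columns[[pp]]]])
      if (den > 0) num / den else 1
    }, numeric(1))
    structure(list(
      beta = beta, b = b, sigma2 = sigma2, sigma2_se = sigma2_se,
      fisher_info = info, loglik = loglik, laplace = laplace,
      converged = converged, boundary = boundary, n_iter = n_iter,
      graph = graph, spec = spec, xref = colMeans(env$X),
      xcols = colnames(env$X), fixed_xi = fixed_xi,
      random_group = if (env$q > 0) env$group else NULL,
      random_node = if (env$q > 0) env$rnode else NULL,
      group_levels = if (env$q > 0) env$glevels else NULL,
      cohort = cohort, n = env$n), class = "aster_fit")
  }

  if (env$q == 0) {
    return(mk_fit(fix$pars, sigma2 = NULL, sigma2_se = NULL,
                  info = fix$si$info, loglik = fix$si$loglik,
                  laplace = fix$si$loglik, converged = fix$converged,
                  boundary = fix$boundary, n_iter = total_iter))
  }

  ## Laplace criterion as a function of log(sigma2), with warm starts
  bidx <- J * p + seq_len(env$q)
  jr <- match(env$rnode, env$mn)
  warm <- c(fix$pars, numeric(env$q))
  laplace_at <- function(ls2) {
    sigma2 <- exp(ls2)
    nt <- .newton(env, warm, sigma2)
    warm <<- nt$pars
    total_iter <<- total_iter + nt$iter
    Hbb <- nt$si$info[bidx, bidx, drop = FALSE]
    ld <- determinant(sigma2 * Hbb + diag(env$q), logarithm = TRUE)$modulus
    list(val = nt$penll - 0.5 * as.numeric(ld), nt = nt)
  }
  obj <- function(ls2) -laplace_at(ls2)$val
  lo <- log(1e-9); hi <- log(50)
  opt <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-6)
  lm_opt <- -opt$objective
  lm_lo <- -obj(lo)
  if (lm_lo >= lm_opt - 1e-7 || exp(opt$minimum) < 1e-8) {
    ## boundary: sigma2 = 0, fit collapses to the fixed-effects fit
    pars0 <- c(fix$pars, numeric(env$q))
    si0 <- .score_info(env, pars0)
    info0 <- si0$info
    ## penalty block undefined at 0; report the unpenalized information
    return(mk_fit(pars0, sigma2 = 0, sigma2_se = NA_real_, info = info0,
                  loglik = si0$loglik, laplace = fix$si$loglik,
                  converged = fix$converged, boundary = fix$boundary,
                  n_iter = total_iter))
  }
  la <- laplace_at(opt$minimum)
  sigma2 <- exp(opt$minimum)
  nt <- la$nt
  info_pen <- nt$si$info
  info_pen[cbind(bidx, bidx)] <- info_pen[cbind(bidx, bidx)] + 1 / sigma2
  ## curvature of the Laplace criterion in log sigma2 -> SE of sigma2
  h <- 1e-3
  d2 <- (laplace_at(opt$minimum + h)$val - 2 * lm_opt +
           laplace_at(opt$minimum - h)$val) / h^2
  sigma2_se <- if (is.finite(d2) && d2 < 0) sigma2 * sqrt(-1 / d2) else NA_real_
  mk_fit(nt$pars, sigma2 = sigma2, sigma2_se = sigma2_se, info = info_pen,
         loglik = nt$si$loglik, laplace = lm_opt, converged = nt$converged,
         boundary = nt$boundary, n_iter = total_iter)
}

#' @export
print.aster_fit <- function(x, ...) {
  cat("Aster life-history model fit (n =", x$n, ")\n")
  cat("log-likelihood:", format(x$loglik), "\n")
  if (!is.null(x$sigma2))
    cat(sprintf("sigma2[%s @ %s]: %.6g%s\n", x$random_group, x$random_node,
                x$sigma2, if (x$sigma2 == 0) " (boundary)" else ""))
  cat("converged:", x$converged,
      if (x$boundary) "(canonical parameter at clip bound)" else "", "\n")
  print(x$beta)
  invisible(x)
}

## ---------------------------------------------------------------------------
## familial fitness and derived quantities

## fitness of each lineage given full parameter vector, at a reference row
.familial_map <- function(fit, pars, xref) {
  graph <- fit$graph
  mn <- .modeled_nodes(graph)
  p <- length(xref); J <- length(mn)
  q <- length(fit$group_levels)
  phi0 <- vapply(seq_len(J), function(j)
    sum(xref * pars[((j - 1) * p + 1):(j * p)]), numeric(1))
  names(phi0) <- mn
  b <- pars[J * p + seq_len(q)]
  vapply(seq_len(q), function(i) {
    phi <- phi0
    phi[fit$random_node] <- phi[fit$random_node] + b[i]
    th <- phi_to_theta(graph, phi)
    fitness_scalar(graph, mean_value_map(graph, th, fixed_xi = fit$fixed_xi))
  }, numeric(1))
}

#' Familial mean fitnesses from a fitted model
#'
#' Maps each lineage's random-effect point estimate, added to the reference
#' cell's unconditional canonical parameters at the assigned node, through
#' the mean-value map and the fitness scalar, giving per-lineage expected
#' seeds per seed planted. The covariance of the familial fitnesses is
#' obtained by the delta method from the approximate observed information
#' of `(beta, b)`.
#'
#' @param fit An `"aster_fit"` with a random term.
#' @param newdata Optional one-row data frame giving the covariate profile
#'   of the reference cell; default is the average design row of the fitted
#'   cohort.
#' @return An object of class `"familial_fitness"`: a data frame with
#'   columns `sire`, `mu`, `se`, the full covariance matrix in
#'   `attr(, "cov")`, and the cohort labels in `attr(, "cohort")`.
#' @export
familial_fitness <- function(fit, newdata = NULL) {
  if (is.null(fit$random_group))
    stop("fit has no random term; familial fitnesses are undefined")
  xref <- .reference_row(fit, newdata)
  pars <- c(unname(fit$beta), unname(fit$b))
  mu <- .familial_map(fit, pars, xref)
  ## numeric Jacobian (central differences) of the familial map
  P <- length(pars)
  G <- matrix(0, length(mu), P)
  for (k in seq_len(P)) {
    h <- 1e-6 * max(1, abs(pars[k]))
    up <- pars; up[k] <- up[k] + h
    dn <- pars; dn[k] <- dn[k] - h
    G[, k] <- (.familial_map(fit, up, xref) -
                 .familial_map(fit, dn, xref)) / (2 * h)
  }
  if (!is.null(fit$sigma2) && fit$sigma2 == 0) {
    ## boundary: b is pinned at 0 (infinite shrinkage), so only fixed-effect
    ## uncertainty propagates; the unpenalized joint information is singular
    pidx <- seq_along(fit$beta)
    V <- G[, pidx, drop = FALSE] %*%
      solve(fit$fisher_info[pidx, pidx], t(G[, pidx, drop = FALSE]))
  } else {
    V <- G %*% solve(fit$fisher_info, t(G))
  }
  V <- (V + t(V)) / 2
  out <- data.frame(sire = fit$group_levels, mu = mu,
                    se = sqrt(pmax(diag(V), 0)))
  dimnames(V) <- list(fit$group_levels, fit$group_levels)
  structure(out, cov = V, cohort = fit$cohort, class =
              c("familial_fitness", "data.frame"))
}

.reference_row <- function(fit, newdata) {
  if (is.null(newdata)) return(unname(fit$xref))
  X <- stats::model.matrix(fit$spec$fixed, newdata)
  if (!identical(colnames(X), fit$xcols))
    stop("reference cell does not match the fitted design")
  drop(X[1, ])
}

#' Cohort mean fitness before selection
#'
#' The unweighted average of the familial mean fitnesses, with its
#' delta-method standard error `sqrt(1' V 1) / n`.
#'
#' @param ffs A `"familial_fitness"` object.
#' @return List with `estimate` and `se`.
#' @export
cohort_mean_fitness <- function(ffs) {
  stopifnot(inherits(ffs, "familial_fitness"))
  V <- attr(ffs, "cov")
  n <- nrow(ffs)
  se <- if (is.null(V)) NA_real_ else sqrt(max(sum(V), 0)) / n
  list(estimate = mean(ffs$mu), se = se)
}

#' Delta-method standard error
#'
#' `sqrt(g' I^{-1} g)` for a scalar functional with gradient `g` and
#' approximate Fisher information `I`.
#'
#' @param fisher_info Symmetric positive-definite information matrix.
#' @param gradient Numeric gradient of the functional in the same
#'   parameterization.
#' @return Nonnegative scalar standard error.
#' @export
delta_method_se <- function(fisher_info, gradient) {
  v <- drop(crossprod(gradient, solve(fisher_info, gradient)))
  sqrt(max(v, 0))
}

#' Variance of a mapped Gaussian effect by Gauss--Hermite quadrature
#'
#' Computes `Var(f(Z))` for `Z ~ N(0, sigma2)` with an `n_nodes`-point
#' Gauss--Hermite rule; used to map the canonical-scale sire variance to the
#' mean-value (fitness) scale.
#'
#' @param sigma2 Variance of the Gaussian effect.
#' @param f Vectorized function of the effect.
#' @param n_nodes Number of quadrature nodes (default 21).
#' @return Nonnegative scalar variance.
#' @export
va_quadrature <- function(sigma2, f, n_nodes = 21) {
  if (sigma2 <= 0) return(0)
  gh <- pracma::gaussHermite(n_nodes)
  z <- sqrt(2 * sigma2) * gh$x
  w <- gh$w / sqrt(pi)
  fz <- vapply(z, f, numeric(1))
  m <- sum(w * fz)
  max(sum(w * fz^2) - m^2, 0)
}

#' Additive genetic variance for fitness
#'
#' Maps the fitted canonical-scale sire variance component to the
#' mean-value scale by pushing Gauss--Hermite quadrature points of
#' `N(0, sigma2_hat)` through the familial fitness map at the reference
#' cell, and multiplies the resulting variance by 4, the paternal half-sib
#' factor (sire variance estimates one quarter of the additive genetic
#' variance).
#'
#' @inheritParams familial_fitness
#' @param n_nodes Number of quadrature nodes.
#' @return List with `va_w` (additive genetic variance of fitness, squared
#'   seeds per seed planted), `sigma2_canonical`, and `method`.
#' @export
estimate_va <- function(fit, newdata = NULL, n_nodes = 21) {
  if (is.null(fit$random_group))
    stop("fit has no random term")
  xref <- .reference_row(fit, newdata)
  graph <- fit$graph
  mn <- .modeled_nodes(graph)
  p <- length(xref)
  phi0 <- vapply(seq_along(mn), function(j)
    sum(xref * fit$beta[((j - 1) * p + 1):(j * p)]), numeric(1))
  names(phi0) <- mn
  f <- function(bz) {
    phi <- phi0
    phi[fit$random_node] <- phi[fit$random_node] + bz
    th <- phi_to_theta(graph, phi)
    fitness_scalar(graph, mean_value_map(graph, th, fixed_xi = fit$fixed_xi))
  }
  va <- 4 * va_quadrature(fit$sigma2, f, n_nodes)
  list(va_w = va, sigma2_canonical = fit$sigma2,
       method = sprintf("gauss-hermite-%d, half-sib factor 4", n_nodes))
}
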