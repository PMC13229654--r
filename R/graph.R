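## Life-history graphical model: a forest of chains of conditional
## one-parameter exponential families (Bernoulli / Poisson arrows), the
## canonical-parameter scales, the mean-value scale, and the scalar fitness
## functional with the subsampled-pod adjustment.

# canonical parameters are clipped at +/- this bound before exponentiation
THETA_CLIP <- 30

.clip_theta <- function(theta) pmin(pmax(theta, -THETA_CLIP), THETA_CLIP)

## cumulant functions c(theta), their first two derivatives
.cumulant <- function(theta, family) {
  theta <- .clip_theta(theta)
  switch(family,
    bernoulli = ifelse(theta > 0, theta + log1p(exp(-theta)), log1p(exp(theta))),
    poisson = exp(theta),
    stop("unknown family: ", family)
  )
}

.cumulant1 <- function(theta, family) {
  theta <- .clip_theta(theta)
  switch(family,
    bernoulli = stats::plogis(theta),
    poisson = exp(theta),
    stop("unknown family: ", family)
  )
}

.cumulant2 <- function(theta, family) {
  theta <- .clip_theta(theta)
  switch(family,
    bernoulli = {
      p <- stats::plogis(theta)
      p * (1 - p)
    },
    poisson = exp(theta),
    stop("unknown family: ", family)
  )
}

#' Construct a life-history graph
#'
#' A life-history graph is a forest of chains rooted at the constant node
#' `"1"`. Each non-root node carries a one-parameter exponential family
#' (`"bernoulli"` or `"poisson"`) conditional on its unique predecessor, or
#' the tag `"fixed"` for a node that is observed and conditioned on rather
#' than modeled (used for the count of pods subsampled for seed counting).
#'
#' @param nodes Character vector of node names in topological order
#'   (every node's predecessor appears earlier, or is `"1"`).
#' @param pred Named character vector mapping each node to its predecessor
#'   node name, with `"1"` denoting the constant root.
#' @param family Named character vector mapping each node to
#'   `"bernoulli"`, `"poisson"`, or `"fixed"`.
#' @param fitness_node Name of the terminal seed-count node; must be a leaf.
#' @param subsample Optional length-2 character vector
#'   `c(total = ..., sampled = ...)` naming the total-pod node and the
#'   sampled-pod node, enabling the subsampling adjustment of the fitness
#'   scalar.
#' @param columns Named character vector mapping node names to column names
#'   in cohort data; defaults to lower-case node names.
#' @return An object of class `"lh_graph"`.
#' @seealso [default_fitness_graph()] for the shipped
#'   germination-to-seed-count graph.
#' @export
lh_graph <- function(nodes, pred, family, fitness_node,
                     subsample = NULL, columns = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1)
  pred <- pred[nodes]
  family <- family[nodes]
  if (anyNA(pred) || anyNA(family))
    stop("every node needs a predecessor and a family tag")
  bad <- !family %in% c("bernoulli", "poisson", "fixed")
  if (any(bad)) stop("unknown family tag: ", paste(family[bad], collapse = ", "))
  ## topological order / unique predecessor / acyclicity
  for (i in seq_along(nodes)) {
    p <- pred[[i]]
    if (p != "1" && !p %in% nodes[seq_len(i - 1)])
      stop("node '", nodes[i], "' has predecessor '", p,
           "' that is not an earlier node or \"1\"")
  }
  if (!fitness_node %in% nodes) stop("fitness_node not in graph")
  if (fitness_node %in% pred)
    stop("fitness_node must be a leaf")
  if (!is.null(subsample)) {
    subsample <- c(total = unname(subsample[["total"]]),
                   sampled = unname(subsample[["sampled"]]))
    if (!all(subsample %in% nodes)) stop("subsample nodes not in graph")
  }
  if (is.null(columns)) {
    columns <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", nodes)
    columns <- stats::setNames(tolower(columns), nodes)
  }
  structure(
    list(nodes = nodes, pred = pred, family = family,
         fitness_node = fitness_node, subsample = subsample,
         columns = columns),
    class = "lh_graph"
  )
}

#' @export
print.lh_graph <- function(x, ...) {
  cat("Life-history graph (", length(x$nodes), " nodes)\n", sep = "")
  for (nd in x$nodes)
    cat(sprintf("  %s -> %s  [%s]\n", x$pred[[nd]], nd, x$family[[nd]]))
  cat("fitness node:", x$fitness_node, "\n")
  if (!is.null(x$subsample))
    cat("subsample adjustment:", x$subsample[["sampled"]], "of",
        x$subsample[["total"]], "\n")
  invisible(x)
}

## modeled (non-fixed) node names, in topological order
.modeled_nodes <- function(graph) graph$nodes[graph$family != "fixed"]

#' Default life-history fitness graph for an annual plant
#'
#' The shipped graph follows the full annual life cycle of a planted seed:
#' germination (Bernoulli), survival to flowering (Bernoulli given
#' germination), total pods produced (Poisson given flowering), the number
#' of pods subsampled for seed counting (observed, conditioned on), and the
#' number of seeds counted in the sampled pods (Poisson with the sampled pod
#' count as exposure). The fitness scalar rescales seeds counted in the
#' sample back to the whole plant.
#'
#' @return An `"lh_graph"` object.
#' @export
default_fitness_graph <- function() {
  nodes <- c("Germ", "Flower", "TotalPods", "SamplePods", "Seeds")
  lh_graph(
    nodes = nodes,
    pred = c(Germ = "1", Flower = "Germ", TotalPods = "Flower",
             SamplePods = "TotalPods", Seeds = "SamplePods"),
    family = c(Germ = "bernoulli", Flower = "bernoulli",
               TotalPods = "poisson", SamplePods = "fixed",
               Seeds = "poisson"),
    fitness_node = "Seeds",
    subsample = c(total = "TotalPods", sampled = "SamplePods"),
    columns = c(Germ = "germ", Flower = "flower", TotalPods = "total_pods",
                SamplePods = "sample_pods", Seeds = "seeds")
  )
}

#' Read or write a life-history graph as JSON
#'
#' @param path File path.
#' @return `read_graph_json()` returns an `"lh_graph"`;
#'   `write_graph_json()` returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lh_graph(nodes = x$nodes, pred = unlist(x$pred), family = unlist(x$family),
           fitness_node = x$fitness_node,
           subsample = if (!is.null(x$subsample)) unlist(x$subsample),
           columns = if (!is.null(x$columns)) unlist(x$columns))
}

#' @rdname read_graph_json
#' @param graph An `"lh_graph"` object.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, pred = as.list(graph$pred),
         family = as.list(graph$family), fitness_node = graph$fitness_node,
         subsample = as.list(graph$subsample),
         columns = as.list(graph$columns)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## cohort data

#' Validate a cohort data frame against a life-history graph
#'
#' Checks the structural rules a per-individual life-history record must
#' satisfy: integer nonnegative node values, Bernoulli nodes bounded by their
#' predecessor, zero values wherever the predecessor is zero (an individual
#' that never germinated cannot flower), sampled pods no greater than total
#' pods, and presence of a sire label on every row.
#'
#' @param graph An `"lh_graph"`.
#' @param data A data frame with one row per planted seed; must contain the
#'   node columns named by `graph$columns` and a `sire` column.
#' @return `data`, invisibly, if valid; otherwise an error describing the
#'   first violation (with offending row numbers).
#' @export
validate_cohort <- function(graph, data) {
  cols <- graph$columns[graph$nodes]
  miss <- setdiff(c(unname(cols), "sire"), names(data))
  if (length(miss) > 0)
    stop("cohort data lacks required columns: ", paste(miss, collapse = ", "))
  for (nd in graph$nodes) {
    x <- data[[cols[[nd]]]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
        any(x != round(x)))
      stop("node column '", cols[[nd]],
           "' must contain nonnegative integers")
    p <- graph$pred[[nd]]
    pv <- if (p == "1") rep(1, nrow(data)) else data[[cols[[p]]]]
    bad <- which(x > 0 & pv == 0)
    if (length(bad) > 0)
      stop("structural-zero violation at node '", nd, "' (rows ",
           paste(utils::head(bad, 5), collapse = ", "),
           "): value positive while predecessor is zero")
    if (graph$family[[nd]] == "bernoulli") {
      bad <- which(x > pv)
      if (length(bad) > 0)
        stop("Bernoulli node '", nd, "' exceeds predecessor (rows ",
             paste(utils::head(bad, 5), collapse = ", "), ")")
    }
  }
  if (!is.null(graph$subsample)) {
    tot <- data[[cols[[graph$subsample[["total"]]]]]]
    sam <- data[[cols[[graph$subsample[["sampled"]]]]]]
    bad <- which(sam > tot)
    if (length(bad) > 0)
      stop("sampled pods exceed total pods (rows ",
           paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (anyNA(data$sire)) stop("missing sire labels")
  invisible(data)
}

## matrix of observed predecessor values, one column per modeled node
.pred_obs <- function(graph, data) {
  mn <- .modeled_nodes(graph)
  out <- matrix(1, nrow(data), length(mn), dimnames = list(NULL, mn))
  for (nd in mn) {
    p <- graph$pred[[nd]]
    if (p != "1") out[, nd] <- data[[graph$columns[[p]]]]
  }
  out
}

.node_obs <- function(graph, data) {
  mn <- .modeled_nodes(graph)
  out <- sapply(mn, function(nd) data[[graph$columns[[nd]]]])
  matrix(out, nrow = nrow(data), dimnames = list(NULL, mn))
}

## ---------------------------------------------------------------------------
## log likelihood

#' Aster log-likelihood on the conditional canonical scale
#'
#' Evaluates the joint exponential-family log-likelihood
#' \eqn{\ell = \sum_j x_j \theta_j - x_{p(j)} c_j(\theta_j)} over all
#' individuals and modeled nodes, with \eqn{c(\theta) = \log(1 + e^\theta)}
#' for Bernoulli arrows and \eqn{c(\theta) = e^\theta} for Poisson arrows.
#' Constants not involving \eqn{\theta} (e.g. \eqn{\log x!}) are dropped.
#' Rows whose predecessor value is zero contribute zero: the conditional
#' family is degenerate at sample size zero.
#'
#' @param graph An `"lh_graph"`.
#' @param data A validated cohort data frame.
#' @param theta Named numeric vector with one conditional canonical
#'   parameter per modeled node (shared by all rows), or a numeric matrix
#'   with one row per individual and one named column per modeled node.
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(graph, data, theta) {
  validate_cohort(graph, data)
  mn <- .modeled_nodes(graph)
  x <- .node_obs(graph, data)
  pr <- .pred_obs(graph, data)
  if (is.matrix(theta)) {
    th <- theta[, mn, drop = FALSE]
  } else {
    if (!all(mn %in% names(theta)))
      stop("theta must be named with one entry per modeled node")
    th <- matrix(rep(theta[mn], each = nrow(data)), nrow(data),
                 dimnames = list(NULL, mn))
  }
  if (any(!is.finite(th))) stop("theta must be finite")
  ll <- 0
  for (nd in mn)
    ll <- ll + sum(x[, nd] * th[, nd] -
                     pr[, nd] * .cumulant(th[, nd], graph$family[[nd]]))
  ll
}

## ---------------------------------------------------------------------------
## parameter-scale maps

## successors of each modeled node among modeled nodes
.succ_modeled <- function(graph) {
  mn <- .modeled_nodes(graph)
  lapply(stats::setNames(mn, mn), function(nd) mn[graph$pred[mn] == nd])
}

#' Convert between conditional and unconditional canonical parameters
#'
#' The unconditional canonical parameter of node \eqn{j} is
#' \eqn{\phi_j = \theta_j - \sum_{k: p(k) = j} c_k(\theta_k)}, summing over
#' modeled successors of \eqn{j}; `phi_to_theta()` inverts this by backward
#' recursion from the leaves. A node whose successors are all fixed (or
#' absent) has \eqn{\phi = \theta}. The two maps are exact inverses.
#'
#' @param graph An `"lh_graph"`.
#' @param theta,phi Named numeric vector (one entry per modeled node) or a
#'   matrix with named columns, one row per individual.
#' @return Object of the same shape on the other scale.
#' @export
theta_to_phi <- function(graph, theta) {
  vec <- !is.matrix(theta)
  mn <- .modeled_nodes(graph)
  th <- if (vec) matrix(theta[mn], 1, dimnames = list(NULL, mn))
        else theta[, mn, drop = FALSE]
  succ <- .succ_modeled(graph)
  phi <- th
  for (nd in mn)
    for (k in succ[[nd]])
      phi[, nd] <- phi[, nd] - .cumulant(th[, k], graph$family[[k]])
  if (vec) stats::setNames(phi[1, ], mn) else phi
}

#' @rdname theta_to_phi
#' @export
phi_to_theta <- function(graph, phi) {
  vec <- !is.matrix(phi)
  mn <- .modeled_nodes(graph)
  ph <- if (vec) matrix(phi[mn], 1, dimnames = list(NULL, mn))
        else phi[, mn, drop = FALSE]
  succ <- .succ_modeled(graph)
  th <- ph
  for (nd in rev(mn))  # leaves first: successors already converted
    for (k in succ[[nd]])
      th[, nd] <- th[, nd] + .cumulant(th[, k], graph$family[[k]])
  if (vec) stats::setNames(th[1, ], mn) else th
}

#' Map canonical parameters to the mean-value (measurement) scale
#'
#' Computes per-node conditional means \eqn{\xi_j = c_j'(\theta_j)}
#' (Bernoulli: logistic; Poisson: exponential) and unconditional means
#' \eqn{\mu_j = \xi_j \mu_{p(j)}} with \eqn{\mu_{\mathrm{root}} = 1}, the
#' expected count at each node per seed planted. A fixed (conditioned-on)
#' node takes its conditional mean from `fixed_xi`.
#'
#' @param graph An `"lh_graph"`.
#' @param theta Named numeric vector of conditional canonical parameters for
#'   the modeled nodes.
#' @param fixed_xi Named numeric vector giving the conditional mean per unit
#'   predecessor for each fixed node (e.g. the realized pod subsampling
#'   rate). Defaults to 1 for every fixed node.
#' @return A list with components `xi` and `mu`, each a named vector over
#'   all non-root nodes.
#' @export
mean_value_map <- function(graph, theta, fixed_xi = NULL) {
  mn <- .modeled_nodes(graph)
  if (!all(mn %in% names(theta)))
    stop("theta must be named with one entry per modeled node")
  xi <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  for (nd in graph$nodes) {
    if (graph$family[[nd]] == "fixed") {
      xi[nd] <- if (!is.null(fixed_xi) && nd %in% names(fixed_xi))
        fixed_xi[[nd]] else 1
    } else {
      xi[nd] <- .cumulant1(theta[[nd]], graph$family[[nd]])
    }
  }
  mu <- xi
  for (nd in graph$nodes) {
    p <- graph$pred[[nd]]
    mu[nd] <- xi[nd] * (if (p == "1") 1 else mu[[p]])
  }
  list(xi = xi, mu = mu)
}

#' Scalar fitness from mean-value parameters
#'
#' Expected number of seeds produced per seed planted. When the graph
#' carries a subsample pair, seeds counted in the sampled pods are rescaled
#' to the whole plant:
#' \eqn{W = \mu_{\mathrm{Seeds}} \mu_{\mathrm{TotalPods}} /
#' \mu_{\mathrm{SamplePods}}}; otherwise \eqn{W} is the unconditional mean
#' at the fitness node.
#'
#' @param graph An `"lh_graph"`.
#' @param mv A mean-value parameter list as returned by [mean_value_map()].
#' @return Nonnegative scalar fitness.
#' @export
fitness_scalar <- function(graph, mv) {
  mu <- mv$mu
  if (is.null(graph$subsample)) return(unname(mu[[graph$fitness_node]]))
  tot <- mu[[graph$subsample[["total"]]]]
  sam <- mu[[graph$subsample[["sampled"]]]]
  sds <- mu[[graph$fitness_node]]
  if (sam == 0) {
    if (sds > 0) stop("degenerate subsample: zero sampled pods with positive seeds")
    return(0)
  }
  unname(sds * tot / sam)
}
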