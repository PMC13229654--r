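## Small graphs and simulated fixtures shared across test files.

bern_graph <- function() lh_graph("Y", c(Y = "1"), c(Y = "bernoulli"), "Y")

pois_graph <- function() lh_graph("Y", c(Y = "1"), c(Y = "poisson"), "Y")

## Bernoulli -> Poisson chain
chain_graph <- function() {
  lh_graph(c("G", "P"), c(G = "1", P = "G"),
           c(G = "bernoulli", P = "poisson"), "P")
}

## small balanced half-sib design for quick fits
small_design <- function(n_sires = 20) {
  crossing_design(n_sires = n_sires, dams_per_sire = 2,
                  seeds_per_family = 20, locations_per_family = 4,
                  seeds_per_location = 5)
}

## clean truth without nuisance variation unless asked for
plain_truth <- function(sigma2_sire = 0.2, sigma2_gxe = 0, block_sd = 0,
                        subsample_rate = 0.7, ...) {
  generator_truth(sigma2_sire = sigma2_sire, sigma2_gxe = sigma2_gxe,
                  block_sd = block_sd, subsample_rate = subsample_rate, ...)
}

## a hand-built fit object for unit tests of the familial-fitness map:
## single Poisson fitness node, intercept theta0, given sire effects
manual_pois_fit <- function(theta0, b, info = diag(1 + length(b))) {
  g <- pois_graph()
  structure(list(
    beta = c("Y:(Intercept)" = theta0), b = b, sigma2 = 0.1,
    fisher_info = info, loglik = NA_real_, converged = TRUE,
    boundary = FALSE, n_iter = 0, graph = g,
    spec = aster_spec(fixed = ~1, random = c(sire = "Y")),
    xref = c("(Intercept)" = 1), xcols = "(Intercept)",
    fixed_xi = numeric(0), random_group = "sire", random_node = "Y",
    group_levels = names(b),
    cohort = list(site = "S1", year = 1, gen = "G1"), n = 0L),
    class = "aster_fit")
}
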