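## Simulation of pedigreed two-generation field cohorts under a paternal
## half-sib crossing design: sire effects, lineage-by-year interaction, and
## transect (block) effects enter the conditional canonical parameter of
## the terminal seed node; life-history outcomes are sampled forward along
## the graph; pods are thinned to give the subsampled seed counts; and the
## offspring generation is grown from the realized seed output of the
## parental families with binomial thinning at planting.

#' Paternal half-sib crossing and planting design
#'
#' @param n_sires Number of G0 pollen parents (default 42).
#' @param dams_per_sire Full-sib groups per sire (default 3).
#' @param seeds_per_family Seeds planted per full-sib family (default 30);
#'   must equal `locations_per_family * seeds_per_location`.
#' @param locations_per_family Planting locations per family (default 6).
#' @param seeds_per_location Seeds per location (default 5).
#' @return An object of class `"crossing_design"`.
#' @export
crossing_design <- function(n_sires = 42, dams_per_sire = 3,
                            seeds_per_family = 30, locations_per_family = 6,
                            seeds_per_location = 5) {
  stopifnot(n_sires >= 1, dams_per_sire >= 1, seeds_per_family >= 1,
            locations_per_family >= 1, seeds_per_location >= 1)
  if (seeds_per_family != locations_per_family * seeds_per_location)
    stop("seeds_per_family must equal locations_per_family * seeds_per_location")
  structure(list(n_sires = n_sires, dams_per_sire = dams_per_sire,
                 seeds_per_family = seeds_per_family,
                 locations_per_family = locations_per_family,
                 seeds_per_location = seeds_per_location),
            class = "crossing_design")
}

#' Generative truth for cohort simulation
#'
#' Baseline conditional canonical parameters per year, plus the variance
#' structure of the pedigree: sire variance and lineage-by-year interaction
#' variance on the canonical scale of the seed node, transect-level
#' environmental SD, the pod subsampling rate, and the fraction of each
#' family's realized seed output planted in the offspring generation.
#'
#' Defaults describe an annual plant whose cohort mean fitness sits in the
#' low single digits of seeds per seed planted, with a year-2 environment
#' distinctly poorer than year 1.
#'
#' @param theta0 Named list of named numeric vectors: one entry per year,
#'   each with conditional canonical parameters for the modeled nodes
#'   `Germ`, `Flower`, `TotalPods`, `Seeds`.
#' @param sigma2_sire Sire variance (canonical scale, seed node).
#' @param sigma2_gxe Sire-by-year interaction variance.
#' @param block_sd SD of transect effects (canonical scale, seed node).
#' @param subsample_rate Probability a pod is sampled for seed counting.
#' @param g2_planting_fraction Fraction of each family's realized seed
#'   output planted in the G2 generation.
#' @return An object of class `"generator_truth"`.
#' @export
generator_truth <- function(
    theta0 = list(
      `1` = c(Germ = stats::qlogis(0.30), Flower = stats::qlogis(0.50),
              TotalPods = log(6), Seeds = log(3)),
      `2` = c(Germ = stats::qlogis(0.25), Flower = stats::qlogis(0.45),
              TotalPods = log(4), Seeds = log(3))),
    sigma2_sire = 0.25, sigma2_gxe = 0.05, block_sd = 0.2,
    subsample_rate = 0.7, g2_planting_fraction = 0.25) {
  stopifnot(sigma2_sire >= 0, sigma2_gxe >= 0, block_sd >= 0,
            subsample_rate >= 0, subsample_rate <= 1,
            g2_planting_fraction >= 0, g2_planting_fraction <= 1)
  structure(list(theta0 = theta0, sigma2_sire = sigma2_sire,
                 sigma2_gxe = sigma2_gxe, block_sd = block_sd,
                 subsample_rate = subsample_rate,
                 g2_planting_fraction = g2_planting_fraction),
            class = "generator_truth")
}

.theta0_year <- function(truth, year) {
  key <- as.character(year)
  if (!key %in% names(truth$theta0))
    stop("no baseline parameters for year ", year)
  truth$theta0[[key]]
}

## sample node values forward given per-individual canonical seed-node shift;
## returns the observed columns plus the unobserved total seed output
.sample_rows <- function(n, th0, seed_shift, subsample_rate) {
  germ <- stats::rbinom(n, 1, stats::plogis(th0[["Germ"]]))
  flower <- ifelse(germ == 1,
                   stats::rbinom(n, 1, stats::plogis(th0[["Flower"]])), 0L)
  pods <- ifelse(flower == 1,
                 stats::rpois(n, exp(th0[["TotalPods"]])), 0L)
  sample_pods <- stats::rbinom(n, pods, subsample_rate)
  lam <- exp(.clip_theta(th0[["Seeds"]] + seed_shift))
  seeds <- stats::rpois(n, sample_pods * lam)
  seeds_unsampled <- stats::rpois(n, (pods - sample_pods) * lam)
  data.frame(germ = as.integer(germ), flower = as.integer(flower),
             total_pods = as.integer(pods),
             sample_pods = as.integer(sample_pods),
             seeds = as.integer(seeds),
             total_seed_output = as.integer(seeds + seeds_unsampled))
}

## expected fitness per seed planted for a lineage with canonical seed-node
## lineage effect `eff`, averaging over block effects (and any extra
## independent canonical-scale noise with variance `extra_var`) lognormally
.true_lineage_fitness <- function(truth, year, eff, extra_var = 0) {
  th0 <- .theta0_year(truth, year)
  stats::plogis(th0[["Germ"]]) * stats::plogis(th0[["Flower"]]) *
    exp(th0[["TotalPods"]]) *
    exp(th0[["Seeds"]] + eff + (truth$block_sd^2 + extra_var) / 2)
}

#' Simulate one pedigreed field cohort
#'
#' Draws (or reuses) sire effects and a lineage-by-year interaction, assigns
#' full-sib families to planting locations on random transects, and samples
#' each individual's life-history record forward along the default fitness
#' graph. The true familial mean fitnesses used are attached as attributes
#' for recovery testing.
#'
#' @param design A [crossing_design()].
#' @param truth A [generator_truth()].
#' @param site Site label.
#' @param year Year key into `truth$theta0`.
#' @param generation Generation tag, `"G1"` or `"G2"`.
#' @param sire_effects Optional named vector of canonical sire effects to
#'   reuse (e.g. across replicate cohorts); drawn `N(0, sigma2_sire)` if
#'   `NULL`.
#' @param seed Optional RNG seed for reproducibility.
#' @return A cohort data frame (columns `id, site, year, gen, sire, dam,
#'   block, pos, germ, flower, total_pods, sample_pods, seeds`) with
#'   attributes `sire_effects`, `gxe_effects`, `true_mu` (true familial
#'   fitnesses for this cohort-year), and `family_seed_output`.
#' @export
simulate_cohort <- function(design, truth, site = "S1", year = 1,
                            generation = "G1", sire_effects = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- design$n_sires
  sires <- sprintf("S%03d", seq_len(ns))
  if (is.null(sire_effects)) {
    sire_effects <- stats::setNames(
      stats::rnorm(ns, 0, sqrt(truth$sigma2_sire)), sires)
  } else {
    sires <- names(sire_effects)
    ns <- length(sires)
  }
  gxe <- stats::setNames(stats::rnorm(ns, 0, sqrt(truth$sigma2_gxe)), sires)
  fam <- expand.grid(dam_i = seq_len(design$dams_per_sire),
                     sire = sires, stringsAsFactors = FALSE)
  fam$dam <- paste0(fam$sire, "D", fam$dam_i)
  nloc_total <- nrow(fam) * design$locations_per_family
  ## ~25 planting locations per 50-m transect (2 m spacing)
  n_blocks <- max(2, ceiling(nloc_total / 25))
  block_eff <- stats::rnorm(n_blocks, 0, truth$block_sd)
  loc_block <- sample(rep_len(seq_len(n_blocks), nloc_total))

  rows <- fam[rep(seq_len(nrow(fam)),
                  each = design$seeds_per_family), c("sire", "dam")]
  nloc_per_fam <- design$locations_per_family
  loc_within <- rep(rep(seq_len(nloc_per_fam),
                        each = design$seeds_per_location), nrow(fam))
  loc_global <- (rep(seq_len(nrow(fam)), each = design$seeds_per_family) - 1) *
    nloc_per_fam + loc_within
  n <- nrow(rows)
  th0 <- .theta0_year(truth, year)
  shift <- sire_effects[rows$sire] + gxe[rows$sire] +
    block_eff[loc_block[loc_global]]
  out <- .sample_rows(n, th0, shift, truth$subsample_rate)
  dat <- data.frame(
    id = sprintf("%s_%s_%s_%05d", site, year, generation, seq_len(n)),
    site = site, year = year, gen = generation,
    sire = rows$sire, dam = rows$dam,
    block = sprintf("T%02d", loc_block[loc_global]),
    pos = sprintf("L%05d", loc_global),
    out[c("germ", "flower", "total_pods", "sample_pods", "seeds")],
    stringsAsFactors = FALSE)
  fso <- rowsum(out$total_seed_output, rows$dam)
  true_mu <- vapply(sires, function(s)
    .true_lineage_fitness(truth, year, sire_effects[[s]] + gxe[[s]]),
    numeric(1))
  structure(dat, sire_effects = sire_effects, gxe_effects = gxe,
            true_mu = true_mu,
            family_seed_output = stats::setNames(fso[, 1], rownames(fso)))
}

#' Simulate a two-generation field experiment
#'
#' Produces the cohort triple of the two-year scheme: the pedigreed G1
#' cohort grown in year 1, a genetically replicate G1 cohort grown in year
#' 2 (same sire effects, fresh lineage-by-year draws), and the
#' open-pollinated G2 offspring of the year-1 G1 families grown alongside
#' the replicate in year 2. G2 family sizes are a binomial thinning of each
#' G1 family's realized seed output at the planting fraction; G2 rows carry
#' the maternal grandsire as their lineage label, inherit half the
#' maternal-side sire effect, and receive an independent pollen-pool draw
#' per individual. Families with zero realized seed output are absent from
#' G2 (with a message).
#'
#' The generator-truth familial fitnesses and the true partition of the
#' change in mean fitness are returned for recovery testing.
#'
#' @inheritParams simulate_cohort
#' @param years Length-2 vector of year keys (default `c(1, 2)`).
#' @return A list with elements `g1_prev`, `g1_par`, `g2` (cohort data
#'   frames) and `truth` (list with `mu_prev`, `mu_par`, `mu_off`, and a
#'   `partition` data frame of the true component values).
#' @export
simulate_two_generations <- function(design, truth, site = "S1",
                                     years = c(1, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g1_prev <- simulate_cohort(design, truth, site, years[1], "G1")
  b <- attr(g1_prev, "sire_effects")
  g1_par <- simulate_cohort(design, truth, site, years[2], "G1",
                            sire_effects = b)
  ## offspring generation from the realized seed output of year-1 families
  fso <- attr(g1_prev, "family_seed_output")
  dams <- names(fso)
  planted <- stats::rbinom(length(fso), fso, truth$g2_planting_fraction)
  names(planted) <- dams
  empty <- dams[fso == 0]
  if (length(empty) > 0)
    message("G1 families with zero seed output absent from G2: ",
            paste(empty, collapse = ", "))
  keep <- planted > 0
  dams <- dams[keep]; planted <- planted[keep]
  grandsire <- sub("D[0-9]+$", "", dams)
  n2 <- sum(planted)
  rows_sire <- rep(grandsire, planted)
  rows_dam <- rep(dams, planted)
  gxe2 <- stats::setNames(stats::rnorm(length(b), 0, sqrt(truth$sigma2_gxe)),
                          names(b))
  ## half the maternal-side effect through the grandsire lineage, plus an
  ## independent paternal (pollen pool) contribution per individual
  pollen <- stats::rnorm(n2, 0, sqrt(truth$sigma2_sire))
  th0 <- .theta0_year(truth, years[2])
  nloc <- ceiling(n2 / 5)
  n_blocks <- max(2, ceiling(nloc / 25))
  block_eff <- stats::rnorm(n_blocks, 0, truth$block_sd)
  loc_of_row <- sample(rep_len(seq_len(nloc), n2))
  blk <- rep_len(seq_len(n_blocks), nloc)[loc_of_row]
  shift <- b[rows_sire] / 2 + gxe2[rows_sire] + pollen + block_eff[blk]
  out <- .sample_rows(n2, th0, shift, truth$subsample_rate)
  g2 <- data.frame(
    id = sprintf("%s_%s_G2_%05d", site, years[2], seq_len(n2)),
    site = site, year = years[2], gen = "G2",
    sire = rows_sire, dam = rows_dam,
    block = sprintf("T%02d", blk), pos = sprintf("L%05d", loc_of_row),
    out[c("germ", "flower", "total_pods", "sample_pods", "seeds")],
    stringsAsFactors = FALSE)

  sires <- names(b)
  gxe1 <- attr(g1_prev, "gxe_effects")
  mu_prev <- attr(g1_prev, "true_mu")
  mu_par <- attr(g1_par, "true_mu")
  mu_off <- vapply(sires, function(s)
    .true_lineage_fitness(truth, years[2], b[[s]] / 2 + gxe2[[s]],
                          extra_var = truth$sigma2_sire), numeric(1))
  pr <- cohort_pair(mu_prev, mu_par, mu_off)
  part <- data.frame(
    component = c("total", "selection", "environmental", "residual"),
    estimate = c(total_change(pr)$estimate,
                 selection_change(pr$prev$mu)$estimate,
                 environmental_change(pr)$estimate,
                 residual_change(pr)$estimate),
    row.names = NULL)
  list(g1_prev = g1_prev, g1_par = g1_par, g2 = g2,
       truth = list(mu_prev = mu_prev, mu_par = mu_par, mu_off = mu_off,
                    partition = part))
}
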