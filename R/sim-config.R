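#' Default genetic-coefficient covariance for the bivariate simulation
#'
#' Builds the 5x5 covariance of the random-regression genetic coefficients
#' `[grp0, grp1, ind0, ind1, ind2]` so that (i) the mean daily genetic
#' variance matches the requested levels for the group and individual traits
#' and (ii) the whole-period genetic correlation between the two traits
#' equals `period_r`. The cross-block is a single intercept-intercept
#' loading solved against the period-correlation formula on the given day
#' grids, so the target is met exactly by construction.
#'
#' @param G1 2x2 group-trait coefficient covariance.
#' @param G2 3x3 individual-trait coefficient covariance.
#' @param period_r Target whole-period genetic correlation.
#' @param basis_grp,basis_ind Legendre bases of the two traits.
#' @param days_grp,days_ind Integer day grids of the two traits.
#' @return 5x5 positive-definite covariance matrix.
#' @export
make_true_G <- function(G1 = matrix(c(0.15, 0.03, 0.03, 0.05), 2),
                        G2 = diag(c(0.08, 0.04, 0.03)),
                        period_r = 0.3,
                        basis_grp = legendre_basis(1, 15, 45),
                        basis_ind = legendre_basis(2, 1, 75),
                        days_grp = 15:45,
                        days_ind = 1:75) {
  phi1s <- colSums(leg_eval(basis_grp, days_grp))
  phi2s <- colSums(leg_eval(basis_ind, days_ind))
  denom <- sqrt(drop(phi1s %*% G1 %*% phi1s)) * sqrt(drop(phi2s %*% G2 %*% phi2s))
  # single loading on (ind0, grp0)
  c12 <- period_r * denom / (phi2s[1] * phi1s[1])
  G12 <- matrix(0, 3, 2)
  G12[1, 1] <- c12
  G <- rbind(cbind(G1, t(G12)), cbind(G12, G2))
  dimnames(G) <- rep(list(c("grp0", "grp1", "ind0", "ind1", "ind2")), 2)
  check_psd(G, "true_G")
  G
}

check_psd <- function(M, name, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-7)) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    abort(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g).",
                  name, min(ev)))
  }
  invisible(TRUE)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic feed-intake experiment: a two-stage
#' pedigree, partial SNP genotyping, weight-sorted pens sharing feeders
#' (group-level records at two time points), and a disjoint test-station
#' cohort with daily individual records. Default variance levels follow the
#' scale of DanBred-type growing-pig data: mean daily genetic variance about
#' 0.17 (group trait) and 0.10 (individual trait), permanent-environment
#' variance about 0.08, residual variance 1.94 on the animal-day scale for
#' group records, and a mean daily feed-intake curve rising from about 1.5
#' to 3.4 kg/day over the test.
#'
#' @param n_founders Number of unrelated founder animals (half of each sex).
#' @param n_sires Number of distinct sires in service per generation (elite
#'   boars each mated to several dams, giving the half-sib family structure
#'   of a nucleus herd).
#' @param n_generations Number of descendant generations; each generation
#'   mates `floor(n_founders/2)` dam-sire pairs.
#' @param offspring_per_mating Offspring per mating; a vector is recycled
#'   over generations (default: small early generations carrying the
#'   relationship structure, a large final phenotyped generation).
#' @param n_ind_animals Number of final-generation animals routed to the
#'   test station (daily individual records); the remainder form the
#'   weight-sorted group-housing cohort.
#' @param n_snps Number of unlinked SNPs.
#' @param founder_maf_range Range of founder allele frequencies.
#' @param genotyped_fraction Fraction of phenotyped animals genotyped.
#' @param true_G 5x5 covariance of genetic coefficients
#'   `[grp0, grp1, ind0, ind1, ind2]` (see [make_true_G()]).
#' @param true_P1 2x2 group permanent-environment (feeder/pen) covariance.
#' @param true_P2 3x3 individual permanent-environment covariance.
#' @param sigma_e_group Group-record residual variance on the animal-day
#'   scale (a record carries variance `nt/nd * sigma_e_group`).
#' @param sigma_e_ind Length-8 vector of residual variances by
#'   days-on-test class (<=10, 11-20, ..., 61-70, >=71).
#' @param pen_size Animals per pen.
#' @param pens_per_feeder Pens sharing one feeder (a feeding group).
#' @param group_record_days Day-on-test targets of the two group recordings;
#'   recording periods are `1..d1` and `(d1+1)..d2`, each dated at its
#'   mid-point day (floor convention).
#' @param record_day_jitter Half-width of the per-group uniform integer
#'   jitter on the two recording days ("approximately" day 30 and 60: the
#'   realised days differ between groups, which also identifies the group
#'   residual variance separately from the group permanent-environment
#'   covariance).
#' @param pretest_dropout Probability that an assigned animal leaves before
#'   the first recording (group sizes then range below the pen capacity,
#'   as in field data).
#' @param ind_test_length_days Length of the individual test.
#' @param dropout_hazard Probability that a group-housed animal leaves at a
#'   recording-period boundary.
#' @param mean_fi Length-2 vector: population mean daily feed intake (kg/d)
#'   at day 1 and at the last test day (linear in between).
#' @param ym_effect_sd SD of start year-month effects (kg/d).
#' @param weight_mean,weight_sd Start body-weight distribution (kg).
#' @param weight_slope Fixed regression of daily FI on start weight
#'   (kg/d per kg).
#' @param coef_from_snps Generate genetic coefficients from additive SNP
#'   effects instead of pedigree transmission (for demonstrations where the
#'   genomic matrix captures the true relationships).
#' @param groups_per_ym,ind_per_ym Batch sizes sharing one start year-month.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_founders = 200,
                       n_sires = 20,
                       n_generations = 2,
                       offspring_per_mating = c(4, 20),
                       n_ind_animals = 800,
                       n_snps = 2000,
                       founder_maf_range = c(0.05, 0.5),
                       genotyped_fraction = 0.5,
                       true_G = NULL,
                       true_P1 = matrix(c(0.07, 0.01, 0.01, 0.03), 2),
                       true_P2 = diag(c(0.07, 0.02, 0.01)),
                       sigma_e_group = 1.94,
                       sigma_e_ind = c(0.16, 0.18, 0.20, 0.22, 0.24, 0.26, 0.28, 0.30),
                       pen_size = 10,
                       pens_per_feeder = 2,
                       group_record_days = c(30, 60),
                       record_day_jitter = 5,
                       pretest_dropout = 0.02,
                       ind_test_length_days = 75,
                       dropout_hazard = 0.008,
                       mean_fi = c(1.5, 3.4),
                       ym_effect_sd = 0.1,
                       weight_mean = 27,
                       weight_sd = 2.5,
                       weight_slope = 0.02,
                       coef_from_snps = FALSE,
                       groups_per_ym = 8,
                       ind_per_ym = 100) {
  cfg <- list(
    n_founders = n_founders, n_sires = n_sires,
    n_generations = n_generations,
    offspring_per_mating = offspring_per_mating,
    n_ind_animals = n_ind_animals,
    n_snps = n_snps, founder_maf_range = founder_maf_range,
    genotyped_fraction = genotyped_fraction,
    true_P1 = true_P1, true_P2 = true_P2,
    sigma_e_group = sigma_e_group, sigma_e_ind = sigma_e_ind,
    pen_size = pen_size, pens_per_feeder = pens_per_feeder,
    group_record_days = group_record_days,
    record_day_jitter = record_day_jitter,
    pretest_dropout = pretest_dropout,
    ind_test_length_days = ind_test_length_days,
    dropout_hazard = dropout_hazard, mean_fi = mean_fi,
    ym_effect_sd = ym_effect_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_slope = weight_slope,
    coef_from_snps = coef_from_snps,
    groups_per_ym = groups_per_ym, ind_per_ym = ind_per_ym)
  # recording periods and their mid-point days (floor convention)
  d <- unname(group_record_days)
  cfg$group_record_days <- d
  if (length(d) != 2 || d[1] >= d[2]) {
    abort("`group_record_days` must be two strictly increasing days.")
  }
  if (d[1] < 1 || d[2] > ind_test_length_days) {
    abort("`group_record_days` must lie within [1, ind_test_length_days].")
  }
  if (d[1] + record_day_jitter >= d[2] - record_day_jitter) {
    abort("`record_day_jitter` too large for the recording-day targets.")
  }
  cfg$periods <- list(c(start = 1, end = d[1]), c(start = d[1] + 1, end = d[2]))
  cfg$mid_days <- vapply(cfg$periods, function(p) floor((p["start"] + p["end"]) / 2),
                         numeric(1))
  # basis wide enough for the jittered mid-point days
  cfg$basis_grp <- legendre_basis(1, cfg$mid_days[1] - record_day_jitter,
                                  cfg$mid_days[2] + record_day_jitter)
  cfg$basis_ind <- legendre_basis(2, 1, ind_test_length_days)
  cfg$days_grp <- seq(cfg$basis_grp$t_min, cfg$basis_grp$t_max)
  cfg$days_ind <- seq_len(ind_test_length_days)
  cfg$true_G <- true_G %||% make_true_G(
    basis_grp = cfg$basis_grp, basis_ind = cfg$basis_ind,
    days_grp = cfg$days_grp, days_ind = cfg$days_ind)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_psd(cfg$true_G, "true_G")
  check_psd(cfg$true_P1, "true_P1")
  check_psd(cfg$true_P2, "true_P2")
  stopifnot(nrow(cfg$true_G) == 5, nrow(cfg$true_P1) == 2, nrow(cfg$true_P2) == 3)
  if (cfg$sigma_e_group < 0 || any(cfg$sigma_e_ind < 0)) {
    abort("Residual variances must be non-negative.")
  }
  if (length(cfg$sigma_e_ind) != 8) {
    abort("`sigma_e_ind` must hold 8 class variances.")
  }
  for (p in c("genotyped_fraction", "dropout_hazard")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("`%s` must lie in [0, 1].", p))
  }
  if (cfg$founder_maf_range[1] <= 0 || cfg$founder_maf_range[2] > 0.5 ||
      diff(cfg$founder_maf_range) < 0) {
    abort("`founder_maf_range` must be an increasing interval in (0, 0.5].")
  }
  invisible(cfg)
}

#' Map days on test to the 8 residual classes of the individual trait
#'
#' Classes are the intervals `<=10, 11-20, ..., 61-70, >=71`.
#' @param t Integer days on test.
#' @return Integer class in 1..8.
#' @export
dot_class <- function(t) {
  pmin(8L, as.integer(ceiling(t / 10)))
}

# population mean daily FI (kg/d), linear between day 1 and the last day
mean_curve <- function(cfg, t) {
  L <- cfg$ind_test_length_days
  cfg$mean_fi[1] + (cfg$mean_fi[2] - cfg$mean_fi[1]) * (t - 1) / (L - 1)
}
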