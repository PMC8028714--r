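# Covariance-function transforms: per-day variances, heritability and
# genetic-correlation trajectories, whole-period correlation, (G)EBV sums.

#' Per-day variance from a random-regression coefficient covariance
#'
#' Evaluates `phi(t) %*% cov %*% t(phi(t))` on a day grid; applies
#' identically to genetic and permanent-environment coefficient blocks.
#'
#' @param coef_cov Coefficient covariance block (dimension = basis order + 1).
#' @param basis A [legendre_basis()].
#' @param days Days on test to evaluate.
#' @return Tibble `day`, `variance`.
#' @export
variance_trajectory <- function(coef_cov, basis, days) {
  coef_cov <- as.matrix(coef_cov)
  if (nrow(coef_cov) != basis$order + 1) {
    abort(sprintf("Covariance dimension %d does not match basis order %d + 1.",
                  nrow(coef_cov), basis$order))
  }
  phi <- leg_eval(basis, days)
  tibble(day = as.numeric(days),
         variance = rowSums((phi %*% coef_cov) * phi))
}

#' Heritability trajectory over days on test
#'
#' Per-day additive genetic, permanent-environment, residual and phenotypic
#' variances, and the heritability `h2(t) = sigma_a2(t) / sigma_p2(t)`. For
#' the individual trait the residual is the day's class variance; for the
#' group trait it is the homogeneous animal-day residual.
#'
#' @param vc A [variance_components()] (bivariate, or univariate matching
#'   `trait`).
#' @param trait `"group"` or `"individual"`.
#' @param basis Legendre basis of the trait.
#' @param days Day grid.
#' @return Tibble of class `penfeed_trajectory` with columns `day`,
#'   `sigma_a2`, `sigma_pe2`, `sigma_e2`, `sigma_p2`, `h2`.
#' @export
heritability_trajectory <- function(vc, trait = c("group", "individual"),
                                    basis, days) {
  trait <- match.arg(trait)
  nc <- nrow(vc$G)
  if (nc == 5) {
    gs <- split_G(vc$G)
    Gt <- if (trait == "group") gs$G1 else gs$G2
  } else {
    Gt <- vc$G
  }
  Pt <- if (trait == "group") vc$P1 else vc$P2
  sa <- variance_trajectory(Gt, basis, days)$variance
  spe <- if (is.null(Pt)) rep(0, length(days)) else
    variance_trajectory(Pt, basis, days)$variance
  se <- if (trait == "group") {
    if (is.null(vc$sigma_e_group)) abort("`sigma_e_group` missing from `vc`.")
    rep(vc$sigma_e_group, length(days))
  } else {
    if (is.null(vc$sigma_e_ind)) abort("`sigma_e_ind` missing from `vc`.")
    vc$sigma_e_ind[dot_class(days)]
  }
  sp <- sa + spe + se
  h2 <- ifelse(sp > 0, sa / sp, NA_real_)
  if (any(sp <= 0)) {
    warn("Zero phenotypic variance on some days; heritability undefined there (NA).")
  }
  structure(tibble(day = as.numeric(days), sigma_a2 = sa, sigma_pe2 = spe,
                   sigma_e2 = se, sigma_p2 = sp, h2 = h2,
                   trait = trait),
            class = c("penfeed_trajectory", "tbl_df", "tbl", "data.frame"))
}

#' Daily genetic correlation between group- and individual-level intake
#'
#' `r_t = phi_t2 G12 phi_t1' / sqrt(phi_t1 G1 phi_t1') / sqrt(phi_t2 G2
#' phi_t2')` per day, with `G1`, `G2`, `G12` the blocks of the bivariate
#' coefficient covariance.
#'
#' @param vc Bivariate [variance_components()] (5x5 `G`).
#' @param basis_grp,basis_ind Trait bases.
#' @param days Common day grid (defaults to the intersection of the two
#'   basis ranges, integer days).
#' @return Tibble `day`, `r` (`NA` where a trait has zero variance).
#' @export
daily_genetic_correlation <- function(vc, basis_grp, basis_ind, days = NULL) {
  if (nrow(vc$G) != 5) abort("Daily genetic correlation needs the bivariate 5x5 G.")
  days <- days %||% seq(max(basis_grp$t_min, basis_ind$t_min),
                        min(basis_grp$t_max, basis_ind$t_max))
  gs <- split_G(vc$G)
  p1 <- leg_eval(basis_grp, days)
  p2 <- leg_eval(basis_ind, days)
  v1 <- rowSums((p1 %*% gs$G1) * p1)
  v2 <- rowSums((p2 %*% gs$G2) * p2)
  cv <- rowSums((p2 %*% gs$G12) * p1)
  r <- ifelse(v1 > 0 & v2 > 0, cv / sqrt(v1 * v2), NA_real_)
  if (any(v1 <= 0 | v2 <= 0)) {
    warn("Zero genetic variance on some days; correlation undefined there (NA).")
  }
  tibble(day = as.numeric(days), r = r)
}

#' Whole-period genetic correlation between the two traits
#'
#' Column sums of each trait's daily covariate matrix give the summed
#' covariate vectors `phi1*` (2 entries) and `phi2*` (3 entries); the
#' period correlation is
#' `phi2* G12 phi1*' / sqrt(phi1* G1 phi1*') / sqrt(phi2* G2 phi2*')` --
#' the correlation of breeding values summed over the test days.
#'
#' @inheritParams daily_genetic_correlation
#' @param days_grp,days_ind Day grids summed over for each trait.
#' @return Scalar correlation.
#' @export
period_genetic_correlation <- function(vc, basis_grp, basis_ind,
                                       days_grp, days_ind) {
  if (nrow(vc$G) != 5) abort("Period genetic correlation needs the bivariate 5x5 G.")
  gs <- split_G(vc$G)
  phi1s <- colSums(leg_eval(basis_grp, days_grp))
  phi2s <- colSums(leg_eval(basis_ind, days_ind))
  v1 <- drop(phi1s %*% gs$G1 %*% phi1s)
  v2 <- drop(phi2s %*% gs$G2 %*% phi2s)
  if (v1 <= 0 || v2 <= 0) {
    warn("Zero period genetic variance; correlation undefined (NA).")
    return(NA_real_)
  }
  drop(phi2s %*% gs$G12 %*% phi1s) / sqrt(v1 * v2)
}

#' Daily and period-summed (G)EBV from fitted genetic coefficients
#'
#' The (G)EBV of animal `i` on day `t` is `phi(t) %*% a_i`; the period
#' value sums the daily values over the requested day set.
#'
#' @param coef_tbl Tibble of genetic coefficient solutions: column `animal`
#'   plus one column per coefficient (matching the basis order + 1).
#' @param basis Trait basis.
#' @param days Day set summed over.
#' @param animals Optional subset of animals.
#' @return List with `daily` (tibble `animal`, `day`, `ebv`) and `period`
#'   (tibble `animal`, `ebv`).
#' @export
ebv_period_sum <- function(coef_tbl, basis, days, animals = NULL) {
  coef_tbl <- as_tibble(coef_tbl)
  if (!is.null(animals)) {
    miss <- setdiff(animals, coef_tbl$animal)
    if (length(miss)) {
      abort(paste0("No genetic solutions for animal(s): ",
                   paste(utils::head(miss, 5), collapse = ", ")))
    }
    coef_tbl <- coef_tbl[match(animals, coef_tbl$animal), , drop = FALSE]
  }
  A <- as.matrix(coef_tbl[, setdiff(names(coef_tbl), "animal"), drop = FALSE])
  phi <- leg_eval(basis, days)
  if (ncol(A) != ncol(phi)) {
    abort("Coefficient count does not match the basis order + 1.")
  }
  D <- A %*% t(phi) # n x length(days)
  daily <- tibble(animal = rep(coef_tbl$animal, times = length(days)),
                  day = rep(as.numeric(days), each = nrow(A)),
                  ebv = as.numeric(D))
  period <- tibble(animal = coef_tbl$animal, ebv = rowSums(D))
  list(daily = daily, period = period)
}

#' Monte-Carlo standard errors for trajectory functionals
#'
#' Draws variance-component parameter vectors from the asymptotic normal
#' distribution implied by the inverse average-information matrix, projects
#' each draw onto the PSD cone, recomputes the requested functional, and
#' reports per-day standard deviations.
#'
#' @param fit A `penfeed_reml` fit with an invertible AI matrix.
#' @param functional One of `"h2_group"`, `"h2_individual"`, `"r_daily"`.
#' @param basis_grp,basis_ind Bases (as used in the fit).
#' @param days Day grid.
#' @param n_draws Number of parameter draws.
#' @param seed Seed for the draws.
#' @return Tibble `day`, `estimate`, `se`.
#' @export
trajectory_se <- function(fit, functional = c("h2_group", "h2_individual", "r_daily"),
                          basis_grp = NULL, basis_ind = NULL, days,
                          n_draws = 10000, seed = 1) {
  functional <- match.arg(functional)
  ai <- fit$ai_matrix
  if (is.null(ai)) abort("Fit carries no AI matrix.")
  aiinv <- tryCatch(solve(ai), error = function(e) {
    abort("AI matrix is not invertible; no asymptotic covariance available.")
  })
  aiinv <- (aiinv + t(aiinv)) / 2
  theta <- vc_flatten(fit$vc, fit$param_map)
  e <- eigen(aiinv, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  set.seed(seed)
  draws <- matrix(rnorm(n_draws * length(theta)), n_draws) %*% rt
  draws <- sweep(draws, 2, theta, "+")
  eval_fun <- function(th) {
    vci <- vc_unflatten(th, fit$param_map, floor_psd = TRUE)
    switch(functional,
      h2_group = heritability_trajectory(vci, "group", basis_grp, days)$h2,
      h2_individual = heritability_trajectory(vci, "individual", basis_ind, days)$h2,
      r_daily = daily_genetic_correlation(vci, basis_grp, basis_ind, days)$r)
  }
  est <- eval_fun(theta)
  acc <- matrix(NA_real_, n_draws, length(days))
  for (i in seq_len(n_draws)) acc[i, ] <- eval_fun(draws[i, ])
  tibble(day = as.numeric(days), estimate = est,
         se = apply(acc, 2, stats::sd, na.rm = TRUE))
}
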