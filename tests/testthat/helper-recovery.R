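# Shared heavy fixture: replicated parameter-recovery simulations with
# bivariate AI-REML fits and leave-one-group-out cross-validation under the
# three model variants. Computed once per test run and cached; both the
# recovery and the prediction-ordering checks draw on it.
#
# Study conditions: 60 feeding groups of 20 (weight-sorted pens, two pens
# per feeder), 800 individually recorded animals over 60 days, 50% of
# phenotyped animals genotyped, true whole-period genetic correlation 0.3,
# individual-trait mean daily heritability about 0.25, group residual on
# the animal-day scale much larger than the genetic variance. Genetic
# coefficients are generated from additive SNP effects so that the genomic
# relationship matrix carries real information beyond the pedigree.

.penfeed_cache <- new.env(parent = emptyenv())

recovery_config <- function() {
  sim_config(ind_test_length_days = 60, coef_from_snps = TRUE)
}

recovery_replicates <- function(n_reps = 10, n_cv = 10) {
  key <- sprintf("recovery_%d_%d", n_reps, n_cv)
  if (!is.null(.penfeed_cache[[key]])) return(.penfeed_cache[[key]])
  cfg <- recovery_config()
  spec_bi <- model_spec("bivariate")
  spec_un <- model_spec("univariate_group")
  tr_mean <- function(M, b, d) mean(variance_trajectory(M, b, d)$variance)
  rows <- list(); cv_rows <- list()
  for (rep in seq_len(n_reps)) {
    sim <- simulate_population(cfg, seed = 1000 + rep)
    sim$pedigree <- ped_prune(sim$pedigree,
                              c(unlist(sim$grp_records$present),
                                sim$ind_records$animal,
                                rownames(sim$genotypes)))
    des <- build_design(sim, spec_bi, basis_grp = cfg$basis_grp,
                        basis_ind = cfg$basis_ind)
    Kinv <- ainverse(sim$pedigree)
    # each replicate estimated independently from its own cold start
    fit <- suppressWarnings(ai_reml(des, Kinv, max_iter = 15, par_tol = 1e-3))
    vc <- fit$vc
    rows[[rep]] <- tibble::tibble(
      rep = rep,
      gen_grp = tr_mean(vc$G[1:2, 1:2], cfg$basis_grp, cfg$days_grp),
      gen_ind = tr_mean(vc$G[3:5, 3:5], cfg$basis_ind, cfg$days_ind),
      pe_grp = tr_mean(vc$P1, cfg$basis_grp, cfg$days_grp),
      pe_ind = tr_mean(vc$P2, cfg$basis_ind, cfg$days_ind),
      se_grp = vc$sigma_e_group,
      se_ind = mean(vc$sigma_e_ind, na.rm = TRUE),
      period_r = period_genetic_correlation(vc, cfg$basis_grp, cfg$basis_ind,
                                            cfg$days_grp, cfg$days_ind),
      logL = fit$logLik, iters = fit$iterations)
    if (rep <= n_cv) {
      # pre-estimated variance components (full data, pedigree-based), as
      # in the validation design; the univariate variant refits its own
      desu <- build_design(sim, spec_un, basis_grp = cfg$basis_grp)
      fitu <- suppressWarnings(ai_reml(desu, Kinv, max_iter = 10, par_tol = 1e-3))
      Hmat <- gmatrix(sim$genotypes)
      Hi <- hinverse(sim$pedigree, Hmat)
      cv_ss <- suppressWarnings(run_logo_cv(
        sim, vc, model_spec("bivariate", relationship = "H"), Hi,
        basis_grp = cfg$basis_grp, basis_ind = cfg$basis_ind))
      cv_bp <- suppressWarnings(run_logo_cv(
        sim, vc, spec_bi, Kinv,
        basis_grp = cfg$basis_grp, basis_ind = cfg$basis_ind))
      cv_up <- suppressWarnings(run_logo_cv(
        sim, fitu$vc, spec_un, Kinv, basis_grp = cfg$basis_grp))
      grab <- function(cv, lab) tibble::tibble(
        rep = rep, variant = lab,
        rho_fr = cv$stats$rho_fr[cv$stats$stratum == "all"],
        b_fr = cv$stats$b_fr[cv$stats$stratum == "all"],
        rho_yc_r = cv$stats$rho_yc_r[cv$stats$stratum == "group"],
        b_yc_r = cv$stats$b_yc_r[cv$stats$stratum == "group"])
      cv_rows[[length(cv_rows) + 1L]] <- dplyr::bind_rows(
        grab(cv_ss, "bivariate_ssGBLUP"),
        grab(cv_bp, "bivariate_PBLUP"),
        grab(cv_up, "univariate_PBLUP"))
    }
  }
  truth <- list(
    gen_grp = tr_mean(cfg$true_G[1:2, 1:2], cfg$basis_grp, cfg$days_grp),
    gen_ind = tr_mean(cfg$true_G[3:5, 3:5], cfg$basis_ind, cfg$days_ind),
    pe_grp = tr_mean(cfg$true_P1, cfg$basis_grp, cfg$days_grp),
    pe_ind = tr_mean(cfg$true_P2, cfg$basis_ind, cfg$days_ind),
    se_grp = cfg$sigma_e_group,
    se_ind = mean(cfg$sigma_e_ind[sort(unique(dot_class(cfg$days_ind)))]),
    period_r = 0.3)
  out <- list(estimates = dplyr::bind_rows(rows),
              cv = dplyr::bind_rows(cv_rows), truth = truth, config = cfg)
  .penfeed_cache[[key]] <- out
  out
}
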