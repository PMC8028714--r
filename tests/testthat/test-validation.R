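cv_toy <- function(seed = 51) {
  cfg <- sim_config(n_founders = 60, n_sires = 10, n_generations = 2,
                    offspring_per_mating = c(4, 12), n_ind_animals = 60,
                    n_snps = 150, pen_size = 5, groups_per_ym = 100,
                    ind_test_length_days = 60)
  sim <- simulate_population(cfg, seed = seed)
  list(cfg = cfg, sim = sim,
       vt = variance_components(cfg$true_G[1:2, 1:2], P1 = cfg$true_P1,
                                sigma_e_group = cfg$sigma_e_group))
}

test_that("comparison statistics have their algebraic closed forms", {
  x <- c(1, 2, 3, 4)
  s <- lr_statistics(x, x)
  expect_equal(s$rho_fr, 1)
  expect_equal(s$b_fr, 1)
  # reduced twice as dispersed as full: slope of full on reduced is 1/2
  s2 <- lr_statistics(x, 2 * x)
  expect_equal(s2$b_fr, 0.5)
  # hand-computed 4-point regression
  full <- c(1, 2, 3, 4); red <- c(2, 3, 5, 6)
  s3 <- lr_statistics(full, red, y_c = c(1.5, 2.5, 4.5, 5.5))
  expect_equal(s3$rho_fr, cor(full, red))
  expect_equal(s3$b_fr, cov(full, red) / var(red))
  expect_equal(s3$b_yc_r, cov(c(1.5, 2.5, 4.5, 5.5), red) / var(red))
  expect_true(is.na(suppressWarnings(lr_statistics(full, rep(1, 4)))$rho_fr))
  # correlations invariant to affine rescaling; slope scales inversely
  a <- rnorm(10); b <- a + rnorm(10, 0, 0.3)
  expect_equal(lr_statistics(a, b)$rho_fr, lr_statistics(2 + 3 * a, 2 + 3 * b)$rho_fr)
  expect_equal(lr_statistics(a, 10 * b)$b_fr, lr_statistics(a, b)$b_fr / 10)
})

test_that("audit-mode cross-validation returns exact identities", {
  t <- cv_toy()
  cv <- suppressWarnings(run_logo_cv(t$sim, t$vt, model_spec("univariate_group"),
                                     ainverse(t$sim$pedigree),
                                     basis_grp = t$cfg$basis_grp, audit = TRUE))
  st <- cv$stats[cv$stats$stratum == "all", ]
  expect_equal(st$rho_fr, 1)
  expect_equal(st$b_fr, 1)
  expect_true(all(cv$group$d_fr == 0))
})

test_that("each fold's downdated solutions equal a direct reduced-data refit", {
  t <- cv_toy()
  spec <- model_spec("univariate_group")
  Kinv <- ainverse(t$sim$pedigree)
  cv <- suppressWarnings(run_logo_cv(t$sim, t$vt, spec, Kinv,
                                     basis_grp = t$cfg$basis_grp))
  expect_equal(cv$n_folds, dplyr::n_distinct(t$sim$grp_records$group))
  gids <- unique(t$sim$grp_records$group)[1:2]
  des_full <- build_design(t$sim, spec, basis_grp = t$cfg$basis_grp)
  for (g1 in gids) {
    ds2 <- t$sim
    ds2$grp_records <- ds2$grp_records[ds2$grp_records$group != g1, ]
    fit2 <- assemble_and_solve(build_design(ds2, spec, basis_grp = t$cfg$basis_grp),
                               t$vt, Kinv)
    eb <- penfeed:::period_ebv_by_group(fit2$genetic, des_full)
    direct <- eb$animal[eb$animal$group == as.character(g1), ]
    wood <- cv$animal[cv$animal$group == as.character(g1), ]
    m <- dplyr::inner_join(wood, dplyr::rename(direct, ebv_direct = "ebv"),
                           by = c("group", "animal"))
    expect_lt(max(abs(m$ebv_reduced - m$ebv_direct)), 1e-8)
  }
  # animal strata partition the group-recorded animals
  expect_equal(sum(cv$animal$stratum == "genotyped") +
                 sum(cv$animal$stratum == "non_genotyped"), nrow(cv$animal))
})

test_that("corrected phenotypes decompose into summed breeding values plus residuals", {
  t <- cv_toy()
  spec <- model_spec("univariate_group")
  des <- build_design(t$sim, spec, basis_grp = t$cfg$basis_grp)
  Kinv <- ainverse(t$sim$pedigree)
  fit <- assemble_and_solve(des, t$vt, Kinv)
  yc <- corrected_group_phenotypes(fit)
  # hand-assembled for two groups: sum over records of member daily EBV + residual
  g <- des$grp_records
  res <- fit$residuals[fit$residuals$trait == "group", ]
  for (gid in unique(g$group)[1:2]) {
    rows <- which(g$group == gid)
    val <- 0
    for (r in rows) {
      phi <- drop(leg_eval(des$basis_grp, g$day[r]))[1:2]
      idx <- match(g$present[[r]], fit$genetic$animal)
      val <- val + sum(as.matrix(fit$genetic[idx, -1]) %*% phi) + res$resid[r]
    }
    expect_equal(yc$y_c[yc$group == as.character(gid)], val, tolerance = 1e-10)
  }
  # zero genetic variance: corrected phenotypes reduce to summed residuals
  eps <- 1e-12
  vc0 <- variance_components(diag(eps, 2), P1 = t$vt$P1,
                             sigma_e_group = t$vt$sigma_e_group)
  fit0 <- assemble_and_solve(des, vc0, Kinv)
  yc0 <- corrected_group_phenotypes(fit0)
  res0 <- fit0$residuals[fit0$residuals$trait == "group", ]
  agg <- tapply(res0$resid, res0$group, sum)
  expect_equal(yc0$y_c, as.numeric(agg[yc0$group]), tolerance = 1e-6)
})

test_that("near-zero heritability leaves no predictive signal", {
  t <- cv_toy()
  cfg0 <- t$cfg
  cfg0$true_G <- diag(1e-6, 5)
  attr(cfg0, "class") <- "sim_config"
  sim0 <- simulate_population(cfg0, seed = 77)
  vc0 <- variance_components(diag(1e-6, 2), P1 = cfg0$true_P1,
                             sigma_e_group = cfg0$sigma_e_group)
  cv <- suppressWarnings(run_logo_cv(sim0, vc0, model_spec("univariate_group"),
                                     ainverse(sim0$pedigree),
                                     basis_grp = cfg0$basis_grp))
  r <- cv$stats$rho_yc_r[cv$stats$stratum == "group"]
  expect_lt(abs(r), 0.35) # Monte-Carlo noise band around zero
})
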