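test_that("per-day variances follow the covariance-function closed forms", {
  b <- legendre_basis(1, 1, 60)
  v <- variance_trajectory(diag(2), b, c(1, 30.5, 60))
  expect_equal(v$variance, c(2, 1, 2)) # 1 + x(t)^2
  B <- matrix(c(0.2, 0.05, 0.05, 0.1), 2)
  expect_equal(variance_trajectory(B, b, 30.5)$variance, 0.2)
  expect_equal(variance_trajectory(B, b, 60)$variance, 0.4) # 0.2 + 2*0.05 + 0.1
  expect_error(variance_trajectory(diag(3), b, 10), "does not match")
})

test_that("daily heritability combines the three variance sources", {
  # constant covariance functions at the field-typical group-trait scale
  vc <- variance_components(G = diag(c(0.17, 0)), P1 = diag(c(0.08, 0)),
                            sigma_e_group = 1.94)
  h <- heritability_trajectory(vc, "group", legendre_basis(1, 15, 45), 15:45)
  expect_equal(unique(round(h$sigma_p2, 10)), 0.17 + 0.08 + 1.94)
  expect_equal(h$h2, rep(0.17 / 2.19, 31), tolerance = 1e-12)
  expect_equal(round(h$h2[1], 3), 0.078)
  # no genetic variance: zero heritability everywhere
  vc0 <- variance_components(G = diag(0, 2), P1 = diag(c(0.08, 0)),
                             sigma_e_group = 1.94)
  expect_true(all(heritability_trajectory(vc0, "group",
                                          legendre_basis(1, 15, 45), 15:45)$h2 == 0))
})

test_that("crossing a residual-class boundary changes only the residual part", {
  vc <- variance_components(G = diag(c(0.1, 0, 0)), P2 = diag(c(0.05, 0, 0)),
                            sigma_e_ind = c(0.2, 0.4, rep(0.4, 6)))
  h <- heritability_trajectory(vc, "individual", legendre_basis(2, 1, 60),
                               c(10, 11))
  expect_equal(h$sigma_e2, c(0.2, 0.4))
  expect_equal(h$sigma_a2[1], h$sigma_a2[2], tolerance = 1e-6)
  expect_equal(h$h2, 0.1 / (0.1 + 0.05 + c(0.2, 0.4)), tolerance = 1e-6)
})

test_that("daily genetic correlations follow the cross-covariance closed form", {
  bg <- legendre_basis(1, 15, 45)
  bi <- legendre_basis(2, 1, 60)
  G0 <- as.matrix(Matrix::bdiag(diag(2) * 0.2, diag(3) * 0.1))
  vc0 <- variance_components(G0)
  r0 <- daily_genetic_correlation(vc0, bg, bi, 15:45)
  expect_true(all(r0$r == 0))
  # rank-1 cross structure: every coefficient proportional to one factor
  Gp <- tcrossprod(c(1, 0.2, 0.5, 0.1, 0.05))
  vc1 <- variance_components(Gp + diag(1e-12, 5))
  r1 <- daily_genetic_correlation(vc1, bg, bi, 15:45)
  expect_true(all(abs(r1$r - 1) < 1e-4))
})

test_that("daily and period correlations match Monte-Carlo coefficient draws", {
  set.seed(40)
  bg <- legendre_basis(1, 15, 45)
  bi <- legendre_basis(2, 1, 60)
  G1 <- diag(2); G2 <- diag(3)
  G12 <- matrix(0, 3, 2); G12[1, 1] <- 0.3
  G <- rbind(cbind(G1, t(G12)), cbind(G12, G2))
  vc <- variance_components(G)
  n <- 1e6
  draws <- matrix(rnorm(n * 5), n) %*% chol(G)
  days_g <- 15:45; days_i <- 1:60
  # daily check on three days
  for (d in c(15, 30, 45)) {
    p1 <- drop(leg_eval(bg, d)); p2 <- drop(leg_eval(bi, d))
    bv_g <- draws[, 1:2] %*% p1
    bv_i <- draws[, 3:5] %*% p2
    r_mc <- cor(bv_g, bv_i)
    r_cl <- daily_genetic_correlation(vc, bg, bi, d)$r
    expect_lt(abs(r_mc - r_cl), 0.01)
  }
  # whole-period: correlation of period-summed breeding values
  s1 <- colSums(leg_eval(bg, days_g)); s2 <- colSums(leg_eval(bi, days_i))
  r_mc <- cor(draws[, 1:2] %*% s1, draws[, 3:5] %*% s2)
  r_cl <- period_genetic_correlation(vc, bg, bi, days_g, days_i)
  expect_lt(abs(r_mc - r_cl), 0.01)
  # order-0 bases collapse the period correlation onto the daily one
  G00 <- matrix(c(G[1, 1], G[1, 3], G[3, 1], G[3, 3]), 2)
  # only intercepts active: the period correlation collapses to the
  # (constant) daily correlation
  G5 <- matrix(0, 5, 5)
  G5[1, 1] <- G00[1, 1]; G5[3, 3] <- G00[2, 2]
  G5[1, 3] <- G5[3, 1] <- G00[1, 2]
  vc5 <- variance_components(G5)
  expect_equal(period_genetic_correlation(vc5, bg, bi, days_g, days_i),
               daily_genetic_correlation(vc5, bg, bi, 30)$r, tolerance = 1e-9)
})

test_that("correlations always lie in [-1, 1] for random PSD covariances", {
  set.seed(41)
  bg <- legendre_basis(1, 15, 45)
  bi <- legendre_basis(2, 1, 60)
  for (k in 1:25) {
    G <- rand_pd(5, 0.3)
    vc <- variance_components(G)
    r <- daily_genetic_correlation(vc, bg, bi, 15:45)$r
    expect_true(all(r >= -1 - 1e-10 & r <= 1 + 1e-10))
    rp <- period_genetic_correlation(vc, bg, bi, 15:45, 1:60)
    expect_true(rp >= -1 - 1e-10 && rp <= 1 + 1e-10)
  }
})

test_that("period breeding values sum the daily values", {
  b <- legendre_basis(1, 1, 61)
  co <- tibble::tibble(animal = 1:3, grp0 = c(1, 0, 0.5), grp1 = c(0, 1, 0.2))
  # intercept only: period sum = number of days
  days <- c(11, 31, 51) # symmetric about day 31
  e <- ebv_period_sum(co, b, days)
  expect_equal(e$period$ebv[1], 3)
  expect_equal(e$period$ebv[2], 0, tolerance = 1e-12) # odd term cancels
  phi <- leg_eval(b, c(15, 45))
  e2 <- ebv_period_sum(co[3, ], b, c(15, 45))
  expect_equal(e2$period$ebv, sum(phi %*% c(0.5, 0.2)))
  # additivity over a partition of the day set
  all_days <- ebv_period_sum(co, b, 1:61)$period$ebv
  part <- ebv_period_sum(co, b, 1:30)$period$ebv +
    ebv_period_sum(co, b, 31:61)$period$ebv
  expect_equal(all_days, part)
  expect_error(ebv_period_sum(co, b, days, animals = 99), "No genetic solutions")
})

test_that("simulation-based standard errors track the analytic delta method", {
  # scalar toy: h2 = g / (g + e); asymptotic covariance diag(v_g, v_e)
  g <- 0.3; e <- 0.7
  v_g <- 0.004; v_e <- 0.009
  fit <- list(
    vc = structure(list(G = matrix(g), P1 = NULL, P2 = NULL,
                        sigma_e_group = e, sigma_e_ind = NULL),
                   class = "variance_components"),
    ai_matrix = diag(1 / c(v_g, v_e)),
    param_map = list(nc = 1, np1 = 0, np2 = 0, has_p1 = FALSE, has_p2 = FALSE,
                     labels = "grp", iG = 1, iP1 = integer(0), iP2 = integer(0),
                     iR = 2, n_theta = 2))
  b0 <- legendre_basis(0, 1, 10)
  se <- trajectory_se(fit, "h2_group", basis_grp = b0, days = 5,
                      n_draws = 20000, seed = 2)
  # first-order delta method for g/(g+e)
  d <- c(e, -g) / (g + e)^2
  se_analytic <- sqrt(sum(d^2 * c(v_g, v_e)))
  expect_lt(abs(se$se - se_analytic) / se_analytic, 0.1)
  se_b <- trajectory_se(fit, "h2_group", basis_grp = b0, days = 5,
                        n_draws = 40000, seed = 3)
  expect_lt(abs(se_b$se - se$se) / se$se, 0.05)
  # degenerate asymptotic covariance: zero uncertainty
  fit0 <- fit; fit0$ai_matrix <- diag(1e12, 2)
  se0 <- trajectory_se(fit0, "h2_group", basis_grp = b0, days = 5,
                       n_draws = 2000, seed = 4)
  expect_lt(se0$se, 1e-5)
})

test_that("variance trajectories are invariant to the basis parameterisation", {
  # mapping the day range [a1,b1] -> [a2,b2] transforms the covariates
  # linearly, phi2(t) = phi1(t) T; the transformed coefficient covariance
  # B2 = T^{-1} B1 T^{-T} reproduces the same per-day variances
  b1 <- legendre_basis(1, 1, 60)
  b2 <- legendre_basis(1, 11, 100)
  days <- seq(11, 60)
  P1 <- leg_eval(b1, days); P2 <- leg_eval(b2, days)
  T <- solve(crossprod(P2), crossprod(P2, P1)) # exact linear map
  B1 <- matrix(c(0.2, 0.05, 0.05, 0.1), 2)
  B2 <- T %*% B1 %*% t(T)
  v1 <- variance_trajectory(B1, b1, days)$variance
  v2 <- variance_trajectory(B2, b2, days)$variance
  expect_equal(v1, v2, tolerance = 1e-10)
})
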