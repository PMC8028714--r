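test_that("MME solutions and likelihood match the dense oracle on random toys", {
  for (seed in 1:5) {
    toy <- rand_toy_dataset(seed, bivariate = seed %% 2 == 0)
    spec <- if (seed %% 2 == 0) model_spec("bivariate") else
      model_spec("univariate_group")
    des <- build_design(toy, spec)
    set.seed(seed + 100)
    vc <- rand_vc(spec)
    Kinv <- ainverse(toy$pedigree)
    A <- amatrix(toy$pedigree)
    fit <- assemble_and_solve(des, vc, Kinv)
    oracle <- dense_blup(des, vc, A)
    # relative to the solution scale (fixed effects sit at the group-record
    # magnitude of tens of kg/d)
    expect_lt(max(abs(fit$fixed$estimate - oracle$b)) /
                max(1, max(abs(oracle$b))), 1e-7)
    expect_lt(max(abs(as.numeric(t(as.matrix(fit$genetic[, -1]))) - oracle$u)) /
                max(1, max(abs(oracle$u))), 1e-7)
    expect_equal(fit$logLik, oracle$logL, tolerance = 1e-7)
  }
})

test_that("the likelihood is invariant to record order", {
  toy <- rand_toy_dataset(31)
  spec <- model_spec("bivariate")
  set.seed(31)
  vc <- rand_vc(spec)
  Kinv <- ainverse(toy$pedigree)
  l1 <- restricted_loglik(build_design(toy, spec), vc, Kinv)
  toy2 <- toy
  set.seed(1)
  toy2$ind_records <- toy2$ind_records[sample(nrow(toy2$ind_records)), ]
  toy2$grp_records <- toy2$grp_records[sample(nrow(toy2$grp_records)), ]
  l2 <- restricted_loglik(build_design(toy2, spec), vc, Kinv)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("a parentless-data animal's solution is its parents' average", {
  toy <- rand_toy_dataset(7, bivariate = FALSE)
  ped <- toy$pedigree
  # add an offspring of two recorded animals, itself without records
  parents <- toy$grp_records$present[[1]][1:2]
  newid <- max(ped$animal) + 1L
  toy$pedigree <- rbind(ped, tibble::tibble(animal = newid, sire = parents[1],
                                            dam = parents[2]))
  spec <- model_spec("univariate_group")
  des <- build_design(toy, spec)
  set.seed(7)
  vc <- rand_vc(spec)
  fit <- assemble_and_solve(des, vc, ainverse(toy$pedigree))
  gen <- fit$genetic
  child <- as.numeric(gen[gen$animal == newid, -1])
  pa <- colMeans(as.matrix(gen[gen$animal %in% parents, -1]))
  expect_equal(child, unname(pa), tolerance = 1e-8)
})

test_that("vanishing random variances push solutions to weighted least squares", {
  toy <- rand_toy_dataset(8, bivariate = FALSE)
  spec <- model_spec("univariate_group")
  des <- build_design(toy, spec)
  eps <- 1e-10
  vc <- variance_components(diag(eps, 2), P1 = diag(eps, 2), sigma_e_group = 1)
  fit <- assemble_and_solve(des, vc, ainverse(toy$pedigree))
  expect_lt(max(abs(as.matrix(fit$genetic[, -1]))), 1e-5)
  X <- as.matrix(des$X)
  Winv <- diag(1 / des$rw)
  b_wls <- solve(t(X) %*% Winv %*% X, t(X) %*% Winv %*% des$y)
  expect_equal(fit$fixed$estimate, as.numeric(b_wls), tolerance = 1e-4)
})

test_that("residual orthogonality holds at the solution", {
  toy <- rand_toy_dataset(9)
  spec <- model_spec("bivariate")
  des <- build_design(toy, spec)
  set.seed(9)
  vc <- rand_vc(spec)
  fit <- assemble_and_solve(des, vc, ainverse(toy$pedigree))
  ms <- fit$raw
  g <- as.numeric(Matrix::crossprod(des$X, ms$rinv * ms$resid))
  expect_lt(max(abs(g)) / max(abs(des$y)), 1e-6)
})

test_that("constraining the bivariate cross blocks to zero reproduces univariate fits", {
  toy <- rand_toy_dataset(12)
  Kinv <- ainverse(toy$pedigree)
  spec_bi <- model_spec("bivariate")
  des_bi <- build_design(toy, spec_bi,
                         basis_grp = legendre_basis(1, 10, 50),
                         basis_ind = legendre_basis(2, 1, 60))
  set.seed(12)
  vc_bi <- rand_vc(spec_bi)
  vc_bi$G[1:2, 3:5] <- 0
  vc_bi$G[3:5, 1:2] <- 0
  fit_bi <- assemble_and_solve(des_bi, vc_bi, Kinv)
  vc_g <- variance_components(vc_bi$G[1:2, 1:2], P1 = vc_bi$P1,
                              sigma_e_group = vc_bi$sigma_e_group)
  des_g <- build_design(toy[c("pedigree", "grp_records")],
                        model_spec("univariate_group"),
                        basis_grp = legendre_basis(1, 10, 50))
  fit_g <- assemble_and_solve(des_g, vc_g, Kinv)
  vc_i <- variance_components(vc_bi$G[3:5, 3:5], P2 = vc_bi$P2,
                              sigma_e_ind = vc_bi$sigma_e_ind)
  des_i <- build_design(toy[c("pedigree", "ind_records")],
                        model_spec("univariate_individual"),
                        basis_ind = legendre_basis(2, 1, 60))
  fit_i <- assemble_and_solve(des_i, vc_i, Kinv)
  m <- match(fit_g$genetic$animal, fit_bi$genetic$animal)
  expect_lt(max(abs(as.matrix(fit_bi$genetic[m, c("grp0", "grp1")]) -
                    as.matrix(fit_g$genetic[, c("grp0", "grp1")]))), 1e-6)
  m2 <- match(fit_i$genetic$animal, fit_bi$genetic$animal)
  expect_lt(max(abs(as.matrix(fit_bi$genetic[m2, c("ind0", "ind1", "ind2")]) -
                    as.matrix(fit_i$genetic[, c("ind0", "ind1", "ind2")]))), 1e-6)
  expect_equal(fit_bi$logLik, fit_g$logLik + fit_i$logLik, tolerance = 1e-6)
})
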