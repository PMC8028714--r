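test_that("group rows sum member covariates and carry nt/nd residual weights", {
  toy <- rand_toy_dataset(seed = 1)
  # force a clean check record: 3 members at the basis midpoint day
  m <- toy$grp_records$members[[1]][1:3]
  toy$grp_records <- toy$grp_records[1, ]
  toy$grp_records$members <- list(m)
  toy$grp_records$present <- list(m)
  toy$grp_records$nt <- 3
  toy$grp_records$nd <- 30
  toy$grp_records$day <- 30
  spec <- model_spec("bivariate")
  des <- build_design(toy, spec, basis_grp = legendre_basis(1, 15, 45),
                      basis_ind = legendre_basis(2, 1, 60))
  row <- des$Z[1, ]
  nz <- which(row != 0)
  # phi(30) = [1, 0] on [15, 45]: each member has 1 in its intercept column
  expect_equal(unname(row[nz]), rep(1, 3))
  apos <- match(m, des$ids)
  expect_equal(sort((nz - 1) %/% des$n_coef + 1), sort(apos))
  expect_equal(des$rw[1], 3 / 30)
})

test_that("group fixed-regression columns enumerate size-by-class cells", {
  toy <- rand_toy_dataset(seed = 2, bivariate = FALSE)
  g <- toy$grp_records
  g$size_class <- rep(c(14, 20, 20), each = 2)
  toy$grp_records <- g
  spec <- model_spec("univariate_group")
  des <- build_design(toy, spec, basis_grp = legendre_basis(1, 10, 50))
  cells <- length(unique(interaction(g$size_class, g$time_point, drop = TRUE)))
  expect_equal(cells, 4)
  n_cell_cols <- sum(grepl("^g_b[0-9]+_cell", c(des$fixed_names, des$dropped_fixed)))
  expect_equal(n_cell_cols, cells * (spec$nf_grp + 1))
})

test_that("records referencing animals outside the pedigree are rejected", {
  toy <- rand_toy_dataset(seed = 3)
  toy$grp_records$present[[1]] <- c(toy$grp_records$present[[1]], 999L)
  spec <- model_spec("bivariate")
  expect_error(build_design(toy, spec), "absent from the pedigree")
  toy2 <- rand_toy_dataset(seed = 3)
  toy2$ind_records$animal[1] <- 998L
  expect_error(build_design(toy2, spec), "absent from the pedigree")
})

test_that("records outside the basis range are rejected", {
  toy <- rand_toy_dataset(seed = 4)
  spec <- model_spec("bivariate")
  expect_error(build_design(toy, spec, basis_grp = legendre_basis(1, 20, 40)),
               "outside the basis range")
})

test_that("single-animal groups with one-day periods reduce to an individual-record model", {
  # same records presented as size-1 groups (nt = nd = 1) and as individual
  # records: with matching bases, orders, and residual structure the two
  # designs span the same model and give identical genetic solutions
  set.seed(6)
  ped <- rand_pedigree()
  finals <- tail(ped$animal, 10)
  days <- c(15, 45)
  grp <- dplyr::bind_rows(lapply(seq_along(finals), function(i) {
    tibble::tibble(group = i, time_point = 1:2, day = days,
                   ym = "2016-01", mean_start_weight = 27, size_class = 1,
                   nt = 1, nd = 1, y = rnorm(2, 2.5, 0.6),
                   members = list(finals[i], finals[i]),
                   present = list(finals[i], finals[i]))
  }))
  ind <- tibble::tibble(animal = rep(finals, each = 2),
                        day = rep(days, length(finals)),
                        ym = "2016-01", weight = 27, y = grp$y)
  basis <- legendre_basis(1, 10, 50)
  vc_g <- variance_components(matrix(c(0.2, 0.03, 0.03, 0.08), 2),
                              P1 = matrix(c(0.1, 0.01, 0.01, 0.05), 2),
                              sigma_e_group = 0.4)
  vc_i <- variance_components(vc_g$G, P2 = vc_g$P1, sigma_e_ind = rep(0.4, 8))
  Kinv <- ainverse(ped)
  des_g <- build_design(list(pedigree = ped, grp_records = grp),
                        model_spec("univariate_group"), basis_grp = basis)
  des_i <- build_design(list(pedigree = ped, ind_records = ind),
                        model_spec("univariate_individual", nr_ind = 1,
                                   np_ind = 1, resid_ind = "homogeneous"),
                        basis_ind = basis)
  fit_g <- assemble_and_solve(des_g, vc_g, Kinv)
  fit_i <- assemble_and_solve(des_i, vc_i, Kinv)
  expect_lt(max(abs(as.matrix(fit_g$genetic[, -1]) -
                    as.matrix(fit_i$genetic[, -1]))), 1e-8)
  # fitted values agree too (the fixed-effect columns span the same space,
  # so the restricted likelihoods differ only by a reparameterisation
  # constant while every prediction coincides)
  expect_lt(max(abs(fit_g$residuals$fitted - fit_i$residuals$fitted)), 1e-8)
})
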