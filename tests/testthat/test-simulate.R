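small_cfg <- function(...) {
  sim_config(n_founders = 40, n_sires = 8, n_generations = 2,
             offspring_per_mating = c(4, 8), n_ind_animals = 30,
             n_snps = 60, pen_size = 5, ind_test_length_days = 60, ...)
}

test_that("the same configuration and seed reproduce the dataset exactly", {
  cfg <- small_cfg()
  s1 <- simulate_population(cfg, seed = 9)
  s2 <- simulate_population(cfg, seed = 9)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$grp_records$y, s2$grp_records$y)
  expect_identical(s1$ind_records$y, s2$ind_records$y)
  s3 <- simulate_population(cfg, seed = 10)
  expect_false(identical(s1$grp_records$y, s3$grp_records$y))
})

test_that("a zero genetic covariance produces exactly zero breeding values", {
  cfg <- small_cfg(true_G = matrix(0, 5, 5))
  sim <- suppressWarnings(simulate_population(cfg, seed = 2))
  expect_true(all(as.matrix(sim$truth$coefficients[, -1]) == 0))
})

test_that("full sibs share half of the additive coefficient variation", {
  # many small families: one sib pair per mating keeps the pairs close to
  # independent so the Monte-Carlo tolerance is meaningful
  cfg <- sim_config(n_founders = 4200, n_sires = 2000, n_generations = 1,
                    offspring_per_mating = 2, n_ind_animals = 100,
                    n_snps = 5, ind_test_length_days = 60)
  sim <- simulate_population(cfg, seed = 3)
  ped <- sim$pedigree
  fin <- ped[ped$generation == 1, ]
  fam <- split(fin$animal, paste(fin$sire, fin$dam))
  pairs <- do.call(rbind, lapply(fam, function(a) {
    if (length(a) < 2) return(NULL)
    cbind(a[1], a[2])
  }))
  expect_gte(nrow(pairs), 2000)
  co <- sim$truth$coefficients
  r <- cor(co$ind0[match(pairs[, 1], co$animal)],
           co$ind0[match(pairs[, 2], co$animal)])
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("weight-sorted pens and feeder groups are assigned as specified", {
  cfg <- small_cfg()
  an <- tibble::tibble(animal = 1:40, weight = rnorm(40, 27, 2.5))
  g <- assign_groups(an, sim_config(pen_size = 10, pens_per_feeder = 2,
                                    n_founders = 40))
  expect_equal(sum(!is.na(g$group)), 40)
  expect_equal(dplyr::n_distinct(g$group), 2)
  expect_true(all(table(g$group) == 20))
  # too few animals for one pen: everyone unassigned
  g9 <- assign_groups(tibble::tibble(animal = 1:9, weight = rnorm(9)),
                      sim_config(pen_size = 10, pens_per_feeder = 2))
  expect_true(all(is.na(g9$group)))
  # sorting: within-pen weight spread below random assignment on average
  set.seed(11)
  sds <- replicate(100, {
    an <- tibble::tibble(animal = 1:40, weight = rnorm(40, 27, 2.5))
    gs <- assign_groups(an, sim_config(pen_size = 10, pens_per_feeder = 2))
    sorted_sd <- mean(tapply(gs$weight, gs$pen, sd))
    shuf <- gs
    shuf$pen <- sample(shuf$pen)
    c(sorted_sd, mean(tapply(shuf$weight, shuf$pen, sd)))
  })
  expect_lt(mean(sds[1, ]), mean(sds[2, ]))
})

test_that("cohorts are disjoint and group records keep consistent bookkeeping", {
  cfg <- small_cfg()
  sim <- simulate_population(cfg, seed = 4)
  grp_animals <- unique(unlist(sim$grp_records$members))
  ind_animals <- unique(sim$ind_records$animal)
  expect_length(intersect(grp_animals, ind_animals), 0)
  g <- sim$grp_records
  expect_true(all(g$nt == lengths(g$present)))
  expect_true(all(lengths(g$members) >= g$nt))
  # drop-outs leave at the period boundary and shrink nt at time point 2
  post <- sim$dropouts$animal[sim$dropouts$drop_day > 0]
  if (length(post)) {
    for (gid in unique(g$group)) {
      n1 <- g$nt[g$group == gid & g$time_point == 1]
      n2 <- g$nt[g$group == gid & g$time_point == 2]
      lost <- length(intersect(post, g$present[g$group == gid & g$time_point == 1][[1]]))
      expect_equal(n1 - lost, n2)
    }
  }
})

test_that("recording periods land on floor mid-point days when jitter is off", {
  cfg <- small_cfg(record_day_jitter = 0, group_record_days = c(30, 60))
  sim <- simulate_population(cfg, seed = 5)
  expect_true(all(sim$grp_records$day[sim$grp_records$time_point == 1] == 15))
  expect_true(all(sim$grp_records$day[sim$grp_records$time_point == 2] == 45))
  expect_true(all(sim$grp_records$nd == 30))
})

test_that("group-record residuals follow the nt/nd scaling law", {
  # all genetic and permanent-environment variances zero: the spread of the
  # records around the deterministic mean is (nt/nd) * sigma_e
  for (conf in list(c(pen = 3, d1 = 30, d2 = 60), c(pen = 5, d1 = 30, d2 = 60),
                    c(pen = 3, d1 = 20, d2 = 56))) {
    cfg <- sim_config(n_founders = 400, n_sires = 50, n_generations = 1,
                      offspring_per_mating = 22, n_ind_animals = 20,
                      n_snps = 5, pen_size = conf["pen"], pens_per_feeder = 2,
                      group_record_days = c(conf["d1"], conf["d2"]),
                      record_day_jitter = 0, pretest_dropout = 0,
                      dropout_hazard = 0, ym_effect_sd = 0, weight_sd = 1e-9,
                      true_G = matrix(0, 5, 5), true_P1 = matrix(0, 2, 2),
                      true_P2 = diag(0, 3), ind_test_length_days = 60)
    sim <- suppressWarnings(simulate_population(cfg, seed = conf["pen"] * 7))
    g <- sim$grp_records
    resid <- g$y - vapply(seq_len(nrow(g)), function(r) {
      per <- if (g$time_point[r] == 1) seq_len(cfg$periods[[1]]["end"]) else
        seq(cfg$periods[[2]]["start"], cfg$periods[[2]]["end"])
      g$nt[r] * mean(penfeed:::mean_curve(cfg, per)) +
        cfg$weight_slope * g$nt[r] * cfg$weight_mean
    }, numeric(1))
    expect_gte(nrow(g), 400)
    expect_lt(abs(var(resid) / (mean(g$nt / g$nd) * cfg$sigma_e_group) - 1), 0.15)
  }
})

test_that("daily individual records reduce to the deterministic mean when noise-free", {
  cfg <- small_cfg(true_G = matrix(0, 5, 5), true_P1 = matrix(0, 2, 2),
                   true_P2 = diag(0, 3), sigma_e_ind = rep(0, 8),
                   ym_effect_sd = 0, weight_sd = 1e-12)
  sim <- suppressWarnings(simulate_population(cfg, seed = 6))
  r <- sim$ind_records
  expected <- penfeed:::mean_curve(cfg, r$day) + cfg$weight_slope * r$weight
  expect_equal(r$y, expected, tolerance = 1e-9)
})

test_that("day-15 individual record variance matches the closed form", {
  cfg <- sim_config(n_founders = 600, n_sires = 60, n_generations = 1,
                    offspring_per_mating = 20, n_ind_animals = 5500,
                    n_snps = 5, ym_effect_sd = 0, weight_sd = 1e-9,
                    ind_test_length_days = 60)
  sim <- simulate_population(cfg, seed = 7)
  y15 <- sim$ind_records$y[sim$ind_records$day == 15]
  phi <- drop(leg_eval(cfg$basis_ind, 15))
  pred <- drop(phi %*% cfg$true_G[3:5, 3:5] %*% phi) +
    drop(phi %*% cfg$true_P2 %*% phi) + cfg$sigma_e_ind[dot_class(15)]
  expect_gte(length(y15), 5000)
  expect_lt(abs(var(y15) / pred - 1), 0.05)
})

test_that("feeder visits aggregate to daily intake", {
  v <- tibble::tibble(animal = c(1, 1, 2), day = c(3, 3, 3),
                      amount = c(0.5, 0.7, 1.1))
  d <- sum_daily_visits(v)
  expect_equal(d$y[d$animal == 1], 1.2)
  expect_equal(d$y[d$animal == 2], 1.1)
})

test_that("founder coefficient moments recover the configured covariance", {
  cfg <- sim_config(n_founders = 6000, n_sires = 10, n_generations = 0,
                    offspring_per_mating = 1, n_ind_animals = 100,
                    n_snps = 5, ind_test_length_days = 60)
  sim <- simulate_population(cfg, seed = 8)
  co <- as.matrix(sim$truth$coefficients[, -1])
  S <- cov(co)
  scale <- max(diag(cfg$true_G))
  expect_lt(max(abs(S - cfg$true_G)) / scale, 0.05)
})
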