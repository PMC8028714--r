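# Synthetic feed-intake experiment: pedigree, genotypes, weight-sorted pens
# sharing feeders, pooled group records at two time points, and a disjoint
# test-station cohort with daily individual records.

# draw n vectors from MVN(0, Sigma); eigen square root so that exactly
# singular covariances (e.g. an all-zero genetic covariance) are handled.
rmvn0 <- function(n, Sigma) {
  k <- nrow(Sigma)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(rnorm(n * k), n, k) %*% rt
}

#' Simulate a full group- plus individual-recording experiment
#'
#' Generates a multi-generation pedigree, unlinked SNP genotypes by gene
#' dropping, animal-specific random-regression coefficients transmitted
#' through the pedigree (parent average plus Mendelian sampling scaled by
#' the parents' inbreeding), weight-sorted pens combined into feeding
#' groups, pooled group feed-intake records at two time points with
#' boundary drop-outs, and daily individual records with eight
#' heterogeneous residual classes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of `(config, seed)`.
#' @return A `sim_dataset` list: `pedigree`, `animals`, `genotypes`,
#'   `groups`, `grp_records`, `ind_records`, `dropouts`, `truth`, `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_founders = 40, offspring_per_mating = 6,
#'                   n_ind_animals = 40, n_snps = 50)
#' sim <- simulate_population(cfg, seed = 1)
#' }
#' @export
simulate_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config

  ## -- pedigree ------------------------------------------------------------
  n_mat <- floor(cfg$n_founders / 2)
  animal <- seq_len(cfg$n_founders)
  sire <- dam <- rep(0L, cfg$n_founders)
  gen <- rep(0L, cfg$n_founders)
  sex <- rep(c("M", "F"), length.out = cfg$n_founders)
  opm <- rep_len(cfg$offspring_per_mating, cfg$n_generations)
  for (g in seq_len(cfg$n_generations)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(females) < n_mat) {
      abort("Not enough females in the previous generation for the matings.")
    }
    in_service <- sample(males, min(cfg$n_sires, length(males)))
    s <- sample(in_service, n_mat, replace = TRUE)
    d <- sample(females, n_mat, replace = FALSE)
    n_off <- n_mat * opm[g]
    new_ids <- length(animal) + seq_len(n_off)
    animal <- c(animal, new_ids)
    sire <- c(sire, rep(s, each = opm[g]))
    dam <- c(dam, rep(d, each = opm[g]))
    gen <- c(gen, rep(g, n_off))
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
  }
  pedigree <- tibble(animal = animal, sire = sire, dam = dam,
                     generation = gen, sex = sex)
  n <- nrow(pedigree)
  inb <- ped_inbreeding(pedigree)

  ## -- genotypes by gene dropping (unlinked loci) --------------------------
  p <- runif(cfg$n_snps, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  H1 <- matrix(0L, n, cfg$n_snps)
  H2 <- matrix(0L, n, cfg$n_snps)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (s == 0L) {
      H1[i, ] <- rbinom(cfg$n_snps, 1L, p)
    } else {
      pick <- runif(cfg$n_snps) < 0.5
      H1[i, ] <- ifelse(pick, H1[s, ], H2[s, ])
    }
    if (d == 0L) {
      H2[i, ] <- rbinom(cfg$n_snps, 1L, p)
    } else {
      pick <- runif(cfg$n_snps) < 0.5
      H2[i, ] <- ifelse(pick, H1[d, ], H2[d, ])
    }
  }
  dosage <- H1 + H2

  ## -- genetic coefficients ------------------------------------------------
  if (cfg$coef_from_snps) {
    denom <- 2 * sum(p * (1 - p))
    eG <- eigen(cfg$true_G, symmetric = TRUE)
    rtG <- eG$vectors %*% (sqrt(pmax(eG$values, 0)) * t(eG$vectors))
    B <- matrix(rnorm(cfg$n_snps * 5), cfg$n_snps, 5) %*% rtG / sqrt(denom)
    a_coef <- sweep(dosage, 2, 2 * p) %*% B
  } else {
    d_ms <- inb$d[match(pedigree$animal, inb$animal)]
    ms <- rmvn0(n, cfg$true_G) # standard draws scaled per animal below
    a_coef <- matrix(0, n, 5)
    for (i in seq_len(n)) {
      s <- sire[i]; d <- dam[i]
      pa <- numeric(5)
      if (s > 0) pa <- pa + 0.5 * a_coef[s, ]
      if (d > 0) pa <- pa + 0.5 * a_coef[d, ]
      a_coef[i, ] <- pa + sqrt(d_ms[i]) * ms[i, ]
    }
  }
  colnames(a_coef) <- c("grp0", "grp1", "ind0", "ind1", "ind2")

  ## -- cohorts, weights, year-months --------------------------------------
  finals <- pedigree$animal[pedigree$generation == cfg$n_generations]
  if (length(finals) <= cfg$n_ind_animals) {
    abort("Final generation too small for `n_ind_animals` plus a group cohort.")
  }
  ind_cohort <- sort(sample(finals, cfg$n_ind_animals))
  grp_cohort <- setdiff(finals, ind_cohort)
  weight <- setNames(rnorm(length(finals), cfg$weight_mean, cfg$weight_sd), finals)

  groups <- assign_groups(
    tibble(animal = grp_cohort, weight = unname(weight[as.character(grp_cohort)])),
    cfg)
  assigned <- dplyr::filter(groups, !is.na(.data$group))
  n_groups <- if (nrow(assigned)) max(assigned$group) else 0L

  ym_label <- function(batch) {
    # synthetic calendar starting 2015-08
    m0 <- (2015 * 12 + 7) + (batch - 1)
    sprintf("%04d-%02d", m0 %/% 12, m0 %% 12 + 1)
  }
  grp_ym <- ym_label(ceiling(seq_len(max(n_groups, 1L)) / cfg$groups_per_ym))
  ind_ym <- ym_label(ceiling(seq_along(ind_cohort) / cfg$ind_per_ym))
  ym_levels <- unique(c(paste0("g", grp_ym), paste0("i", ind_ym)))
  ym_eff <- setNames(rnorm(length(ym_levels), 0, cfg$ym_effect_sd), ym_levels)

  animals <- tibble(
    animal = finals,
    cohort = ifelse(finals %in% ind_cohort, "individual", "group"),
    weight = unname(weight[as.character(finals)]))
  animals$group <- assigned$group[match(animals$animal, assigned$animal)]
  animals$pen <- assigned$pen[match(animals$animal, assigned$animal)]
  animals$ym <- NA_character_
  animals$ym[animals$cohort == "individual"] <-
    paste0("i", ind_ym)[match(animals$animal[animals$cohort == "individual"], ind_cohort)]
  has_grp <- !is.na(animals$group)
  animals$ym[has_grp] <- paste0("g", grp_ym[animals$group[has_grp]])

  ## -- genotyped subset ----------------------------------------------------
  phenotyped <- c(ind_cohort, assigned$animal)
  n_geno <- round(cfg$genotyped_fraction * length(phenotyped))
  genotyped <- sort(sample(phenotyped, n_geno))
  genotypes <- dosage[match(genotyped, pedigree$animal), , drop = FALSE]
  rownames(genotypes) <- genotyped
  colnames(genotypes) <- paste0("snp", seq_len(cfg$n_snps))

  ## -- dropouts ------------------------------------------------------------
  # pre-test removals (group below pen capacity at time point 1) and
  # boundary drop-outs leaving between the two recording periods
  pre <- assigned$animal[runif(nrow(assigned)) < cfg$pretest_dropout]
  rest <- setdiff(assigned$animal, pre)
  drop1 <- rest[runif(length(rest)) < cfg$dropout_hazard]
  dropouts <- dplyr::bind_rows(
    tibble(animal = pre, drop_day = 0),
    tibble(animal = drop1, drop_day = rep(unname(cfg$periods[[1]]["end"]),
                                          length(drop1))))

  ## -- permanent-environment coefficients ----------------------------------
  pe_grp <- rmvn0(max(n_groups, 1L), cfg$true_P1)
  pe_ind <- rmvn0(length(ind_cohort), cfg$true_P2)
  rownames(pe_ind) <- ind_cohort

  truth <- list(
    coefficients = tibble(animal = pedigree$animal) |>
      dplyr::bind_cols(as_tibble(a_coef)),
    pe_group = tibble(group = seq_len(n_groups),
                      pe0 = pe_grp[seq_len(n_groups), 1],
                      pe1 = pe_grp[seq_len(n_groups), 2]),
    pe_individual = tibble(animal = ind_cohort,
                           pe0 = pe_ind[, 1], pe1 = pe_ind[, 2], pe2 = pe_ind[, 3]),
    ym_effects = tibble(ym = ym_levels, effect = unname(ym_eff)),
    vc = variance_components(cfg$true_G, cfg$true_P1, cfg$true_P2,
                             cfg$sigma_e_group, cfg$sigma_e_ind),
    allele_freqs = p)

  ds <- structure(list(
    pedigree = pedigree, animals = animals, genotypes = genotypes,
    groups = assigned, dropouts = dropouts, truth = truth,
    config = cfg, seed = seed), class = "sim_dataset")

  ds$ind_records <- make_individual_records(ds, cfg)
  ds$grp_records <- make_group_records(ds, cfg)

  # derived truths through the same covariance-function formulas used for
  # estimates, so simulation and analysis agree by construction
  h2g <- heritability_trajectory(truth$vc, trait = "group",
                                 basis = cfg$basis_grp, days = cfg$days_grp)
  h2i <- heritability_trajectory(truth$vc, trait = "individual",
                                 basis = cfg$basis_ind, days = cfg$days_ind)
  ds$truth$h2_group <- h2g
  ds$truth$h2_individual <- h2i
  ds$truth$period_r <- period_genetic_correlation(
    truth$vc, cfg$basis_grp, cfg$basis_ind, cfg$days_grp, cfg$days_ind)
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_dataset> %d animals in pedigree; %d feeding groups (%d group records),\n",
    "  %d individual animals (%d daily records); %d genotyped; %d dropouts\n"),
    nrow(x$pedigree), dplyr::n_distinct(x$groups$group), nrow(x$grp_records),
    sum(x$animals$cohort == "individual"), nrow(x$ind_records),
    nrow(x$genotypes), nrow(x$dropouts)))
  invisible(x)
}

#' Sort animals into weight-matched pens and feeding groups
#'
#' Animals are sorted by start body weight and filled into pens of
#' `pen_size`; `pens_per_feeder` consecutive pens share one feeder and form
#' a feeding group. Animals left over after the last complete group stay
#' unassigned (reported with `NA` group).
#'
#' @param animals Data frame with columns `animal` and `weight`.
#' @param config A [sim_config()] (only `pen_size` and `pens_per_feeder`
#'   are used).
#' @return Tibble `animal`, `weight`, `pen`, `group` (`NA` when unassigned).
#' @export
assign_groups <- function(animals, config) {
  animals <- as_tibble(animals)
  stopifnot(all(c("animal", "weight") %in% names(animals)))
  ord <- order(animals$weight, decreasing = TRUE)
  out <- animals[ord, c("animal", "weight")]
  n <- nrow(out)
  per_group <- config$pen_size * config$pens_per_feeder
  n_groups <- n %/% per_group
  pen <- rep(NA_integer_, n)
  grp <- rep(NA_integer_, n)
  k <- n_groups * per_group
  if (k > 0) {
    pen[1:k] <- rep(seq_len(k %/% config$pen_size), each = config$pen_size)
    grp[1:k] <- rep(seq_len(n_groups), each = per_group)
  }
  out$pen <- pen
  out$group <- grp
  out
}

#' Daily individual feed-intake records for the test-station cohort
#'
#' One record per animal per day on test: population mean curve, start
#' year-month effect, regression on start weight, the animal's genetic and
#' permanent-environment random-regression curves, and a residual drawn
#' from the day's residual class.
#'
#' @param dataset A `sim_dataset` (or a list with `animals` and `truth`).
#' @param config A [sim_config()].
#' @return Tibble `animal`, `day`, `ym`, `weight`, `dot_class`, `y`.
#' @export
make_individual_records <- function(dataset, config) {
  cfg <- config
  an <- dplyr::filter(dataset$animals, .data$cohort == "individual")
  if (!nrow(an)) abort("No animals flagged for individual recording.")
  L <- cfg$ind_test_length_days
  days <- seq_len(L)
  phi <- leg_eval(cfg$basis_ind, days) # L x 3
  coefs <- dataset$truth$coefficients
  A <- as.matrix(coefs[match(an$animal, coefs$animal), c("ind0", "ind1", "ind2")])
  PE <- as.matrix(dataset$truth$pe_individual[
    match(an$animal, dataset$truth$pe_individual$animal), c("pe0", "pe1", "pe2")])
  ymv <- dataset$truth$ym_effects
  ym_eff <- ymv$effect[match(an$ym, ymv$ym)]
  cls <- dot_class(days)
  sde <- sqrt(cfg$sigma_e_ind[cls])
  n <- nrow(an)
  gen_part <- A %*% t(phi) # n x L
  pe_part <- PE %*% t(phi)
  e <- matrix(rnorm(n * L), n, L) * rep(sde, each = n)
  fixed <- outer(ym_eff + cfg$weight_slope * an$weight, rep(1, L)) +
    outer(rep(1, n), mean_curve(cfg, days))
  Y <- fixed + gen_part + pe_part + e
  tibble(
    animal = rep(an$animal, times = L),
    day = rep(days, each = n),
    ym = rep(an$ym, times = L),
    weight = rep(an$weight, times = L),
    dot_class = rep(cls, each = n),
    y = as.numeric(Y)) |>
    dplyr::arrange(.data$animal, .data$day)
}

#' Pooled group feed-intake records at the two recording time points
#'
#' For every feeding group and recording period, the phenotype is the total
#' latent feed intake of the animals present, summed over the animals and
#' the days of the period and divided by the period length `nd`, dated at
#' the period's mid-point day. Random-regression effects enter at the
#' mid-point day (the day at which the record is evaluated by the model);
#' daily residuals accumulate, so a record's residual variance is
#' `nt/nd * sigma_e_group`.
#'
#' @inheritParams make_individual_records
#' @return Tibble `group`, `time_point`, `day`, `ym`, `mean_start_weight`,
#'   `size_class`, `nt`, `nd`, `y`, and list-columns `members` (initial) and
#'   `present` (animals contributing to the record).
#' @export
make_group_records <- function(dataset, config) {
  cfg <- config
  assigned <- dataset$groups
  if (!nrow(assigned)) abort("No feeding groups assigned.")
  coefs <- dataset$truth$coefficients
  ymv <- dataset$truth$ym_effects
  an <- dataset$animals
  drops <- dataset$dropouts
  pre_gone <- drops$animal[drops$drop_day == 0]
  mid_gone <- drops$animal[drops$drop_day > 0]
  groups <- sort(unique(assigned$group))
  jit <- cfg$record_day_jitter
  rows <- list()
  for (g in groups) {
    members <- assigned$animal[assigned$group == g]
    ym <- an$ym[match(members[1], an$animal)]
    ym_e <- ymv$effect[match(ym, ymv$ym)]
    pe_g <- unlist(dataset$truth$pe_group[dataset$truth$pe_group$group == g,
                                          c("pe0", "pe1")])
    # recording days are only approximately the targets; each group gets
    # its own realised pair of recording days
    d1 <- cfg$group_record_days[1] + sample(seq(-jit, jit), 1)
    d2 <- min(cfg$group_record_days[2] + sample(seq(-jit, jit), 1),
              cfg$ind_test_length_days)
    periods <- list(c(start = 1, end = d1), c(start = d1 + 1, end = d2))
    present1 <- setdiff(members, pre_gone)
    w1 <- an$weight[match(present1, an$animal)]
    for (tp in 1:2) {
      present <- if (tp == 1) present1 else setdiff(present1, mid_gone)
      nt <- length(present)
      per <- periods[[tp]]
      pdays <- seq(per["start"], per["end"])
      nd <- length(pdays)
      mid <- floor((per["start"] + per["end"]) / 2)
      phi <- drop(leg_eval(cfg$basis_grp, mid))
      Ag <- as.matrix(coefs[match(present, coefs$animal), c("grp0", "grp1")])
      gen <- sum(Ag %*% phi)
      pe <- sum(phi * pe_g)
      wp <- an$weight[match(present, an$animal)]
      fixed <- nt * (mean(mean_curve(cfg, pdays)) + ym_e) +
        cfg$weight_slope * sum(wp)
      e <- sum(rnorm(nt * nd, 0, sqrt(cfg$sigma_e_group))) / nd
      rows[[length(rows) + 1L]] <- tibble(
        group = g, time_point = tp, day = unname(mid), ym = ym,
        mean_start_weight = mean(w1), size_class = length(present1),
        nt = nt, nd = nd, y = fixed + gen + pe + e,
        members = list(members), present = list(present))
    }
  }
  dplyr::bind_rows(rows)
}

#' Aggregate feeder-visit amounts into daily feed intake
#'
#' Station feeders log one row per visit; the daily phenotype is the sum of
#' the visit amounts within an animal-day.
#'
#' @param visits Data frame with columns `animal`, `day`, `amount`.
#' @return Tibble `animal`, `day`, `y` (kg/day).
#' @export
sum_daily_visits <- function(visits) {
  as_tibble(visits) |>
    dplyr::group_by(.data$animal, .data$day) |>
    dplyr::summarise(y = sum(.data$amount), .groups = "drop")
}
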