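# Dense-matrix oracles and small random problem generators used across the
# test files. The dense path is written independently of the package's MME
# machinery: V is assembled explicitly and GLS/BLUP computed by direct
# inversion.

# random positive-definite covariance with the given scale
rand_pd <- function(d, scale = 1, seed_mat = NULL) {
  M <- if (is.null(seed_mat)) matrix(rnorm(d * d), d) else seed_mat
  S <- crossprod(M) / d + diag(0.2, d)
  S * scale
}

# random bivariate variance components for toy problems
rand_vc <- function(spec) {
  nc <- spec$n_coef
  G <- rand_pd(nc, 0.3)
  P1 <- if (spec$has_grp) rand_pd(spec$np_grp + 1, 0.2)
  P2 <- if (spec$has_ind) rand_pd(spec$np_ind + 1, 0.2)
  variance_components(
    G, P1 = P1, P2 = P2,
    sigma_e_group = if (spec$has_grp) runif(1, 0.5, 2),
    sigma_e_ind = if (spec$has_ind) runif(8, 0.1, 0.4))
}

# small random pedigree: founders plus two descendant generations
rand_pedigree <- function(n_founders = 10, n_off1 = 14, n_off2 = 16) {
  animal <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  males <- which(seq_len(n_founders) %% 2 == 1)
  females <- which(seq_len(n_founders) %% 2 == 0)
  for (i in seq_len(n_off1)) {
    animal <- c(animal, length(animal) + 1L)
    sire <- c(sire, sample(males, 1))
    dam <- c(dam, sample(females, 1))
  }
  gen1 <- (n_founders + 1):(n_founders + n_off1)
  for (i in seq_len(n_off2)) {
    animal <- c(animal, length(animal) + 1L)
    sire <- c(sire, sample(gen1, 1))
    dam <- c(dam, sample(setdiff(gen1, sire[length(sire)]), 1))
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# random toy dataset (<= 200 records, <= 50 animals) exercising group and,
# optionally, individual records
rand_toy_dataset <- function(seed, bivariate = TRUE) {
  set.seed(seed)
  ped <- rand_pedigree()
  finals <- tail(ped$animal, 16)
  grp_members <- split(finals[1:12], rep(1:3, each = 4))
  days <- c(15, 45)
  grp_records <- dplyr::bind_rows(lapply(seq_along(grp_members), function(g) {
    m <- grp_members[[g]]
    pres2 <- if (g == 1) m[-1] else m # one group loses an animal
    tibble::tibble(
      group = g, time_point = 1:2, day = days + sample(-2:2, 2, TRUE),
      ym = sample(c("2016-01", "2016-02"), 1),
      mean_start_weight = rnorm(1, 27, 1), size_class = length(m),
      nt = c(length(m), length(pres2)), nd = c(28L, 31L),
      y = rnorm(2, 50, 4),
      members = list(m, m), present = list(m, pres2))
  }))
  ind_animals <- tail(finals, 4)
  ind_records <- tidyr::expand_grid(animal = ind_animals, day = seq(2, 58, by = 4))
  ind_records$ym <- "2016-03"
  ind_records$weight <- rep(rnorm(length(ind_animals), 30, 2),
                            each = length(seq(2, 58, by = 4)))
  ind_records$y <- rnorm(nrow(ind_records), 2.2, 0.5)
  if (!bivariate) ind_records <- NULL
  list(pedigree = ped, grp_records = grp_records, ind_records = ind_records)
}

# dense restricted log-likelihood and BLUP solutions: V assembled in full
dense_blup <- function(design, vc, A) {
  X <- as.matrix(design$X)
  Z <- as.matrix(design$Z)
  nc <- design$n_coef
  Gamma_g <- kronecker(A, vc$G) # animal-major ordering matches Z columns
  V <- Z %*% Gamma_g %*% t(Z)
  if (!is.null(design$Wpe)) {
    Wp <- as.matrix(design$Wpe)
    blocks <- c(
      if (length(design$pe1_ids)) replicate(length(design$pe1_ids), vc$P1,
                                            simplify = FALSE),
      if (length(design$pe2_ids)) replicate(length(design$pe2_ids), vc$P2,
                                            simplify = FALSE))
    Ppe <- as.matrix(Matrix::bdiag(blocks))
    V <- V + Wp %*% Ppe %*% t(Wp)
  }
  sig <- numeric(length(design$y))
  for (c in seq_along(design$rclass_labels)) {
    lab <- design$rclass_labels[c]
    rows <- design$rclass == c
    sig[rows] <- if (startsWith(lab, "grp")) {
      k <- sub("grp", "", lab)
      if (k == "") vc$sigma_e_group[1] else vc$sigma_e_group[as.integer(k)]
    } else {
      k <- sub("ind", "", lab)
      if (k == "") vc$sigma_e_ind[1] else vc$sigma_e_ind[as.integer(k)]
    }
  }
  R <- diag(design$rw * sig)
  V <- V + R
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  M <- XtVi %*% X
  b <- solve(M, XtVi %*% design$y)
  r <- design$y - X %*% b
  Py <- Vi %*% r
  u <- Gamma_g %*% t(Z) %*% Py
  logL <- -0.5 * (as.numeric(determinant(V)$modulus) +
                    as.numeric(determinant(M)$modulus) + sum(r * Py))
  list(b = as.numeric(b), u = as.numeric(u), logL = logL)
}
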