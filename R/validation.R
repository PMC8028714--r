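# Leave-one-group-out cross-validation of the group-trait evaluation and
# the partial/whole comparison statistics (correlations and regression
# slopes between full- and reduced-data predictions, and against corrected
# phenotypes).

#' Corrected group phenotypes from a full-data fit
#'
#' Corrects each group record for fixed effects and non-genetic random
#' effects: per record, the corrected phenotype is the sum of the present
#' members' (G)EBV at the record's day plus the record's fitted residual;
#' per group, records are summed.
#'
#' @param fit A `penfeed_mme` full-data solution.
#' @return Tibble `group`, `y_c`.
#' @export
corrected_group_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "penfeed_mme"))
  des <- fit$engine$design
  if (is.null(des$grp_records)) abort("Fit contains no group records.")
  g <- des$grp_records
  res <- fit$residuals
  gres <- res[res$trait == "group", ]
  if (any(!is.finite(gres$resid))) abort("Fitted residuals missing for group records.")
  phi <- leg_eval(des$basis_grp, g$day)[, seq_len(des$spec$nc_grp), drop = FALSE]
  gen <- fit$genetic
  yc_rec <- vapply(seq_len(nrow(g)), function(r) {
    idx <- match(g$present[[r]], gen$animal)
    A <- as.matrix(gen[idx, 1 + seq_len(des$spec$nc_grp), drop = FALSE])
    sum(A %*% phi[r, ]) + gres$resid[r]
  }, numeric(1))
  tibble(group = as.character(g$group), y_c = yc_rec) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(y_c = sum(.data$y_c), .groups = "drop")
}

# per-animal period (G)EBV: daily group-trait EBV summed over the animal's
# group's recorded days
period_ebv_by_group <- function(genetic, des) {
  g <- des$grp_records
  nc1 <- des$spec$nc_grp
  out_a <- list(); out_g <- list()
  for (gid in unique(g$group)) {
    rows <- which(g$group == gid)
    # animals that contributed to at least one of the group's records
    members <- unique(unlist(g$present[rows]))
    idx <- match(members, genetic$animal)
    A <- as.matrix(genetic[idx, 1 + seq_len(nc1), drop = FALSE])
    phi <- leg_eval(des$basis_grp, g$day[rows])[, seq_len(nc1), drop = FALSE]
    ebv <- as.numeric(A %*% colSums(phi)) # sum over the group's recorded days
    out_a[[length(out_a) + 1L]] <- tibble(group = as.character(gid),
                                          animal = members, ebv = ebv)
    # group (G)EBV: sum over records of present members' daily EBV
    gsum <- sum(vapply(seq_along(rows), function(k) {
      pres <- match(g$present[[rows[k]]], genetic$animal)
      Ap <- as.matrix(genetic[pres, 1 + seq_len(nc1), drop = FALSE])
      sum(Ap %*% phi[k, ])
    }, numeric(1)))
    out_g[[length(out_g) + 1L]] <- tibble(group = as.character(gid), ebv = gsum)
  }
  list(animal = dplyr::bind_rows(out_a), group = dplyr::bind_rows(out_g))
}

#' Partial/whole comparison statistics
#'
#' @param full,reduced Aligned numeric vectors of full- and reduced-data
#'   predictions (by animal or by group).
#' @param y_c Optional corrected phenotypes aligned with `reduced` (by
#'   group) for the accuracy statistics.
#' @return One-row tibble with `rho_fr` (Pearson correlation of full on
#'   reduced), `b_fr` (OLS slope of full on reduced) and, when `y_c` is
#'   given, `rho_yc_r` and `b_yc_r`.
#' @export
lr_statistics <- function(full, reduced, y_c = NULL) {
  stopifnot(length(full) == length(reduced))
  if (stats::sd(reduced) == 0 || stats::sd(full) == 0) {
    warn("Zero-variance prediction vector; correlation undefined.")
    return(tibble(rho_fr = NA_real_, b_fr = NA_real_,
                  rho_yc_r = NA_real_, b_yc_r = NA_real_))
  }
  rho <- stats::cor(full, reduced)
  b <- stats::cov(full, reduced) / stats::var(reduced)
  out <- tibble(rho_fr = rho, b_fr = b)
  if (!is.null(y_c)) {
    out$rho_yc_r <- stats::cor(y_c, reduced)
    out$b_yc_r <- stats::cov(y_c, reduced) / stats::var(reduced)
  }
  out
}

#' Leave-one-group-out cross-validation
#'
#' Removes each feeding group's phenotype records in turn (pedigree and
#' genotypes unchanged), re-solves the mixed-model equations on the reduced
#' data with the *pre-estimated* full-data variance components, and
#' assembles the partial/whole statistics: `rho_fr`/`b_fr` between full-
#' and reduced-data period (G)EBV per animal (overall and for the
#' genotyped / non-genotyped strata), `rho_yc_r`/`b_yc_r` between corrected
#' phenotypes and reduced-data group (G)EBV, and the per-group absolute
#' full-vs-reduced difference `d_fr`.
#'
#' Each fold is solved exactly by a rank-two downdate (Woodbury identity)
#' of the full-data factorisation, so a fold costs two triangular solves.
#'
#' @param dataset Dataset as for [build_design()].
#' @param vc Pre-estimated [variance_components()] (not re-estimated per
#'   fold).
#' @param spec A [model_spec()] (`"bivariate"` or `"univariate_group"`).
#' @param Kinv Relationship inverse ([ainverse()] for PBLUP, [hinverse()]
#'   for ssGBLUP).
#' @param basis_grp,basis_ind Optional bases passed to [build_design()].
#' @param genotyped Character/integer vector of genotyped animal ids (for
#'   the strata); defaults to `rownames(dataset$genotypes)`.
#' @param audit If `TRUE`, nothing is removed: every "reduced" solution is
#'   the full solution (identity check; `rho_fr = b_fr = 1`).
#' @return A `penfeed_cv` object: `animal` (per-animal full/reduced period
#'   EBV with stratum), `group` (per-group full/reduced EBV, `y_c`,
#'   `d_fr`), `stats` (tibble of statistics by stratum plus the
#'   group-level accuracy statistics), `n_folds`.
#' @export
run_logo_cv <- function(dataset, vc, spec, Kinv,
                        basis_grp = NULL, basis_ind = NULL,
                        genotyped = NULL, audit = FALSE) {
  if (!spec$has_grp) abort("Leave-one-group-out validation needs the group trait.")
  des <- build_design(dataset, spec, basis_grp = basis_grp, basis_ind = basis_ind)
  engine <- mme_prepare(des, Kinv)
  engine$super <- NA # no selected inverse needed: let CHOLMOD pick supernodal
  ms <- solve_mme(engine, vc)
  full_fit <- wrap_mme_solution(engine, ms, vc)
  genotyped <- as.character(genotyped %||% rownames(dataset$genotypes) %||% character(0))

  g <- des$grp_records
  groups <- unique(g$group)
  full_ebv <- period_ebv_by_group(full_fit$genetic, des)
  yc <- corrected_group_phenotypes(full_fit)

  p <- engine$p_fixed
  nc1 <- des$spec$nc_grp
  red_a <- list(); red_g <- list()
  grp_rows <- which(des$info$trait == "group")
  for (gid in groups) {
    members <- unique(unlist(g$members[g$group == gid]))
    if (audit) {
      gen_red <- full_fit$genetic
    } else {
      rows <- grp_rows[g$group == gid]
      Wt_S <- Matrix::t(engine$W[rows, , drop = FALSE])
      cS <- ms$rinv[rows]
      U <- Wt_S %*% Matrix::Diagonal(x = sqrt(cS))
      v <- sqrt(cS) * des$y[rows]
      T <- as.matrix(Matrix::solve(ms$F, U))
      B <- as.matrix(Matrix::crossprod(U, T))
      s0 <- ms$sol - as.numeric(T %*% v)
      IB <- diag(nrow(B)) - B
      rhs2 <- as.numeric(Matrix::crossprod(U, s0))
      corr <- tryCatch(solve(IB, rhs2), error = function(e) {
        warn(sprintf("Fold %s leaves the equations singular (empty fixed-effect cell); using a pseudo-inverse.", gid))
        qr.coef(qr(IB, tol = 1e-10), rhs2)
      })
      corr[!is.finite(corr)] <- 0
      sol_red <- s0 + as.numeric(T %*% corr)
      Ur <- matrix(sol_red[p + seq_len(engine$n_anim * engine$nc)],
                   ncol = engine$nc, byrow = TRUE)
      gen_red <- dplyr::bind_cols(tibble(animal = des$ids),
                                  as_tibble(Ur, .name_repair = ~ colnames(full_fit$genetic)[-1]))
    }
    eb <- period_ebv_by_group(gen_red, des)
    red_a[[length(red_a) + 1L]] <- dplyr::filter(eb$animal, .data$group == as.character(gid))
    red_g[[length(red_g) + 1L]] <- dplyr::filter(eb$group, .data$group == as.character(gid))
  }
  red_a <- dplyr::bind_rows(red_a)
  red_g <- dplyr::bind_rows(red_g)

  animal <- full_ebv$animal |>
    dplyr::rename(ebv_full = "ebv") |>
    dplyr::left_join(dplyr::rename(red_a, ebv_reduced = "ebv"),
                     by = c("group", "animal")) |>
    dplyr::mutate(stratum = ifelse(as.character(.data$animal) %in% genotyped,
                                   "genotyped", "non_genotyped"))
  group <- full_ebv$group |>
    dplyr::rename(ebv_full = "ebv") |>
    dplyr::left_join(dplyr::rename(red_g, ebv_reduced = "ebv"), by = "group") |>
    dplyr::left_join(yc, by = "group") |>
    dplyr::mutate(d_fr = abs(.data$ebv_full - .data$ebv_reduced))

  stats <- dplyr::bind_rows(
    dplyr::mutate(lr_statistics(animal$ebv_full, animal$ebv_reduced), stratum = "all"),
    if (any(animal$stratum == "genotyped"))
      dplyr::mutate(with(dplyr::filter(animal, .data$stratum == "genotyped"),
                         lr_statistics(ebv_full, ebv_reduced)), stratum = "genotyped"),
    if (any(animal$stratum == "non_genotyped"))
      dplyr::mutate(with(dplyr::filter(animal, .data$stratum == "non_genotyped"),
                         lr_statistics(ebv_full, ebv_reduced)), stratum = "non_genotyped"),
    dplyr::mutate(lr_statistics(group$ebv_full, group$ebv_reduced, y_c = group$y_c),
                  stratum = "group"))

  structure(list(animal = animal, group = group, stats = stats,
                 n_folds = if (audit) 0L else length(groups),
                 spec = spec, relationship = spec$relationship,
                 audit = audit),
            class = "penfeed_cv")
}

#' @export
print.penfeed_cv <- function(x, ...) {
  cat(sprintf("<penfeed_cv> %s; %d folds%s; %d animals, %d groups\n",
              x$spec$traits, x$n_folds, if (x$audit) " (audit mode)" else "",
              nrow(x$animal), nrow(x$group)))
  print(x$stats)
  invisible(x)
}
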