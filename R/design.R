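# Assembly of the stacked design: response, fixed-effect incidence, genetic
# and permanent-environment random-regression incidence, residual weights
# and classes. Group-record rows sum each present member's genetic
# covariates; their residual weight is nt/nd.

#' Build the design matrices of the random-regression model
#'
#' @param dataset List (e.g. a `sim_dataset`) with `pedigree` and, as the
#'   trait selection requires, `grp_records` (columns `group`,
#'   `time_point`, `day`, `ym`, `mean_start_weight`, `size_class`, `nt`,
#'   `nd`, `y`, list-column `present`) and `ind_records` (columns `animal`,
#'   `day`, `ym`, `weight`, `y`).
#' @param spec A [model_spec()].
#' @param basis_grp,basis_ind Optional [legendre_basis()] per trait; by
#'   default the group basis spans the observed recording days and the
#'   individual basis spans day 1 to the last observed day.
#' @return A `penfeed_design` list; see the fields set below. Fixed-effect
#'   columns made redundant by the nesting structure (e.g. class intercepts
#'   aliased with nested regression cells) are detected by pivoted Cholesky
#'   and dropped, recorded in `dropped_fixed`.
#' @export
build_design <- function(dataset, spec, basis_grp = NULL, basis_ind = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ped <- ped_normalise(dataset$pedigree)
  ids <- ped$animal
  n_anim <- length(ids)

  grp <- if (spec$has_grp) as_tibble(dataset$grp_records) else NULL
  ind <- if (spec$has_ind) as_tibble(dataset$ind_records) else NULL
  if (spec$has_grp && (is.null(grp) || !nrow(grp))) {
    abort("Model includes the group trait but no group records were supplied.")
  }
  if (spec$has_ind && (is.null(ind) || !nrow(ind))) {
    abort("Model includes the individual trait but no individual records were supplied.")
  }
  if (spec$has_grp) {
    all_members <- unique(unlist(grp$present))
    if (!all(all_members %in% ids)) {
      abort(paste0("Group member(s) absent from the pedigree: ",
                   paste(utils::head(setdiff(all_members, ids), 5), collapse = ", ")))
    }
  }
  if (spec$has_ind && !all(ind$animal %in% ids)) {
    abort(paste0("Recorded animal(s) absent from the pedigree: ",
                 paste(utils::head(setdiff(ind$animal, ids), 5), collapse = ", ")))
  }

  if (spec$has_grp) {
    rng <- range(grp$day)
    if (diff(rng) == 0) rng <- rng + c(-1, 1) # degenerate single-day span
    basis_grp <- basis_grp %||% legendre_basis(max(spec$nf_grp, spec$nr_grp, spec$np_grp),
                                               rng[1], rng[2])
  }
  if (spec$has_ind) {
    basis_ind <- basis_ind %||% legendre_basis(max(spec$nf_ind, spec$nr_ind, spec$np_ind),
                                               1, max(ind$day))
  }

  n_g <- if (spec$has_grp) nrow(grp) else 0L
  n_i <- if (spec$has_ind) nrow(ind) else 0L
  n <- n_g + n_i
  y <- c(if (n_g) grp$y, if (n_i) ind$y)

  ## ---- fixed effects (dense column blocks, assembled then rank-reduced) ---
  fx_cols <- list()
  add_fx <- function(name, col_g, col_i) {
    # col_g / col_i: numeric vectors (or NULL) for the two row blocks
    v <- c(col_g %||% rep(0, n_g), col_i %||% rep(0, n_i))
    fx_cols[[name]] <<- v
  }
  if (spec$has_grp) {
    phi_gf <- leg_eval(basis_grp, grp$day)
    for (l in sort(unique(grp$ym))) {
      add_fx(paste0("g_ym", l), as.numeric(grp$ym == l), NULL)
    }
    for (m in sort(unique(grp$time_point))) {
      inm <- grp$time_point == m
      add_fx(paste0("g_beta0_m", m), as.numeric(inm), NULL)
      add_fx(paste0("g_beta1_m", m), ifelse(inm, grp$mean_start_weight, 0), NULL)
    }
    cells <- interaction(grp$size_class, grp$time_point, drop = TRUE)
    for (cl in levels(cells)) {
      incl <- cells == cl
      for (k in 0:spec$nf_grp) {
        add_fx(paste0("g_b", k, "_cell", cl), ifelse(incl, phi_gf[, k + 1], 0), NULL)
      }
    }
  }
  if (spec$has_ind) {
    phi_if <- leg_eval(basis_ind, ind$day)
    icls <- dot_class(ind$day)
    for (l in sort(unique(ind$ym))) {
      add_fx(paste0("i_ym", l), NULL, as.numeric(ind$ym == l))
    }
    for (m in sort(unique(icls))) {
      inm <- icls == m
      add_fx(paste0("i_beta0_m", m), NULL, as.numeric(inm))
      add_fx(paste0("i_beta1_m", m), NULL, ifelse(inm, ind$weight, 0))
    }
    for (k in 0:spec$nf_ind) {
      add_fx(paste0("i_b", k), NULL, phi_if[, k + 1])
    }
  }
  Xfull <- do.call(cbind, fx_cols)
  keep <- fixed_rank_keep(Xfull)
  dropped_fixed <- colnames(Xfull)[setdiff(seq_len(ncol(Xfull)), keep)]
  X <- methods::as(Matrix::Matrix(Xfull[, keep, drop = FALSE], sparse = TRUE),
                   "CsparseMatrix")

  ## ---- genetic incidence (animal-major, coefficient inner) ---------------
  nc <- spec$n_coef
  zi <- integer(0); zj <- integer(0); zx <- numeric(0)
  if (spec$has_grp) {
    phi_gr <- leg_eval(basis_grp, grp$day)[, seq_len(spec$nc_grp), drop = FALSE]
    nts <- lengths(grp$present)
    rows <- rep(seq_len(n_g), nts)
    apos <- match(unlist(grp$present), ids)
    zi <- c(zi, rep(rows, each = spec$nc_grp))
    zj <- c(zj, as.integer(outer(seq_len(spec$nc_grp), (apos - 1L) * nc, `+`)))
    zx <- c(zx, as.numeric(t(phi_gr[rows, , drop = FALSE])))
  }
  if (spec$has_ind) {
    phi_ir <- leg_eval(basis_ind, ind$day)[, seq_len(spec$nc_ind), drop = FALSE]
    apos <- match(ind$animal, ids)
    off <- spec$nc_grp
    zi <- c(zi, n_g + rep(seq_len(n_i), each = spec$nc_ind))
    zj <- c(zj, as.integer(outer(off + seq_len(spec$nc_ind), (apos - 1L) * nc, `+`)))
    zx <- c(zx, as.numeric(t(phi_ir)))
  }
  Z <- Matrix::sparseMatrix(i = zi, j = zj, x = zx, dims = c(n, n_anim * nc))

  ## ---- permanent-environment incidence -----------------------------------
  pe1_ids <- character(0); pe2_ids <- character(0)
  np1 <- if (spec$has_grp) spec$np_grp + 1L else 0L
  np2 <- if (spec$has_ind) spec$np_ind + 1L else 0L
  Wpe <- NULL
  if (spec$include_pe) {
    wi <- integer(0); wj <- integer(0); wx <- numeric(0)
    off <- 0L
    if (spec$has_grp) {
      phi_gp <- leg_eval(basis_grp, grp$day)[, seq_len(np1), drop = FALSE]
      if (spec$pe_group_level == "group") {
        pe1_ids <- as.character(sort(unique(grp$group)))
        gpos <- match(as.character(grp$group), pe1_ids)
        wi <- c(wi, rep(seq_len(n_g), each = np1))
        wj <- c(wj, as.integer(outer(seq_len(np1), (gpos - 1L) * np1, `+`)))
        wx <- c(wx, as.numeric(t(phi_gp)))
      } else {
        pe1_ids <- as.character(sort(unique(unlist(grp$present))))
        nts <- lengths(grp$present)
        rows <- rep(seq_len(n_g), nts)
        apos <- match(as.character(unlist(grp$present)), pe1_ids)
        wi <- c(wi, rep(rows, each = np1))
        wj <- c(wj, as.integer(outer(seq_len(np1), (apos - 1L) * np1, `+`)))
        wx <- c(wx, as.numeric(t(phi_gp[rows, , drop = FALSE])))
      }
      off <- length(pe1_ids) * np1
    }
    if (spec$has_ind) {
      phi_ip <- leg_eval(basis_ind, ind$day)[, seq_len(np2), drop = FALSE]
      pe2_ids <- as.character(sort(unique(ind$animal)))
      apos <- match(as.character(ind$animal), pe2_ids)
      wi <- c(wi, n_g + rep(seq_len(n_i), each = np2))
      wj <- c(wj, off + as.integer(outer(seq_len(np2), (apos - 1L) * np2, `+`)))
      wx <- c(wx, as.numeric(t(phi_ip)))
    }
    Wpe <- Matrix::sparseMatrix(i = wi, j = wj, x = wx,
                                dims = c(n, off + length(pe2_ids) * np2))
  }

  ## ---- residual weights and classes --------------------------------------
  rw <- c(if (n_g) grp$nt / grp$nd, rep(1, n_i))
  stopifnot(all(rw > 0))
  rlab <- character(0)
  rclass <- integer(0)
  if (spec$has_grp) {
    if (spec$resid_group == "homogeneous") {
      rlab <- "grp"
      rclass <- rep(1L, n_g)
    } else {
      rlab <- paste0("grp", sort(unique(grp$time_point)))
      rclass <- match(paste0("grp", grp$time_point), rlab)
    }
  }
  if (spec$has_ind) {
    if (spec$resid_ind == "homogeneous") {
      rlab <- c(rlab, "ind")
      rclass <- c(rclass, rep(length(rlab), n_i))
    } else {
      present <- sort(unique(dot_class(ind$day)))
      newlab <- paste0("ind", present)
      rclass <- c(rclass, length(rlab) + match(dot_class(ind$day), present))
      rlab <- c(rlab, newlab)
    }
  }

  info <- dplyr::bind_rows(
    if (spec$has_grp) tibble(trait = "group", day = as.numeric(grp$day),
                             group = as.character(grp$group),
                             animal = NA_integer_,
                             nt = grp$nt, nd = grp$nd),
    if (spec$has_ind) tibble(trait = "individual", day = as.numeric(ind$day),
                             group = NA_character_, animal = ind$animal,
                             nt = 1, nd = 1))

  structure(list(
    y = y, X = X, Z = Z, Wpe = Wpe,
    rw = rw, rclass = rclass, rclass_labels = rlab,
    info = info, spec = spec,
    basis_grp = basis_grp, basis_ind = basis_ind,
    ids = ids, n_coef = nc, nc_grp = spec$nc_grp, nc_ind = spec$nc_ind,
    pe1_ids = pe1_ids, pe2_ids = pe2_ids, np1 = np1, np2 = np2,
    fixed_names = colnames(Xfull)[keep], dropped_fixed = dropped_fixed,
    grp_records = grp, ind_records = ind),
    class = "penfeed_design")
}

# pivoted-Cholesky rank detection on the fixed-effect Gram matrix
fixed_rank_keep <- function(Xfull, tol = 1e-9) {
  G <- crossprod(Xfull)
  sc <- sqrt(pmax(diag(G), .Machine$double.eps))
  Gs <- G / tcrossprod(sc)
  ch <- suppressWarnings(chol(Gs, pivot = TRUE, tol = tol))
  r <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  # refine: pivoted chol can overshoot rank on near-singular blocks
  dvals <- diag(ch)[seq_len(r)]
  r <- sum(dvals > sqrt(tol))
  sort(piv[seq_len(r)])
}

#' @export
print.penfeed_design <- function(x, ...) {
  cat(sprintf("<penfeed_design> %d records (%d group, %d individual); %d animals x %d coefficients; %d fixed columns (%d dropped as aliased); residual classes: %s\n",
              length(x$y), sum(x$info$trait == "group"),
              sum(x$info$trait == "individual"),
              length(x$ids), x$n_coef, ncol(x$X), length(x$dropped_fixed),
              paste(x$rclass_labels, collapse = ", ")))
  invisible(x)
}
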