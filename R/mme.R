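# Henderson's mixed-model equations for the random-regression models:
# sparse assembly, factorisation, solutions, and the restricted
# log-likelihood evaluated through the MME factorisation.

# Precompute per-residual-class crossproducts so that repeated evaluations
# (REML iterations) only reweight and refactorise.
mme_prepare <- function(design, Kinv) {
  stopifnot(inherits(design, "penfeed_design"))
  n_anim <- length(design$ids)
  nc <- design$n_coef
  if (nrow(Kinv) != n_anim) {
    abort(sprintf("Relationship inverse has dimension %d but the pedigree has %d animals.",
                  nrow(Kinv), n_anim))
  }
  K_logdet <- attr(Kinv, "logdet")
  if (is.null(K_logdet)) {
    K_logdet <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  }
  W <- if (is.null(design$Wpe)) cbind(design$X, design$Z) else
    cbind(design$X, design$Z, design$Wpe)
  W <- methods::as(W, "CsparseMatrix")
  ncls <- length(design$rclass_labels)
  M <- vector("list", ncls); u <- vector("list", ncls)
  s <- numeric(ncls); ncount <- integer(ncls); sumlogw <- numeric(ncls)
  cls_rows <- vector("list", ncls)
  for (c in seq_len(ncls)) {
    idx <- which(design$rclass == c)
    cls_rows[[c]] <- idx
    Wc <- W[idx, , drop = FALSE]
    wc <- design$rw[idx]
    Dc <- Matrix::Diagonal(x = 1 / wc)
    M[[c]] <- Matrix::forceSymmetric(Matrix::crossprod(Wc, Dc %*% Wc))
    u[[c]] <- as.numeric(Matrix::crossprod(Wc, design$y[idx] / wc))
    s[c] <- sum(design$y[idx]^2 / wc)
    ncount[c] <- length(idx)
    sumlogw[c] <- sum(log(wc))
  }
  # data scale per residual class (variance of weight-standardised records):
  # lower bounds for the class variances during REML keep the equations
  # well-conditioned enough for an accurate restricted likelihood
  sigma_scale <- vapply(seq_len(ncls), function(c) {
    idx <- cls_rows[[c]]
    v <- stats::var(design$y[idx] / sqrt(design$rw[idx]))
    if (!is.finite(v) || v <= 0) v <- max(s[c] / max(ncount[c], 1), 1e-8)
    v
  }, numeric(1))
  list(design = design, W = W, Kinv = Kinv, K_logdet = K_logdet,
       M = M, u = u, s = s, ncount = ncount, sumlogw = sumlogw,
       cls_rows = cls_rows, sigma_scale = sigma_scale,
       p_fixed = ncol(design$X), n_anim = n_anim, nc = nc,
       gofs = ncol(design$X),
       pe1_n = length(design$pe1_ids), np1 = design$np1,
       pe2_n = length(design$pe2_ids), np2 = design$np2,
       pe1_ofs = ncol(design$X) + n_anim * nc,
       pe2_ofs = ncol(design$X) + n_anim * nc +
         length(design$pe1_ids) * design$np1)
}

# residual variance per class from the variance components
sigma_by_class <- function(engine, vc) {
  labs <- engine$design$rclass_labels
  out <- numeric(length(labs))
  for (c in seq_along(labs)) {
    lab <- labs[c]
    if (startsWith(lab, "grp")) {
      sg <- vc$sigma_e_group
      if (is.null(sg)) abort("`sigma_e_group` missing from the variance components.")
      k <- sub("grp", "", lab)
      out[c] <- if (k == "") sg[1] else sg[min(as.integer(k), length(sg))]
    } else {
      si <- vc$sigma_e_ind
      if (is.null(si)) abort("`sigma_e_ind` missing from the variance components.")
      k <- sub("ind", "", lab)
      out[c] <- if (k == "") si[1] else si[as.integer(k)]
    }
  }
  if (any(!is.finite(out)) || any(out <= 0)) {
    abort("Residual class variances must be positive and available for all classes with records.")
  }
  out
}

# force structural nonzeros so the assembled pattern is invariant to exact
# zeros in a prior inverse (keeps selected-inverse extraction complete)
force_pattern <- function(Minv) {
  Minv[Minv == 0] <- 1e-300
  Minv
}

prior_blocks <- function(engine, vc) {
  des <- engine$design
  G <- psd_check_pd(vc$G, "G")
  Ginv <- force_pattern(chol2inv(chol(G)))
  blocks <- list(Matrix::Matrix(0, engine$p_fixed, engine$p_fixed, sparse = TRUE),
                 Matrix::kronecker(engine$Kinv, Ginv))
  loggamma <- engine$nc * engine$K_logdet +
    engine$n_anim * as.numeric(determinant(G, logarithm = TRUE)$modulus)
  if (engine$pe1_n > 0) {
    P1 <- psd_check_pd(vc$P1, "P1")
    blocks <- c(blocks, list(Matrix::kronecker(Matrix::Diagonal(engine$pe1_n),
                                               force_pattern(chol2inv(chol(P1))))))
    loggamma <- loggamma + engine$pe1_n *
      as.numeric(determinant(P1, logarithm = TRUE)$modulus)
  }
  if (engine$pe2_n > 0) {
    P2 <- psd_check_pd(vc$P2, "P2")
    blocks <- c(blocks, list(Matrix::kronecker(Matrix::Diagonal(engine$pe2_n),
                                               force_pattern(chol2inv(chol(P2))))))
    loggamma <- loggamma + engine$pe2_n *
      as.numeric(determinant(P2, logarithm = TRUE)$modulus)
  }
  list(prior = Matrix::forceSymmetric(Matrix::bdiag(blocks)), loggamma = loggamma)
}

psd_check_pd <- function(M, name) {
  if (is.null(M)) abort(sprintf("`%s` is required by this model but missing.", name))
  M <- as.matrix(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    abort(sprintf("Covariance block `%s` is not positive definite; floor it (psd_floor) or adjust.", name))
  }
  M
}

# Build an index template so that repeated assemblies (REML iterations)
# only fill a value vector: the union pattern is fixed, each component
# matrix knows where its entries land.
mme_template <- function(engine) {
  sig0 <- rep(1, length(engine$M))
  vc0 <- template_vc(engine)
  LHS0 <- Reduce(`+`, purrr::map2(engine$M, sig0, ~ .x / .y))
  pri0 <- prior_blocks(engine, vc0)
  U <- methods::as(Matrix::forceSymmetric(LHS0 + pri0$prior), "CsparseMatrix")
  U0 <- U; U0@x[] <- 0
  locate <- function(B) {
    B <- methods::as(Matrix::forceSymmetric(B), "CsparseMatrix")
    Bm <- B; Bm@x <- as.numeric(seq_along(Bm@x))
    S <- U0 + Bm
    pos <- which(S@x != 0)
    idx <- integer(length(Bm@x))
    idx[as.integer(S@x[pos])] <- pos
    idx
  }
  idx_M <- lapply(engine$M, locate)
  # genetic prior kron template: triplets per Kg entry x block, upper
  # triangle of the assembled matrix only (dsC storage)
  nc <- engine$nc
  Kg <- methods::as(methods::as(engine$Kinv, "generalMatrix"), "CsparseMatrix")
  nE <- length(Kg@x)
  ki <- Kg@i + 1L
  kj <- rep.int(seq_len(nrow(Kg)), diff(Kg@p))
  bi <- rep(seq_len(nc), nc)          # row offset within block (fast)
  bj <- rep(seq_len(nc), each = nc)   # col offset within block
  ti <- engine$gofs + rep((ki - 1L) * nc, each = nc * nc) + rep(bi, nE)
  tj <- engine$gofs + rep((kj - 1L) * nc, each = nc * nc) + rep(bj, nE)
  keep_kron <- ti <= tj
  Kr <- Matrix::sparseMatrix(i = ti[keep_kron], j = tj[keep_kron],
                             x = as.numeric(seq_len(sum(keep_kron))), dims = dim(U))
  Sk <- U0 + Matrix::forceSymmetric(Kr, "U")
  posk <- which(Sk@x != 0)
  idx_kron <- integer(sum(keep_kron))
  idx_kron[as.integer(Sk@x[posk])] <- posk
  # pe prior templates (diagonal blocks, upper triangles)
  pe_idx <- function(off, nb, bs) {
    if (nb == 0) return(NULL)
    i <- off + rep((seq_len(nb) - 1L) * bs, each = bs * bs) + rep(rep(seq_len(bs), bs), nb)
    j <- off + rep((seq_len(nb) - 1L) * bs, each = bs * bs) + rep(rep(seq_len(bs), each = bs), nb)
    keep <- i <= j
    P <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                              x = as.numeric(seq_len(sum(keep))), dims = dim(U))
    S <- U0 + Matrix::forceSymmetric(P, "U")
    pos <- which(S@x != 0)
    idx <- integer(sum(keep))
    idx[as.integer(S@x[pos])] <- pos
    list(idx = idx, keep = keep)
  }
  list(U = U0, idx_M = idx_M, Mx = lapply(engine$M, function(B)
         methods::as(Matrix::forceSymmetric(B), "CsparseMatrix")@x),
       idx_kron = idx_kron, keep_kron = keep_kron, Kgx = Kg@x, nE = nE,
       p1 = pe_idx(engine$pe1_ofs, engine$pe1_n, engine$np1),
       p2 = pe_idx(engine$pe2_ofs, engine$pe2_n, engine$np2))
}

# neutral variance components whose inverses have a full (dense-block)
# pattern, used only to fix the assembled sparsity template
template_vc <- function(engine) {
  dense_cov <- function(d) diag(d) + matrix(1e-4, d, d)
  structure(list(G = dense_cov(engine$nc),
                 P1 = if (engine$pe1_n > 0) dense_cov(engine$np1),
                 P2 = if (engine$pe2_n > 0) dense_cov(engine$np2),
                 sigma_e_group = 1,
                 sigma_e_ind = rep(1, 8)),
            class = "variance_components")
}

# Solve the MME at the given variance components; returns solutions,
# residuals, restricted log-likelihood pieces and the factorisation.
solve_mme <- function(engine, vc) {
  sig <- sigma_by_class(engine, vc)
  if (!is.null(engine$tpl)) {
    tpl <- engine$tpl
    xval <- numeric(length(tpl$U@x))
    for (c in seq_along(tpl$idx_M)) {
      xval[tpl$idx_M[[c]]] <- xval[tpl$idx_M[[c]]] + tpl$Mx[[c]] / sig[c]
    }
    G <- psd_check_pd(vc$G, "G")
    Ginv <- chol2inv(chol(G))
    loggamma <- engine$nc * engine$K_logdet +
      engine$n_anim * as.numeric(determinant(G, logarithm = TRUE)$modulus)
    kx <- (rep(tpl$Kgx, each = engine$nc^2) *
             rep(as.numeric(Ginv), tpl$nE))[tpl$keep_kron]
    xval[tpl$idx_kron] <- xval[tpl$idx_kron] + kx
    if (engine$pe1_n > 0) {
      P1 <- psd_check_pd(vc$P1, "P1")
      xval[tpl$p1$idx] <- xval[tpl$p1$idx] +
        rep(as.numeric(chol2inv(chol(P1))), engine$pe1_n)[tpl$p1$keep]
      loggamma <- loggamma + engine$pe1_n *
        as.numeric(determinant(P1, logarithm = TRUE)$modulus)
    }
    if (engine$pe2_n > 0) {
      P2 <- psd_check_pd(vc$P2, "P2")
      xval[tpl$p2$idx] <- xval[tpl$p2$idx] +
        rep(as.numeric(chol2inv(chol(P2))), engine$pe2_n)[tpl$p2$keep]
      loggamma <- loggamma + engine$pe2_n *
        as.numeric(determinant(P2, logarithm = TRUE)$modulus)
    }
    LHS <- tpl$U
    LHS@x <- xval
    LHS <- Matrix::forceSymmetric(LHS)
    pri <- list(loggamma = loggamma)
  } else {
    LHS <- Reduce(`+`, purrr::map2(engine$M, sig, ~ .x / .y))
    pri <- prior_blocks(engine, vc)
    LHS <- Matrix::forceSymmetric(LHS + pri$prior)
  }
  rhs <- Reduce(`+`, purrr::map2(engine$u, sig, ~ .x / .y))
  F <- tryCatch({
    if (!is.null(engine$sym_factor)) {
      f <- get("factor", envir = engine$sym_factor)
      if (is.null(f)) {
        f <- Matrix::Cholesky(LHS, LDL = FALSE, super = FALSE, perm = TRUE)
      } else {
        f <- Matrix::update(f, LHS)
      }
      assign("factor", f, envir = engine$sym_factor)
      f
    } else {
      # supernodal factorisation (CHOLMOD's choice) is faster for systems
      # with dense genomic blocks; the REML path needs the simplicial
      # factor for the selected inverse and sets engine$super = FALSE
      Matrix::Cholesky(LHS, LDL = FALSE, super = engine$super %||% FALSE,
                       perm = TRUE)
    }
  }, error = function(e) abort(paste0(
    "Mixed-model equations are singular (rank-deficient fixed effects or zero variance): ",
    conditionMessage(e))))
  sol <- as.numeric(Matrix::solve(F, rhs))
  # one step of iterative refinement: the restricted likelihood needs
  # residuals accurate on the absolute scale even when variance ratios are
  # extreme
  rres <- rhs - as.numeric(LHS %*% sol)
  sol <- sol + as.numeric(Matrix::solve(F, rres))
  Lf <- methods::as(F, "sparseMatrix")
  logdetC <- 2 * sum(log(Matrix::diag(Lf)))
  logR <- sum(engine$ncount * log(sig) + engine$sumlogw)
  rvec <- numeric(length(engine$design$y))
  for (c in seq_along(sig)) rvec[engine$cls_rows[[c]]] <- sig[c]
  rinv <- 1 / (engine$design$rw * rvec)
  fitted <- as.numeric(engine$W %*% sol)
  resid <- engine$design$y - fitted
  # y'Py via the residuals (numerically stable when a variance is small:
  # the quadratic form must not be formed as a difference of large terms)
  yPy <- sum(engine$design$y * resid * rinv)
  logL <- -0.5 * (logR + pri$loggamma + logdetC + yPy)
  list(sol = sol, F = F, L = Lf, logL = logL, yPy = yPy,
       logdetC = logdetC, sigma = sig, rinv = rinv,
       fitted = fitted, resid = resid, Py = rinv * resid, rhs = rhs)
}

#' Solve Henderson's mixed-model equations
#'
#' Assembles and solves the MME for the design at fixed variance
#' components, with genetic prior `(G x K)^{-1} = G^{-1} x K^{-1}`,
#' permanent-environment priors from the `P` blocks, and a diagonal
#' residual matrix built from the class variances and the `nt/nd` weights
#' of group records.
#'
#' @param design A [build_design()] result.
#' @param vc A [variance_components()].
#' @param Kinv Sparse relationship inverse from [ainverse()] or
#'   [hinverse()], in the design's pedigree order.
#' @return A `penfeed_mme` object: tibbles `fixed`, `genetic`, `pe_group`,
#'   `pe_individual`, `residuals`, plus `logLik` and internal handles for
#'   downstream reuse.
#' @export
assemble_and_solve <- function(design, vc, Kinv) {
  engine <- mme_prepare(design, Kinv)
  ms <- solve_mme(engine, vc)
  wrap_mme_solution(engine, ms, vc)
}

wrap_mme_solution <- function(engine, ms, vc) {
  des <- engine$design
  p <- engine$p_fixed
  nc <- engine$nc
  coef_names <- c(if (des$spec$has_grp) paste0("grp", 0:(des$spec$nc_grp - 1)),
                  if (des$spec$has_ind) paste0("ind", 0:(des$spec$nc_ind - 1)))
  U <- matrix(ms$sol[p + seq_len(engine$n_anim * nc)], ncol = nc, byrow = TRUE)
  colnames(U) <- coef_names
  genetic <- dplyr::bind_cols(tibble(animal = des$ids), as_tibble(U))
  pe_group <- NULL; pe_individual <- NULL
  if (engine$pe1_n > 0) {
    P1m <- matrix(ms$sol[engine$pe1_ofs + seq_len(engine$pe1_n * engine$np1)],
                  ncol = engine$np1, byrow = TRUE)
    pe_group <- dplyr::bind_cols(tibble(id = des$pe1_ids),
                                 as_tibble(P1m, .name_repair = ~ paste0("pe", seq_along(.) - 1)))
  }
  if (engine$pe2_n > 0) {
    P2m <- matrix(ms$sol[engine$pe2_ofs + seq_len(engine$pe2_n * engine$np2)],
                  ncol = engine$np2, byrow = TRUE)
    pe_individual <- dplyr::bind_cols(tibble(animal = des$pe2_ids),
                                      as_tibble(P2m, .name_repair = ~ paste0("pe", seq_along(.) - 1)))
  }
  residuals <- dplyr::bind_cols(des$info,
                                tibble(y = des$y, fitted = ms$fitted,
                                       resid = ms$resid))
  structure(list(
    fixed = tibble(term = des$fixed_names, estimate = ms$sol[seq_len(p)]),
    genetic = genetic, pe_group = pe_group, pe_individual = pe_individual,
    residuals = residuals, logLik = ms$logL, vc = vc,
    engine = engine, raw = ms), class = "penfeed_mme")
}

#' @export
print.penfeed_mme <- function(x, ...) {
  cat(sprintf("<penfeed_mme> %d records; %d fixed effects; %d animals; restricted logL = %.4f\n",
              nrow(x$residuals), nrow(x$fixed), nrow(x$genetic), x$logLik))
  invisible(x)
}

#' Restricted log-likelihood of the model at given variance components
#'
#' Evaluated through the MME factorisation:
#' `-1/2 (log|R| + log|Gamma| + log|C| + y'Py)`, which equals the direct
#' dense expression `-1/2 (log|V| + log|X'V^{-1}X| + y'Py)` up to the
#' additive constant `-(n - p)/2 log(2*pi)` (omitted).
#'
#' @inheritParams assemble_and_solve
#' @return Scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(design, vc, Kinv) {
  engine <- mme_prepare(design, Kinv)
  solve_mme(engine, vc)$logL
}
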