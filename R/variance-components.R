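#' Variance components of the random-regression models
#'
#' Bundles the genetic coefficient covariance `G` (5x5 for the bivariate
#' model, ordered `[grp0, grp1, ind0, ind1, ind2]`; 2x2 or 3x3 for the
#' univariate sub-models), the permanent-environment blocks `P1` (group,
#' 2x2) and `P2` (individual, 3x3), and the residual variances (one
#' homogeneous animal-day variance for group records; up to eight
#' day-on-test class variances for individual records).
#'
#' @param G Genetic coefficient covariance.
#' @param P1 Group permanent-environment covariance or `NULL`.
#' @param P2 Individual permanent-environment covariance or `NULL`.
#' @param sigma_e_group Group residual variance (animal-day scale) or `NULL`.
#' @param sigma_e_ind Vector of individual residual class variances or `NULL`.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(G, P1 = NULL, P2 = NULL,
                                sigma_e_group = NULL, sigma_e_ind = NULL) {
  G <- as.matrix(G)
  check_psd(G, "G")
  if (!is.null(P1)) check_psd(as.matrix(P1), "P1")
  if (!is.null(P2)) check_psd(as.matrix(P2), "P2")
  if (!is.null(sigma_e_group) && sigma_e_group < 0) {
    abort("`sigma_e_group` must be non-negative.")
  }
  if (!is.null(sigma_e_ind) && any(sigma_e_ind < 0)) {
    abort("`sigma_e_ind` must be non-negative.")
  }
  structure(list(G = G,
                 P1 = if (!is.null(P1)) as.matrix(P1),
                 P2 = if (!is.null(P2)) as.matrix(P2),
                 sigma_e_group = sigma_e_group,
                 sigma_e_ind = sigma_e_ind),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  cat("G (genetic coefficients):\n")
  print(round(x$G, 5))
  if (!is.null(x$P1)) { cat("P1 (group pe):\n"); print(round(x$P1, 5)) }
  if (!is.null(x$P2)) { cat("P2 (individual pe):\n"); print(round(x$P2, 5)) }
  if (!is.null(x$sigma_e_group)) {
    cat(sprintf("sigma_e_group (animal-day): %.5g\n", x$sigma_e_group))
  }
  if (!is.null(x$sigma_e_ind)) {
    cat("sigma_e_ind by class:", paste(signif(x$sigma_e_ind, 4), collapse = " "), "\n")
  }
  invisible(x)
}

# Partition a bivariate G into group (G1), individual (G2) and cross (G12)
# blocks under the fixed coefficient ordering [grp0, grp1, ind0, ind1, ind2].
split_G <- function(G) {
  stopifnot(nrow(G) == 5)
  list(G1 = G[1:2, 1:2, drop = FALSE],
       G2 = G[3:5, 3:5, drop = FALSE],
       G12 = G[3:5, 1:2, drop = FALSE])
}

# Eigenvalue flooring onto the PSD cone; floor relative to the trace.
psd_floor <- function(M, rel = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  floor_val <- rel * max(sum(pmax(e$values, 0)), .Machine$double.eps)
  v <- pmax(e$values, floor_val)
  M2 <- e$vectors %*% (v * t(e$vectors))
  dimnames(M2) <- dimnames(M)
  (M2 + t(M2)) / 2
}
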