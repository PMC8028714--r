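#' Legendre polynomial basis over a day-on-test range
#'
#' Builds the time-covariate basis used by the random-regression models: day
#' `t` is mapped linearly onto `x in [-1, 1]` and the covariate vector is
#' `phi(t) = (P_0(x), ..., P_k(x))` with `P_k` the plain (unnormalised)
#' Legendre polynomials, so the intercept covariate is fixed at 1 for every
#' day.
#'
#' @param order Polynomial order (0 = intercept only). A first-order basis is
#'   the default for the group-level trait, second order for the
#'   individual-level trait.
#' @param t_min,t_max Day-on-test range covered by the basis; evaluation
#'   outside the range is an error unless `extrapolate = TRUE` at evaluation
#'   time.
#' @return An object of class `legendre_basis` with fields `order`, `t_min`,
#'   `t_max`.
#' @examples
#' b <- legendre_basis(2, 1, 60)
#' leg_eval(b, c(1, 30.5, 60))
#' @export
legendre_basis <- function(order, t_min, t_max) {
  stopifnot(length(order) == 1, length(t_min) == 1, length(t_max) == 1)
  if (order < 0 || order != round(order)) {
    abort("`order` must be a non-negative integer.")
  }
  if (!(t_max > t_min)) {
    abort("`t_max` must be strictly greater than `t_min`.")
  }
  structure(
    list(order = as.integer(order), t_min = as.numeric(t_min),
         t_max = as.numeric(t_max)),
    class = "legendre_basis"
  )
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("<legendre_basis> order %d on days [%g, %g]\n",
              x$order, x$t_min, x$t_max))
  invisible(x)
}

#' Evaluate a Legendre basis at days on test
#'
#' @param basis A [legendre_basis()].
#' @param t Numeric vector of days on test.
#' @param extrapolate Allow days outside `[t_min, t_max]` (the mapped `x`
#'   then falls outside `[-1, 1]`). Off by default: the covariance function
#'   is only supported on the fitted range.
#' @return A `length(t) x (order + 1)` matrix; column `k + 1` holds `P_k(x)`.
#' @export
leg_eval <- function(basis, t, extrapolate = FALSE) {
  stopifnot(inherits(basis, "legendre_basis"))
  t <- as.numeric(t)
  if (!extrapolate && length(t) &&
      (min(t) < basis$t_min - 1e-9 || max(t) > basis$t_max + 1e-9)) {
    abort(sprintf(
      "Day(s) on test outside the basis range [%g, %g]: %s. Set `extrapolate = TRUE` to override.",
      basis$t_min, basis$t_max,
      paste(utils::head(t[t < basis$t_min | t > basis$t_max], 5), collapse = ", ")))
  }
  x <- 2 * (t - basis$t_min) / (basis$t_max - basis$t_min) - 1
  legendre_poly_matrix(x, basis$order)
}

# Plain Legendre polynomials via the three-term recurrence
# (k+1) P_{k+1} = (2k+1) x P_k - k P_{k-1}.
legendre_poly_matrix <- function(x, order) {
  n <- length(x)
  phi <- matrix(0, n, order + 1)
  phi[, 1] <- 1
  if (order >= 1) phi[, 2] <- x
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      phi[, k + 2] <- ((2 * k + 1) * x * phi[, k + 1] - k * phi[, k]) / (k + 1)
    }
  }
  colnames(phi) <- paste0("leg", 0:order)
  phi
}
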