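#' Specification of the random-regression mixed model
#'
#' Describes which traits are analysed (the bivariate group + individual
#' model or a univariate sub-model), the Legendre orders of the fixed
#' (`nf`), genetic (`nr`) and permanent-environment (`np`) regressions per
#' trait, the residual-class structure, and the relationship matrix used
#' for the genetic prior.
#'
#' Fixed effects follow the trait equations: start year-month class, a
#' class-specific intercept plus class-specific linear regression on start
#' body weight (days-on-test classes), fixed Legendre regressions nested in
#' group-size-by-test-class cells for the group trait and un-nested for the
#' individual trait.
#'
#' @param traits `"bivariate"`, `"univariate_group"` or
#'   `"univariate_individual"`.
#' @param nr_grp,nr_ind Genetic random-regression orders (defaults 1 and 2).
#' @param np_grp,np_ind Permanent-environment orders (default = genetic).
#' @param nf_grp,nf_ind Fixed-regression orders; must satisfy
#'   `nf >= max(nr, np)` per trait.
#' @param include_pe Fit permanent-environment effects.
#' @param pe_group_level `"group"` (one coefficient pair per feeding group,
#'   the identifiable default) or `"animal"` (per-animal coefficients with
#'   summed incidence, for sensitivity checks).
#' @param resid_group `"homogeneous"` (one variance for both recording
#'   classes, the supported default) or `"two_class"`.
#' @param resid_ind `"classes"` (eight days-on-test classes) or
#'   `"homogeneous"`.
#' @param relationship `"A"` (PBLUP) or `"H"` (ssGBLUP).
#' @return A `model_spec` object.
#' @export
model_spec <- function(traits = c("bivariate", "univariate_group",
                                  "univariate_individual"),
                       nr_grp = 1, nr_ind = 2,
                       np_grp = nr_grp, np_ind = nr_ind,
                       nf_grp = max(nr_grp, np_grp),
                       nf_ind = max(nr_ind, np_ind),
                       include_pe = TRUE,
                       pe_group_level = c("group", "animal"),
                       resid_group = c("homogeneous", "two_class"),
                       resid_ind = c("classes", "homogeneous"),
                       relationship = c("A", "H")) {
  traits <- match.arg(traits)
  spec <- list(
    traits = traits,
    nr_grp = nr_grp, nr_ind = nr_ind, np_grp = np_grp, np_ind = np_ind,
    nf_grp = nf_grp, nf_ind = nf_ind,
    include_pe = include_pe,
    pe_group_level = match.arg(pe_group_level),
    resid_group = match.arg(resid_group),
    resid_ind = match.arg(resid_ind),
    relationship = match.arg(relationship))
  if (spec$nf_grp < max(spec$nr_grp, spec$np_grp) ||
      spec$nf_ind < max(spec$nr_ind, spec$np_ind)) {
    abort("Fixed-regression order must satisfy nf >= max(nr, np) per trait.")
  }
  spec$has_grp <- traits %in% c("bivariate", "univariate_group")
  spec$has_ind <- traits %in% c("bivariate", "univariate_individual")
  spec$nc_grp <- if (spec$has_grp) spec$nr_grp + 1L else 0L
  spec$nc_ind <- if (spec$has_ind) spec$nr_ind + 1L else 0L
  spec$n_coef <- spec$nc_grp + spec$nc_ind
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s; nr = (%s), np = (%s), nf = (%s); pe: %s; residuals: group %s, individual %s; K = %s\n",
              x$traits,
              paste(c(if (x$has_grp) x$nr_grp, if (x$has_ind) x$nr_ind), collapse = ", "),
              paste(c(if (x$has_grp) x$np_grp, if (x$has_ind) x$np_ind), collapse = ", "),
              paste(c(if (x$has_grp) x$nf_grp, if (x$has_ind) x$nf_ind), collapse = ", "),
              if (x$include_pe) x$pe_group_level else "none",
              x$resid_group, x$resid_ind, x$relationship))
  invisible(x)
}
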