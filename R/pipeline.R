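# End-to-end analysis pipeline: simulate (or load) data, estimate variance
# components, predict breeding values, derive genetic-parameter
# trajectories, cross-validate, and write a results directory.

#' Run the analysis pipeline from a configuration
#'
#' Stages (any subset, executed in this order): `simulate`, `reml`,
#' `predict`, `params`, `cv`, `report`. All randomness flows from the
#' single `seed` entry. Outputs are CSV tables, JSON fit summaries and a
#' plain-text log under `out_dir`.
#'
#' @param config Path to a YAML file, or an equivalent named list, with
#'   entries `stages` (character vector), `seed`, `out_dir`, optional
#'   `sim` (arguments for [sim_config()]), `model` (arguments for
#'   [model_spec()]), `reml` (options for [ai_reml()]).
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- cfg$stages %||% c("simulate", "reml", "params")
  bad <- setdiff(stages, c("simulate", "reml", "predict", "params", "cv", "report"))
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% "penfeed_results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", sep = "", file = logf, append = TRUE)
    inform(line)
  }
  logmsg("penfeed %s; seed %d; stages: %s",
         as.character(utils::packageVersion("penfeed")), seed,
         paste(stages, collapse = ", "))
  logmsg("config hash: %s", rlang::hash(cfg))
  res <- list()

  sim_cfg <- do.call(sim_config, cfg$sim %||% list())
  if ("simulate" %in% stages) {
    res$dataset <- simulate_population(sim_cfg, seed = seed)
    write_dataset(res$dataset, file.path(out_dir, "data"))
    logmsg("simulate: %d animals, %d groups, %d individual records",
           nrow(res$dataset$pedigree), dplyr::n_distinct(res$dataset$groups$group),
           nrow(res$dataset$ind_records))
  } else if (!is.null(cfg$data_dir)) {
    ped <- read_pedigree(file.path(cfg$data_dir, "pedigree.csv"))
    res$dataset <- list(
      pedigree = ped,
      ind_records = read_individual_records(
        file.path(cfg$data_dir, "individual_records.csv"), ped),
      grp_records = read_group_records(
        file.path(cfg$data_dir, "group_records.csv"), ped),
      genotypes = read_genotypes(file.path(cfg$data_dir, "genotypes.tsv"), ped))
    logmsg("loaded data from %s", cfg$data_dir)
  } else {
    abort("No `simulate` stage and no `data_dir` given.")
  }

  spec <- do.call(model_spec, cfg$model %||% list())
  des <- build_design(res$dataset, spec,
                      basis_grp = sim_cfg$basis_grp,
                      basis_ind = if (spec$has_ind) sim_cfg$basis_ind)
  Kinv <- if (spec$relationship == "H") {
    G <- gmatrix(res$dataset$genotypes)
    hinverse(res$dataset$pedigree, G)
  } else {
    ainverse(res$dataset$pedigree)
  }
  res$design <- des

  if ("reml" %in% stages) {
    opts <- cfg$reml %||% list()
    res$fit <- do.call(ai_reml, c(list(design = des, Kinv = Kinv), opts))
    logmsg("reml: logL %.4f, %s in %d iterations", res$fit$logLik,
           if (res$fit$converged) "converged" else "not converged",
           res$fit$iterations)
    jsonlite::write_json(
      list(logLik = res$fit$logLik, converged = res$fit$converged,
           iterations = res$fit$iterations,
           G = unclass(res$fit$vc$G), P1 = res$fit$vc$P1, P2 = res$fit$vc$P2,
           sigma_e_group = res$fit$vc$sigma_e_group,
           sigma_e_ind = res$fit$vc$sigma_e_ind,
           ai_matrix = res$fit$ai_matrix),
      file.path(out_dir, "reml_fit.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(tidy(res$fit), file.path(out_dir, "reml_parameters.csv"))
  }

  vc <- if (!is.null(res$fit)) res$fit$vc else res$dataset$truth$vc

  if ("predict" %in% stages) {
    sol <- assemble_and_solve(des, vc, Kinv)
    res$solution <- sol
    readr::write_csv(sol$genetic, file.path(out_dir, "genetic_solutions.csv"))
    readr::write_csv(sol$fixed, file.path(out_dir, "fixed_solutions.csv"))
    logmsg("predict: %d animals solved (%s)", nrow(sol$genetic), spec$relationship)
  }

  if ("params" %in% stages) {
    traj <- list()
    if (spec$has_grp) {
      traj$group <- heritability_trajectory(vc, "group", des$basis_grp,
                                            seq(des$basis_grp$t_min, des$basis_grp$t_max))
    }
    if (spec$has_ind) {
      traj$individual <- heritability_trajectory(vc, "individual", des$basis_ind,
                                                 seq(des$basis_ind$t_min, des$basis_ind$t_max))
    }
    res$trajectories <- dplyr::bind_rows(traj)
    readr::write_csv(res$trajectories, file.path(out_dir, "heritability_trajectories.csv"))
    if (spec$traits == "bivariate") {
      days_g <- seq(des$basis_grp$t_min, des$basis_grp$t_max)
      days_i <- seq(des$basis_ind$t_min, des$basis_ind$t_max)
      res$daily_r <- daily_genetic_correlation(vc, des$basis_grp, des$basis_ind)
      res$period_r <- period_genetic_correlation(vc, des$basis_grp, des$basis_ind,
                                                 days_g, days_i)
      readr::write_csv(res$daily_r, file.path(out_dir, "daily_genetic_correlation.csv"))
      jsonlite::write_json(list(period_r = res$period_r),
                           file.path(out_dir, "period_correlation.json"),
                           auto_unbox = TRUE, digits = NA)
      logmsg("params: whole-period genetic correlation %.4f", res$period_r)
    }
  }

  if ("cv" %in% stages) {
    res$cv <- run_logo_cv(res$dataset, vc, spec, Kinv,
                          basis_grp = des$basis_grp,
                          basis_ind = if (spec$has_ind) des$basis_ind)
    readr::write_csv(res$cv$stats, file.path(out_dir, "cv_statistics.csv"))
    readr::write_csv(res$cv$group, file.path(out_dir, "cv_groups.csv"))
    logmsg("cv: %d folds; rho_fr(all) %.4f", res$cv$n_folds,
           res$cv$stats$rho_fr[res$cv$stats$stratum == "all"])
  }

  if ("report" %in% stages) {
    lines <- c(
      sprintf("penfeed pipeline report (seed %d)", seed),
      sprintf("stages: %s", paste(stages, collapse = ", ")),
      if (!is.null(res$fit)) sprintf("REML logL: %.4f (%d iterations)",
                                     res$fit$logLik, res$fit$iterations),
      if (!is.null(res$period_r)) sprintf("whole-period genetic correlation: %.4f",
                                          res$period_r),
      if (!is.null(res$cv)) sprintf("LOGO-CV rho_yc_r: %.4f",
                                    res$cv$stats$rho_yc_r[res$cv$stats$stratum == "group"]))
    writeLines(lines, file.path(out_dir, "report.txt"))
    logmsg("report written")
  }
  invisible(res)
}
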