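# Readers/writers for the tabular interchange formats (CSV with "."
# decimal; genotypes as TSV with NA for missing; member lists joined with
# ";"), plus the genotype quality-control filters.

#' Read a pedigree CSV (animal, sire, dam; 0 = unknown)
#' @param path File path.
#' @return Validated, topologically sorted pedigree tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, show_col_types = FALSE)
  ped_normalise(ped)[, c("animal", "sire", "dam")]
}

#' Read an individual daily feed-intake record CSV
#'
#' Columns: `animal`, `day`, `ym`, `weight`, `y`. One record per
#' animal-day; duplicates are rejected with their row numbers.
#' @param path File path.
#' @param pedigree Optional pedigree; every recorded animal must appear.
#' @return Tibble with a derived `dot_class` column.
#' @export
read_individual_records <- function(path, pedigree = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("animal", "day", "ym", "weight", "y")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  dup <- which(duplicated(x[, c("animal", "day")]))
  if (length(dup)) {
    abort(paste0("Duplicate animal-day record(s) at row(s): ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(x$day < 1)) abort("Days on test must be >= 1.")
  if (!is.null(pedigree)) {
    bad <- setdiff(x$animal, pedigree$animal)
    if (length(bad)) {
      abort(paste0("Recorded animal(s) absent from the pedigree: ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  x$dot_class <- dot_class(x$day)
  x
}

#' Read a group feed-intake record CSV
#'
#' Columns: `group`, `time_point`, `day`, `ym`, `mean_start_weight`,
#' `size_class`, `nt`, `nd`, `y`, `members`, `present` (the last two as
#' ";"-separated animal-id lists).
#' @inheritParams read_individual_records
#' @return Tibble with `members`/`present` as list-columns.
#' @export
read_group_records <- function(path, pedigree = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(members = "c", present = "c"))
  need <- c("group", "time_point", "day", "ym", "mean_start_weight",
            "size_class", "nt", "nd", "y", "members", "present")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  split_ids <- function(s) lapply(strsplit(s, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    if (all(grepl("^-?[0-9]+$", v))) as.integer(v) else v
  })
  x$members <- split_ids(x$members)
  x$present <- split_ids(x$present)
  if (any(x$nd < 1)) abort("`nd` must be >= 1.")
  if (any(x$nt > lengths(x$members))) abort("`nt` exceeds the member-list length.")
  if (!is.null(pedigree)) {
    bad <- setdiff(unique(unlist(x$members)), pedigree$animal)
    if (length(bad)) {
      abort(paste0("Group member(s) absent from the pedigree: ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  x
}

#' Read a genotype TSV (rows = animals, columns = SNPs, codes 0/1/2/NA)
#' @inheritParams read_individual_records
#' @return Numeric matrix with animal rownames.
#' @export
read_genotypes <- function(path, pedigree = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(x[[1]])
  M <- as.matrix(x[, -1, drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- ids
  ok <- M %in% c(0, 1, 2) | is.na(M)
  if (!all(ok)) abort("Genotype codes must be 0, 1, 2 or NA.")
  if (!is.null(pedigree)) {
    bad <- setdiff(ids, as.character(pedigree$animal))
    if (length(bad)) {
      abort(paste0("Genotyped animal(s) absent from the pedigree: ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  M
}

#' Write the tables of a simulated dataset to a directory
#'
#' Pedigree, individual and group records as CSV, genotypes as TSV, the
#' simulation truth as JSON, and the configuration as YAML.
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$pedigree[, c("animal", "sire", "dam")],
                   file.path(dir, "pedigree.csv"))
  readr::write_csv(dataset$ind_records[, c("animal", "day", "ym", "weight", "y")],
                   file.path(dir, "individual_records.csv"))
  g <- dataset$grp_records
  g$members <- vapply(g$members, paste, character(1), collapse = ";")
  g$present <- vapply(g$present, paste, character(1), collapse = ";")
  readr::write_csv(g, file.path(dir, "group_records.csv"))
  gt <- tibble::as_tibble(dataset$genotypes, rownames = "animal")
  readr::write_tsv(gt, file.path(dir, "genotypes.tsv"))
  truth <- dataset$truth
  jsonlite::write_json(list(
    true_G = unclass(truth$vc$G), true_P1 = truth$vc$P1, true_P2 = truth$vc$P2,
    sigma_e_group = truth$vc$sigma_e_group, sigma_e_ind = truth$vc$sigma_e_ind,
    period_r = dataset$truth$period_r,
    mean_h2_group = mean(truth$h2_group$h2),
    mean_h2_individual = mean(truth$h2_individual$h2)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- dataset$config
  cfg_out <- cfg[!vapply(cfg, function(x) inherits(x, "legendre_basis"), logical(1))]
  cfg_out <- purrr::map(cfg_out, function(x) if (is.matrix(x)) as.data.frame(x) else x)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Quality-control filters for a genotype panel
#'
#' Applies, in order: (1) per-call quality masking (calls below
#' `min_call_quality` set missing), (2) animal filter (mean call rate),
#' (3) SNP filters on the remaining animals: call rate, minor allele
#' frequency, and a one-degree-of-freedom Hardy-Weinberg chi-square test.
#'
#' @param gt Genotype matrix (animals x SNPs, codes 0/1/2/NA).
#' @param quality Optional matrix of per-call quality scores in `[0, 1]`.
#' @param min_call_quality Calls below this are set missing.
#' @param min_animal_call_rate Animals below this mean call rate are
#'   excluded.
#' @param min_snp_call_rate,min_maf,hwe_p_threshold SNP thresholds: call
#'   rate and MAF must exceed their thresholds, the HWE p-value must
#'   exceed `hwe_p_threshold`.
#' @return List: `genotypes` (filtered matrix), `exclusions` (tibble
#'   `item`, `type`, `reason`).
#' @export
qc_filter_genotypes <- function(gt, quality = NULL,
                                min_call_quality = 0.6,
                                min_animal_call_rate = 0.8,
                                min_snp_call_rate = 0.9,
                                min_maf = 0.01,
                                hwe_p_threshold = 1e-7) {
  M <- as.matrix(gt)
  excl <- list()
  if (!is.null(quality)) {
    stopifnot(all(dim(quality) == dim(M)))
    M[quality < min_call_quality] <- NA
  }
  acr <- rowMeans(!is.na(M))
  bad_a <- acr < min_animal_call_rate
  if (any(bad_a)) {
    excl[[length(excl) + 1L]] <- tibble(
      item = rownames(M)[bad_a], type = "animal",
      reason = sprintf("call rate %.3f < %.2f", acr[bad_a], min_animal_call_rate))
    M <- M[!bad_a, , drop = FALSE]
  }
  if (nrow(M) == 0) {
    warn("All animals excluded by the call-rate filter.")
    return(list(genotypes = M, exclusions = qc_exclusion_table(excl)))
  }
  scr <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_pvalues(M)
  bad_cr <- scr <= min_snp_call_rate
  bad_maf <- !bad_cr & maf <= min_maf
  bad_hwe <- !bad_cr & !bad_maf & hwe_p <= hwe_p_threshold
  for (sel_reason in list(list(bad_cr, "call rate"), list(bad_maf, "MAF"),
                          list(bad_hwe, "HWE"))) {
    sel <- sel_reason[[1]]
    if (any(sel)) {
      excl[[length(excl) + 1L]] <- tibble(
        item = colnames(M)[sel], type = "snp", reason = sel_reason[[2]])
    }
  }
  keep <- !(bad_cr | bad_maf | bad_hwe)
  M <- M[, keep, drop = FALSE]
  if (ncol(M) == 0) warn("All SNPs excluded by the QC filters.")
  list(genotypes = M, exclusions = qc_exclusion_table(excl))
}

qc_exclusion_table <- function(excl) {
  out <- dplyr::bind_rows(excl)
  if (!nrow(out)) {
    out <- tibble(item = character(), type = character(), reason = character())
  }
  out
}

# one-df chi-square HWE test per SNP (observed vs expected genotype counts)
hwe_pvalues <- function(M) {
  vapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) return(1)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    p <- mean(x) / 2
    q <- 1 - p
    exp <- n * c(q^2, 2 * p * q, p^2)
    if (any(exp == 0)) return(1)
    stat <- sum((obs - exp)^2 / exp)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
}
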