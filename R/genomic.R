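#' Genomic relationship matrix (allele-frequency centred cross-product)
#'
#' VanRaden's first method: genotype codes 0/1/2 are centred by twice the
#' allele frequency, missing codes are mean-imputed, and
#' `G = Z Z' / (2 * sum(p * (1 - p)))`.
#'
#' @param genotypes Numeric matrix, animals in rows (rownames = ids), SNPs in
#'   columns, codes in `{0, 1, 2, NA}`.
#' @param allele_freqs Optional vector of allele frequencies per SNP; when
#'   `NULL` they are taken as observed means / 2.
#' @return Dense symmetric matrix with dimnames = animal ids and attribute
#'   `allele_freqs`.
#' @export
gmatrix <- function(genotypes, allele_freqs = NULL) {
  M <- as.matrix(genotypes)
  if (is.null(rownames(M))) rownames(M) <- seq_len(nrow(M))
  ok <- M %in% c(0, 1, 2) | is.na(M)
  if (!all(ok)) abort("Genotype codes must be 0, 1, 2 or NA.")
  p <- allele_freqs %||% (colMeans(M, na.rm = TRUE) / 2)
  if (length(p) != ncol(M)) abort("`allele_freqs` length must equal the SNP count.")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    abort("All SNPs are monomorphic: the genomic relationship scale 2*sum(p(1-p)) is zero.")
  }
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0 # missing -> 2p, i.e. centred value 0
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "allele_freqs") <- p
  G
}

#' Inverse of the combined (single-step) relationship matrix
#'
#' Merges pedigree and genomic information:
#' `Hinv = Ainv + [0, 0; 0, Gw^{-1} - A22^{-1}]` on the genotyped block,
#' with `Gw = (1 - blend) * G_adj + blend * A22`. When `tune = TRUE` the
#' genomic matrix is first rescaled (`a + b * G`) so that its mean diagonal
#' and mean off-diagonal match those of `A22`, putting the two matrices on a
#' compatible base-population scale.
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @param G Genomic relationship matrix from [gmatrix()] (rownames = ids);
#'   `NULL` or empty for no genotyped animals.
#' @param blend Weight on `A22` in the blended genomic matrix, in `(0, 1]`.
#' @param tune Rescale G to match `A22` means before blending.
#' @return Sparse symmetric `Hinv` in pedigree order, with attributes `ids`,
#'   `logdet` (log|H|) and `genotyped` (ids in the genomic block).
#' @export
hinverse <- function(ped, G = NULL, blend = 0.05, tune = TRUE) {
  ped <- ped_normalise(ped)
  Ainv <- ainverse(ped)
  ids <- ped$animal
  if (is.null(G) || nrow(G) == 0) {
    attr(Ainv, "genotyped") <- character(0)
    return(Ainv)
  }
  if (!(blend > 0 && blend <= 1)) abort("`blend` must lie in (0, 1].")
  gids <- rownames(G)
  if (!all(gids %in% as.character(ids))) {
    abort("Genotyped animals absent from the pedigree.")
  }
  A <- amatrix(ped)
  idx <- match(gids, as.character(ids))
  A22 <- A[idx, idx, drop = FALSE]
  Gm <- as.matrix(G)
  if (tune) {
    # match mean diagonal and mean off-diagonal: G_adj = a + b G
    nG <- nrow(Gm)
    mdg <- mean(diag(Gm)); mda <- mean(diag(A22))
    mog <- (sum(Gm) - sum(diag(Gm))) / (nG * (nG - 1))
    moa <- (sum(A22) - sum(diag(A22))) / (nG * (nG - 1))
    b <- if (abs(mdg - mog) > 1e-12) (mda - moa) / (mdg - mog) else 1
    a <- mda - b * mdg
    Gm <- a + b * Gm
  }
  Gw <- (1 - blend) * Gm + blend * A22
  ev_min <- min(eigen(Gw, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10 * mean(diag(Gw))) {
    abort("Blended genomic matrix is (near-)singular; increase `blend`.")
  }
  cw <- chol(Gw)
  c22 <- chol(A22)
  Gwi <- chol2inv(cw)
  A22i <- chol2inv(c22)
  Delta <- Gwi - A22i
  n <- length(ids)
  Dsp <- Matrix::sparseMatrix(
    i = rep(idx, times = length(idx)),
    j = rep(idx, each = length(idx)),
    x = as.numeric(Delta), dims = c(n, n),
    dimnames = list(ids, ids))
  Hinv <- methods::as(Matrix::forceSymmetric(Ainv + Dsp), "CsparseMatrix")
  # log|H| = log|A| + log|Gw| - log|A22|
  attr(Hinv, "logdet") <- attr(Ainv, "logdet") +
    2 * sum(log(diag(cw))) - 2 * sum(log(diag(c22)))
  attr(Hinv, "ids") <- ids
  attr(Hinv, "genotyped") <- gids
  Hinv
}
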