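#' Normalise and validate a pedigree table
#'
#' Checks a three-column pedigree (animal, sire, dam; 0 or `NA` = unknown
#' parent), verifies that ids are unique and that no animal is its own
#' ancestor, and returns the pedigree sorted so that parents precede
#' offspring.
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam`.
#' @return A tibble with the same columns in topological order, plus the
#'   integer columns `sire_idx`/`dam_idx` (0 = unknown) used internally.
#' @export
ped_normalise <- function(ped) {
  ped <- as_tibble(ped)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    abort("Pedigree needs columns `animal`, `sire`, `dam`.")
  }
  ped$sire[is.na(ped$sire)] <- 0
  ped$dam[is.na(ped$dam)] <- 0
  ids <- ped$animal
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated animal id(s): ",
                 paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
  }
  n <- nrow(ped)
  sidx <- match(ped$sire, ids, nomatch = 0L)
  didx <- match(ped$dam, ids, nomatch = 0L)
  unk_s <- ped$sire != 0 & sidx == 0L
  unk_d <- ped$dam != 0 & didx == 0L
  if (any(unk_s | unk_d)) {
    abort(paste0("Parent id(s) absent from the pedigree: ",
                 paste(unique(c(ped$sire[unk_s], ped$dam[unk_d]))[1:3],
                       collapse = ", ")))
  }
  # Kahn topological sort; leftover nodes expose a cycle.
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sidx[i], didx[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  depth <- integer(n)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      depth[ch] <- max(depth[ch], depth[v] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ids[setdiff(seq_len(n), order)]
    abort(paste0("Pedigree contains a cycle (animal its own ancestor) ",
                 "involving: ", paste(utils::head(cyc, 5), collapse = ", ")))
  }
  # stable ordering: generation depth, ties by input position, so an
  # already parents-first table keeps its order on a round trip
  ped <- ped[base::order(depth, seq_len(n)), , drop = FALSE]
  ids <- ped$animal
  ped$sire_idx <- match(ped$sire, ids, nomatch = 0L)
  ped$dam_idx <- match(ped$dam, ids, nomatch = 0L)
  ped
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @return Tibble with `animal`, `f` (inbreeding coefficient) and `d`
#'   (Mendelian-sampling variance share, the diagonal of Henderson's D).
#' @export
ped_inbreeding <- function(ped) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  sire <- ped$sire_idx
  dam <- ped$dam_idx
  f <- numeric(n)
  d <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dm <- dam[i]
    d[i] <- 0.5 -
      0.25 * (if (s > 0) f[s] else -1) -
      0.25 * (if (dm > 0) f[dm] else -1)
    if (s == 0 || dm == 0) {
      f[i] <- 0
      next
    }
    # a_ii = sum_j L_j^2 d_j over ancestors j of i (including i).
    aii <- 0
    L[i] <- 1
    anc <- i
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0) {
        if (L[sj] == 0) anc <- c(anc, sj)
        L[sj] <- L[sj] + 0.5 * L[j]
      }
      if (dj > 0) {
        if (L[dj] == 0) anc <- c(anc, dj)
        L[dj] <- L[dj] + 0.5 * L[j]
      }
      aii <- aii + L[j]^2 * d[j]
      L[j] <- 0
    }
    f[i] <- aii - 1
  }
  tibble(animal = ped$animal, f = f, d = d)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense `A`; intended for pedigrees of up to a few thousand animals (tests,
#' oracles, and the genotyped block `A22` of the single-step matrix).
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @return Dense symmetric matrix with dimnames = animal ids, in
#'   parents-before-offspring order.
#' @export
amatrix <- function(ped) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  sire <- ped$sire_idx
  dam <- ped$dam_idx
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; dm <- dam[i]
    aii <- 1
    if (s > 0 && dm > 0) aii <- 1 + 0.5 * A[s, dm]
    A[i, i] <- aii
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- numeric(i - 1)
      if (s > 0) aij <- aij + 0.5 * A[j, s]
      if (dm > 0) aij <- aij + 0.5 * A[j, dm]
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding (Meuwissen-Luo coefficients).
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @return A sparse symmetric matrix (`dsCMatrix`) in pedigree order with
#'   attributes `logdet` (log|A|) and `ids`.
#' @export
ainverse <- function(ped) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  inb <- ped_inbreeding(ped)
  d <- inb$d
  sire <- ped$sire_idx
  dam <- ped$dam_idx
  # triplets: per animal up to 9 entries
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- 1 / d
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  # vectorised triplet assembly
  i <- seq_len(n)
  ii <- i; jj <- i; xx <- b
  has_s <- sire > 0
  has_d <- dam > 0
  ii <- c(ii, i[has_s], i[has_d])
  jj <- c(jj, sire[has_s], dam[has_d])
  xx <- c(xx, -0.5 * b[has_s], -0.5 * b[has_d])
  ii <- c(ii, sire[has_s], dam[has_d])
  jj <- c(jj, i[has_s], i[has_d])
  xx <- c(xx, -0.5 * b[has_s], -0.5 * b[has_d])
  ii <- c(ii, sire[has_s], dam[has_d])
  jj <- c(jj, sire[has_s], dam[has_d])
  xx <- c(xx, 0.25 * b[has_s], 0.25 * b[has_d])
  both <- has_s & has_d
  ii <- c(ii, sire[both], dam[both])
  jj <- c(jj, dam[both], sire[both])
  xx <- c(xx, 0.25 * b[both], 0.25 * b[both])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
  attr(Ainv, "logdet") <- sum(log(d))
  attr(Ainv, "ids") <- ped$animal
  Ainv
}

#' Pedigree relationship matrix and its inverse
#'
#' Convenience wrapper bundling [amatrix()] and [ainverse()] for moderate
#' pedigrees.
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @return List with `A` (dense), `Ainv` (sparse), `ids`, `inbreeding`
#'   (tibble) and `logdet` = log|A|.
#' @export
numerator_relationship <- function(ped) {
  ped <- ped_normalise(ped)
  Ainv <- ainverse(ped)
  list(A = amatrix(ped), Ainv = Ainv, ids = ped$animal,
       inbreeding = ped_inbreeding(ped), logdet = attr(Ainv, "logdet"))
}
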