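#' Prune a pedigree to informative animals
#'
#' Keeps the requested animals plus all their ancestors; leaf animals
#' without records or genotypes contribute nothing to the mixed-model
#' analysis and can be removed to shrink the equations.
#'
#' @param ped Pedigree accepted by [ped_normalise()].
#' @param keep Ids of animals that must be retained (typically all
#'   phenotyped and genotyped animals).
#' @return The pruned pedigree tibble (`animal`, `sire`, `dam`), sorted
#'   parents before offspring.
#' @export
ped_prune <- function(ped, keep) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  need <- rep(FALSE, n)
  need[match(keep, ped$animal)] <- TRUE
  # pedigree is topologically sorted: one reverse sweep collects ancestors
  for (i in rev(seq_len(n))) {
    if (need[i]) {
      if (ped$sire_idx[i] > 0) need[ped$sire_idx[i]] <- TRUE
      if (ped$dam_idx[i] > 0) need[ped$dam_idx[i]] <- TRUE
    }
  }
  out <- ped[need, c("animal", "sire", "dam")]
  ped_normalise(out)[, c("animal", "sire", "dam")]
}
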