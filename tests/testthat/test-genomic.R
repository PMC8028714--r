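test_that("the centred cross-product has its closed form on a two-animal panel", {
  M <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- gmatrix(M, allele_freqs = 0.5)
  expect_equal(unname(G[, ]), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # an all-missing animal is mean-imputed: zero row/column, finite diagonal
  M2 <- rbind(M, c(NA))
  rownames(M2) <- c("a", "b", "c")
  G2 <- gmatrix(M2, allele_freqs = 0.5)
  expect_true(all(is.finite(G2)))
  expect_equal(unname(G2["c", ]), c(0, 0, 0))
  expect_error(gmatrix(matrix(2, 3, 2)), "monomorphic")
  expect_error(gmatrix(matrix(c(0, 3), 1, 2)), "codes")
})

test_that("mean diagonal is near 1 under Hardy-Weinberg panels", {
  set.seed(3)
  n <- 150; m <- 2000
  p <- runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  G <- gmatrix(M)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
})

test_that("gene-dropped parent-offspring pairs average 0.5 genomic relationship", {
  set.seed(4)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  n_pairs <- 60
  h <- function(pp) rbinom(length(pp), 1, pp)
  par1 <- t(replicate(n_pairs, h(p) + h(p)))
  par2 <- t(replicate(n_pairs, h(p) + h(p)))
  gamete <- function(dose) {
    # one gamete from an individual's two (unphased-equivalent) haplotypes
    het <- dose == 1
    g <- dose / 2
    g[het] <- rbinom(sum(het), 1, 0.5)
    g
  }
  off <- t(sapply(seq_len(n_pairs), function(i) gamete(par1[i, ]) + gamete(par2[i, ])))
  M <- rbind(par1, par2, off)
  rownames(M) <- c(paste0("s", 1:n_pairs), paste0("d", 1:n_pairs),
                   paste0("o", 1:n_pairs))
  G <- gmatrix(M, allele_freqs = p)
  po <- mean(G[cbind(paste0("s", 1:n_pairs), paste0("o", 1:n_pairs))])
  expect_lt(abs(po - 0.5), 0.05)
})

test_that("combined single-step inverse degenerates and matches brute force", {
  set.seed(5)
  ped <- data.frame(animal = 1:10,
                    sire = c(0, 0, 0, 1, 1, 3, 3, 5, 5, 7),
                    dam = c(0, 0, 0, 2, 2, 4, 4, 6, 6, 8))
  # no genotyped animals: single-step collapses to the pedigree inverse
  Ai <- ainverse(ped)
  H0 <- hinverse(ped, NULL)
  expect_equal(as.matrix(H0), as.matrix(Ai), tolerance = 1e-12)
  # genotyped subset: compare with the explicit joint matrix
  gids <- c("5", "7", "9", "10")
  m <- 300
  p <- runif(m, 0.2, 0.5)
  M <- sapply(p, function(pp) rbinom(4, 2, pp))
  rownames(M) <- gids
  G <- gmatrix(M)
  blend <- 0.2
  Hi <- hinverse(ped, G, blend = blend, tune = TRUE)
  A <- amatrix(ped)
  idx <- match(gids, rownames(A))
  A22 <- A[idx, idx]
  Gm <- as.matrix(G)
  nG <- nrow(Gm)
  mog <- (sum(Gm) - sum(diag(Gm))) / (nG * (nG - 1))
  moa <- (sum(A22) - sum(diag(A22))) / (nG * (nG - 1))
  b <- (mean(diag(A22)) - moa) / (mean(diag(Gm)) - mog)
  a <- mean(diag(A22)) - b * mean(diag(Gm))
  Gw <- (1 - blend) * (a + b * Gm) + blend * A22
  # textbook joint H built explicitly, then inverted densely
  A12 <- A[-idx, idx]; A11 <- A[-idx, -idx]
  A22i <- solve(A22)
  H11 <- A11 + A12 %*% A22i %*% (Gw - A22) %*% A22i %*% t(A12)
  H12 <- A12 %*% A22i %*% Gw
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gw))
  ord <- c(rownames(A)[-idx], gids)
  Hfull <- solve(H)
  expect_lt(max(abs(as.matrix(Hi)[ord, ord] - Hfull)), 1e-8)
  # all animals genotyped at full blend weight: back to the pedigree matrix
  Mall <- sapply(p, function(pp) rbinom(10, 2, pp))
  rownames(Mall) <- rownames(A)
  Hall <- hinverse(ped, gmatrix(Mall), blend = 1, tune = TRUE)
  expect_lt(max(abs(as.matrix(Hall) - as.matrix(Ai))), 1e-8)
})
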