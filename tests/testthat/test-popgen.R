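test_that("heterozygosity matches hand tallies", {
  # all heterozygous at one locus
  calls <- cbind(L1 = rep(1L, 4), L2 = c(0L, 0L, 2L, 2L))
  rownames(calls) <- paste0("i", 1:4)
  G <- genotype_matrix(calls, setNames(rep(1, 4), rownames(calls)))
  hz <- heterozygosity(G)
  # L1: Ho = 1, p = 0.5, He = 0.5 * 8/7; L2: Ho = 0, p = 0.5, same He
  he_l <- 2 * 0.5 * 0.5 * 8 / 7
  expect_equal(hz$Ho, 0.5)
  expect_equal(hz$He, he_l)
  expect_equal(hz$F_IS, 1 - 0.5 / he_l)

  # monomorphic locus contributes He = 0 and is excluded from F_IS
  calls2 <- cbind(L1 = c(1L, 1L, 0L), L2 = c(2L, 2L, 2L))
  rownames(calls2) <- paste0("i", 1:3)
  G2 <- genotype_matrix(calls2, setNames(rep(1, 3), rownames(calls2)))
  hz2 <- heterozygosity(G2)
  p1 <- 2 / 6
  he1 <- 2 * p1 * (1 - p1) * 6 / 5
  expect_equal(hz2$He, he1 / 2)                 # mean with He(L2) = 0
  expect_equal(hz2$F_IS, 1 - (2 / 3) / he1)     # L2 dropped from F_IS

  # a 10-individual tally with missing data, against direct arithmetic
  set.seed(2)
  calls3 <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                          prob = c(.35, .3, .25, .1)), 10, 4,
                   dimnames = list(paste0("i", 1:10), paste0("L", 1:4)))
  G3 <- genotype_matrix(calls3, setNames(rep(1, 10), rownames(calls3)))
  hz3 <- heterozygosity(G3)
  ho_l <- he_l <- numeric(0)
  for (l in 1:4) {
    g <- calls3[, l]; g <- g[!is.na(g)]
    if (length(g) < 2) next
    p <- mean(g) / 2
    ho_l <- c(ho_l, mean(g == 1))
    he_l <- c(he_l, 2 * p * (1 - p) * 2 * length(g) / (2 * length(g) - 1))
  }
  expect_equal(hz3$Ho, mean(ho_l), tolerance = 1e-12)
  expect_equal(hz3$He, mean(he_l), tolerance = 1e-12)

  # single-individual localities carry no statistics
  G4 <- genotype_matrix(rbind(a = c(0L, 1L), b = c(1L, 1L), c = c(2L, 0L)),
                        c(a = 1, b = 1, c = 2))
  expect_true(is.na(heterozygosity(G4)$Ho[2]))
})

test_that("Weir-Cockerham F_ST matches an independent mean-square oracle", {
  # identical genotype tables: theta near 0 (the WC84 finite-sample
  # correction leaves a small negative value of order -1/(2n))
  set.seed(1)
  half <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30)
  storage.mode(half) <- "integer"
  calls <- rbind(half, half)
  rownames(calls) <- paste0("i", 1:40)
  G <- genotype_matrix(calls, setNames(rep(1:2, each = 20), rownames(calls)))
  expect_lt(abs(pairwise_fst(G)[1, 2]), 0.05)

  # fixed difference at every locus: theta = 1
  calls2 <- rbind(matrix(0L, 3, 4), matrix(2L, 3, 4))
  rownames(calls2) <- paste0("i", 1:6)
  G2 <- genotype_matrix(calls2, setNames(rep(1:2, each = 3), rownames(calls2)))
  expect_equal(pairwise_fst(G2)[1, 2], 1)

  # 2-population, 2-locus worked case vs the mean-square formulation:
  # for balanced sizes theta = (MSP - MSG') etc.; evaluated per locus
  # from first principles (counts of alleles and heterozygotes)
  callsA <- rbind(c(0L, 1L), c(1L, 1L), c(0L, 0L), c(2L, 1L))
  callsB <- rbind(c(2L, 2L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  calls3 <- rbind(callsA, callsB)
  rownames(calls3) <- paste0("i", 1:8)
  colnames(calls3) <- c("L1", "L2")
  G3 <- genotype_matrix(calls3, setNames(rep(1:2, each = 4), rownames(calls3)))
  num <- den <- 0
  for (l in 1:2) {
    n <- c(4, 4)
    p <- c(mean(callsA[, l]) / 2, mean(callsB[, l]) / 2)
    h <- c(mean(callsA[, l] == 1), mean(callsB[, l] == 1))
    r <- 2; nbar <- 4; nc <- 4
    pbar <- mean(p); s2 <- sum((p - pbar)^2) / (r - 1); hbar <- mean(h)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / r - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / r -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    num <- num + a
    den <- den + a + b + hbar / 2
  }
  expect_equal(pairwise_fst(G3)[1, 2], num / den, tolerance = 1e-12)
})

test_that("chord and Prevosti distances evaluate their formulas", {
  freq <- rbind(a = c(0.5, 0.2), b = c(0.5, 0.2))
  expect_equal(chord_distance(freq)[1, 2], 0)
  expect_equal(prevosti_distance(freq)[1, 2], 0)

  fix <- rbind(a = 0, b = 1)
  expect_equal(prevosti_distance(fix)[1, 2], 1)
  expect_equal(chord_distance(fix)[1, 2], 2 / pi * sqrt(2),
               tolerance = 1e-12)

  # missing locus dropped pairwise with L adjusted
  fm <- rbind(a = c(0, 0.5), b = c(1, NA))
  expect_equal(prevosti_distance(fm)[1, 2], 1)
})

test_that("AMOVA components match a brute-force partition", {
  # two fully fixed clusters
  calls <- rbind(matrix(0L, 3, 5), matrix(2L, 3, 5))
  rownames(calls) <- paste0("i", 1:6)
  G <- genotype_matrix(calls, setNames(rep(1:2, each = 3), rownames(calls)))
  res <- amova(G, setNames(c("A", "B"), 1:2), n_perm = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  # only relabellings reproducing the split reach phi = 1: p ~ 0.1 at 3+3
  expect_lte(res$p_value, 0.15)

  # 6-individual toy: components against explicit sums of squares
  set.seed(4)
  calls2 <- matrix(sample(0:2, 6 * 4, replace = TRUE), 6, 4,
                   dimnames = list(paste0("i", 1:6), paste0("L", 1:4)))
  G2 <- genotype_matrix(calls2, setNames(rep(1:2, each = 3), rownames(calls2)))
  cl <- setNames(c("A", "B"), 1:2)
  res2 <- amova(G2, cl, n_perm = 49, seed = 2)
  d2 <- as.matrix(dist(calls2))^2
  ss_t <- sum(d2[upper.tri(d2)]) / 6
  ss_w <- sum(d2[1:3, 1:3][upper.tri(d2[1:3, 1:3])]) / 3 +
    sum(d2[4:6, 4:6][upper.tri(d2[4:6, 4:6])]) / 3
  ms_a <- (ss_t - ss_w) / 1
  ms_w <- ss_w / 4
  s2a <- (ms_a - ms_w) / 3
  expect_equal(res2$phi_st, s2a / (s2a + ms_w), tolerance = 1e-12)

  # null behaviour: panmictic pool gives small phi, unremarkable p
  set.seed(9)
  calls3 <- matrix(rbinom(40 * 50, 2, 0.4), 40, 50,
                   dimnames = list(paste0("i", 1:40), NULL))
  G3 <- genotype_matrix(calls3, setNames(rep(1:2, each = 20),
                                         rownames(calls3)))
  res3 <- amova(G3, setNames(c("A", "B"), 1:2), n_perm = 99, seed = 3)
  expect_lt(abs(res3$phi_st), 0.05)
  expect_gt(res3$p_value, 0.05)
  expect_error(amova(G3, setNames(c("A", "A"), 1:2), 10), "2 clusters")
})

test_that("PCoA reproduces distances and handles duplicates/missing", {
  set.seed(5)
  calls <- matrix(sample(0:2, 8 * 10, replace = TRUE), 8, 10,
                  dimnames = list(paste0("i", 1:8), NULL))
  calls[2, ] <- calls[1, ]                      # duplicate individual
  G <- genotype_matrix(calls, setNames(rep(1, 8), rownames(calls)))
  res <- pcoa_genotypes(G)
  D_in <- as.matrix(dist(calls))
  D_out <- as.matrix(dist(res$coords))
  expect_equal(unname(D_in), unname(D_out), tolerance = 1e-8)
  expect_lt(max(abs(res$coords[1, ] - res$coords[2, ])), 1e-8)
  expect_true(all(diff(res$eig[res$eig > 1e-8]) <= 1e-8))

  # mean imputation: a missing call sits at the locus mean
  calls_na <- calls
  calls_na[3, 1] <- NA
  M <- spreadgen:::.impute_mean(calls_na)
  expect_equal(unname(M[3, 1]), mean(calls_na[-3, 1]))
})

test_that("Mantel statistic and permutation null behave correctly", {
  set.seed(11)
  xy <- matrix(runif(12), 6, 2)
  D1 <- as.matrix(dist(xy))
  expect_equal(mantel_test(D1, D1, n_perm = 9)$r, 1)
  expect_equal(mantel_test(D1, 3 * D1 + 2, n_perm = 9)$r, 1)
  expect_error(mantel_test(D1, matrix(1, 6, 6)), "constant")

  # permutation p approximates the exhaustive null on a small case
  set.seed(12)
  D2 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  obs <- cor(D1[upper.tri(D1)], D2[upper.tri(D2)])
  perms <- spreadgen:::.permutations(6)
  r_null <- apply(perms, 1, function(pm)
    cor(D1[upper.tri(D1)], D2[pm, pm][upper.tri(D2)]))
  p_exact <- mean(r_null >= obs - 1e-15)
  p_mc <- mantel_test(D1, D2, n_perm = 999, seed = 1)$p
  expect_lt(abs(p_mc - p_exact), 0.03)
})

test_that("Mantel r agrees with an independent implementation", {
  set.seed(19)
  D1 <- as.matrix(dist(matrix(runif(20), 10, 2)))
  D2 <- as.matrix(dist(matrix(runif(20), 10, 2)))
  ours <- mantel_test(D1, D2, n_perm = 999, seed = 2)
  ref <- vegan::mantel(D1, D2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("unbiased He tracks the generating heterozygosity", {
  set.seed(31)
  p_true <- 0.3
  he_hat <- replicate(300, {
    g <- rbinom(8, 2, p_true)
    n <- 8
    p <- mean(g) / 2
    2 * p * (1 - p) * 2 * n / (2 * n - 1)
  })
  expect_equal(mean(he_hat), 2 * p_true * (1 - p_true), tolerance = 0.02)
})
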