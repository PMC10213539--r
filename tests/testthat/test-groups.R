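grouped_pedigree <- function(n = 80, missing_rate = 0.15, seed = 3,
                             lines = 2) {
  ped <- random_pedigree(n, missing_rate = missing_rate, seed = seed)
  ped$line <- rep(paste0("L", seq_len(lines)), length.out = n)
  assign_groups(ped)
}

test_that("group assignment follows the line-of-origin rule", {
  ped <- random_pedigree(30, missing_rate = 0.3, seed = 1)
  ped$line <- rep(c("TL1", "TL2"), 15)
  pg <- assign_groups(ped, rule = c(TL1 = "TL1", TL2 = "TL2"))
  groups <- attr(pg, "groups")
  founder <- which(pg$sire == 0L & pg$dam == 0L & pg$line == "TL1")[1]
  expect_equal(groups[pg$sire_group[founder]], "TL1")
  expect_equal(groups[pg$dam_group[founder]], "TL1")
  known <- which(pg$sire > 0L & pg$dam > 0L)[1]
  expect_equal(pg$sire_group[known], 0L)
  half <- which(pg$sire > 0L & pg$dam == 0L & pg$line == "TL2")
  if (length(half)) expect_equal(groups[pg$dam_group[half[1]]], "TL2")
  expect_error(assign_groups(ped, rule = c(TL1 = "TL1")), "TL2")
})

test_that("Q matrix matches the recursion oracle and gene dropping", {
  pg <- grouped_pedigree(100, missing_rate = 0.2, seed = 5)
  Q <- build_Q(pg)
  expect_equal(unname(Q), unname(oracle_Q(pg)), tolerance = 1e-12)
  expect_equal(rowSums(Q), rep(1, nrow(Q)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # base cases
  f <- which(pg$sire == 0L & pg$dam == 0L)[1]
  e <- numeric(ncol(Q)); e[pg$sire_group[f]] <- 1
  expect_equal(unname(Q[f, ]), e)
  # Monte-Carlo gene-dropping agreement for a few late animals
  set.seed(99)
  for (code in c(60, 85, 100)) {
    expect_lt(max(abs(Q[code, ] - oracle_genedrop_Q(pg, code, 4e4))), 0.02)
  }
})

test_that("A* equals the Quaas-Pollak transformation of the dense oracle", {
  # single animal, both parents in one group
  one <- as_pedigree(data.frame(animal = "X", sire = "0", dam = "0",
                                line = "L1"))
  og <- assign_groups(one)
  expect_equal(as.matrix(build_Astar(og)),
               matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # the animal block always reproduces the plain A-inverse exactly
  # (founder slots route to groups, so only the bordering blocks differ)
  full <- random_pedigree(40, missing_rate = 0, seed = 2)
  full$line <- "L1"
  fg <- assign_groups(full)
  As <- as.matrix(build_Astar(fg))
  expect_equal(unname(As[1:40, 1:40]),
               unname(as.matrix(build_A_inverse(full))), tolerance = 1e-12)
  # dense oracle: A* == [Ai, -Ai Q; -Q' Ai, Q' Ai Q]
  pg <- grouped_pedigree(50, missing_rate = 0.25, seed = 8)
  Ai <- solve(oracle_tabular_A(pg$sire, pg$dam))
  Q <- oracle_Q(pg)
  ref <- rbind(cbind(Ai, -Ai %*% Q), cbind(-t(Q) %*% Ai, t(Q) %*% Ai %*% Q))
  expect_equal(as.matrix(build_Astar(pg)), ref, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("gamma estimation handles degenerate and symmetric inputs", {
  gmat <- function(g) matrix(as.numeric(g), nrow(g))
  ped <- random_pedigree(20, missing_rate = 0, seed = 4)
  ped$line <- rep(c("L1", "L2"), 10)
  ids <- ped$id
  # all-heterozygous dosages: every base frequency 0.5, Gamma = 0
  gs <- toy_genotypes(matrix(1, 20, 30), ids = ids)
  expect_equal(gmat(estimate_gamma(ped, gs)), matrix(0, 2, 2),
               tolerance = 1e-12)
  # two groups whose genotyped animals are copies of one another (and
  # equally unrelated): the whole Gamma collapses to a single value
  fped <- as_pedigree(data.frame(animal = sprintf("F%02d", 1:20),
                                 sire = "0", dam = "0",
                                 line = rep(c("L1", "L2"), each = 10)))
  set.seed(1)
  base <- matrix(rbinom(10 * 40, 2, 0.4), 10, 40)
  gam2 <- gmat(estimate_gamma(fped, toy_genotypes(rbind(base, base),
                                                  ids = fped$id)))
  expect_equal(gam2[1, 1], gam2[2, 2], tolerance = 1e-10)
  expect_equal(gam2[1, 2], gam2[1, 1], tolerance = 1e-10)
  # monomorphic-only input errors
  expect_error(estimate_gamma(ped, toy_genotypes(matrix(2, 20, 5), ids = ids)),
               "monomorphic")
})

test_that("gamma recovers the simulator's base-frequency covariance", {
  sim <- small_sim(61, m_wgs = 2000, m_chip = 400, genotyped_gens = 3)
  gam <- estimate_gamma(sim$ped, sim$geno_wgs)
  gt <- sim$truth$gamma_true
  expect_lt(norm(unclass(gam) - gt, "F") / norm(gt, "F"), 0.15)
  # shared-ancestor scenario: positive off-diagonals (ancestral overlap)
  expect_true(all(unclass(gam)[upper.tri(gam)] > 0))
})

test_that("metafounder relationships and their inverse are consistent", {
  # single metafounder with gamma = 0 contributes nothing
  one <- as_pedigree(data.frame(animal = "X", sire = "0", dam = "0",
                                line = "L1"))
  og <- assign_groups(one)
  AG <- build_AGamma(og, matrix(0))
  expect_equal(unname(AG), matrix(c(0, 0, 0, 1), 2))
  # random grouped pedigree, PD Gamma: inverse times dense tabular = I
  pg <- grouped_pedigree(60, missing_rate = 0.2, seed = 6)
  gamma <- matrix(c(0.9, 0.4, 0.4, 1.1), 2)
  si <- ifelse(pg$sire > 0, 2 + pg$sire, pg$sire_group)
  di <- ifelse(pg$dam > 0, 2 + pg$dam, pg$dam_group)
  AGo <- oracle_tabular_A_gamma(si, di, gamma)
  inv <- as.matrix(build_AGamma_inverse(pg, gamma))
  # package order: animals then metafounders; oracle: metafounders first
  n <- nrow(pg)
  perm <- c(2 + seq_len(n), 1:2)
  expect_lt(max(abs(inv %*% AGo[perm, perm] - diag(n + 2))), 1e-8)
  # A22(Gamma) is the genotyped submatrix of the augmented tabular matrix
  ids <- pg$id[c(10, 25, 40)]
  expect_equal(unname(build_A22_gamma(pg, gamma, ids)),
               unname(AGo[perm, perm][match(ids, pg$id), match(ids, pg$id)]),
               tolerance = 1e-12)
  expect_error(build_AGamma_inverse(pg, matrix(c(1, 2, 2, 1), 2)),
               "eigenvalue")
})

test_that("A22(Gamma) diagonal is compatible with 0.5-centered G", {
  sim <- small_sim(61, m_wgs = 2000, m_chip = 400, genotyped_gens = 3)
  gam <- estimate_gamma(sim$ped, sim$geno_wgs)
  pedg <- assign_groups(sim$ped)
  A22g <- build_A22_gamma(pedg, gam, sim$geno_wgs$ids)
  G05 <- build_G(sim$geno_wgs, freq = "half")
  expect_lt(abs(mean(diag(A22g)) - mean(diag(G05))), 0.05)
})
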