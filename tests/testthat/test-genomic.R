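test_that("QC applies every marker and animal filter", {
  # 10 markers over 20 animals; three constructed failures
  set.seed(3)
  n <- 20
  M <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  M[, 2] <- c(1, rep(0, n - 1))              # MAF 0.025 < default? no: 1/40
  M[, 2] <- c(rep(0, n))                      # monomorphic
  M[, 3] <- rep(1, n)                         # all-het: HW deviation 0.5
  M[1:3, 4] <- NA                             # call rate 17/20 = 0.85 < 0.90
  gs <- toy_genotypes(M)
  out <- qc_genotypes(gs)
  expect_equal(out$report$markers_kept, 7)
  expect_false(any(c("mk002", "mk003", "mk004") %in% out$geno$map$marker))
  expect_equal(out$report$markers_monomorphic, 1)
  expect_equal(out$report$markers_geno_freq, 1)
  expect_equal(out$report$markers_call_rate, 1)
  # MAF filter at the printed default threshold
  M2 <- matrix(rbinom(100 * 5, 2, 0.5), 100, 5)
  M2[, 1] <- c(1, rep(0, 99))                 # MAF 0.005 < 0.01
  out2 <- qc_genotypes(toy_genotypes(M2))
  expect_false("mk001" %in% out2$geno$map$marker)
  expect_equal(out2$report$markers_maf, 1)
  # animal with > 10% missing dropped
  M3 <- matrix(rbinom(30 * 20, 2, 0.5), 30, 20)
  M3[5, 1:5] <- NA                            # 25% missing
  out3 <- qc_genotypes(toy_genotypes(M3))
  expect_equal(out3$report$animals_missingness, 1)
  expect_false("id05" %in% out3$geno$ids)
})

test_that("QC drops animals with parent-progeny opposite-homozygote conflicts", {
  ped <- as_pedigree(data.frame(animal = c("P", "M", "K", "W"),
                                sire = c("0", "0", "P", "P"),
                                dam = c("0", "0", "M", "M")))
  set.seed(8)
  m <- 60
  gp <- rbinom(m, 2, 0.5)
  gm <- rbinom(m, 2, 0.5)
  gk <- ifelse(gp == 2, 0, 2)                # K conflicts with P everywhere
  gw <- round((gp + gm) / 2)                 # W roughly consistent
  gs <- toy_genotypes(rbind(gp, gm, gk, gw), ids = c("P", "M", "K", "W"))
  # marker filters neutralised (4 animals cannot support frequency filters)
  out <- qc_genotypes(gs, thresholds = list(maf = 0, geno_freq_dev = 1),
                      ped = ped)
  expect_false("K" %in% out$geno$ids)
  expect_true(all(c("P", "M") %in% out$geno$ids))
  expect_gte(out$report$animals_parent_conflict, 1)
})

test_that("allele frequencies are pooled mean dosage over two", {
  gs <- toy_genotypes(matrix(c(0, 1, 2), 3, 1))
  expect_equal(unname(allele_frequencies(gs)), 0.5)
  set.seed(4)
  M <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
  M[sample(length(M), 30)] <- NA
  brute <- apply(M, 2, function(z) sum(z, na.rm = TRUE) / (2 * sum(!is.na(z))))
  expect_equal(unname(allele_frequencies(toy_genotypes(M))), unname(brute))
})

test_that("G follows VanRaden method 1 in both centering modes", {
  gs <- toy_genotypes(matrix(c(0, 2, 2, 0), 2, 2))
  G <- build_G(gs)
  expect_equal(matrix(as.numeric(G), 2), matrix(c(2, -2, -2, 2), 2),
               tolerance = 1e-12)
  expect_equal(attr(G, "freq_mode"), "observed")
  # identical animals share rows and diagonal entries
  gs2 <- toy_genotypes(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0)))
  G2 <- build_G(gs2)
  expect_equal(G2[1, ], G2[2, ], ignore_attr = TRUE)
  expect_equal(G2[1, 1], G2[2, 2])
  # identity weights change nothing
  expect_equal(build_G(gs2, weights = rep(1, 4)), G2)
  # 0.5-centered mode is invariant to swapping allele labels
  M <- matrix(rbinom(30 * 15, 2, 0.3), 30, 15)
  g_a <- build_G(toy_genotypes(M), freq = "half")
  g_b <- build_G(toy_genotypes(2 - M), freq = "half")
  expect_equal(g_a, g_b, tolerance = 1e-12)
  # fixed markers cannot scale G
  expect_error(build_G(toy_genotypes(matrix(2, 4, 3))), "denominator")
})

test_that("observed-frequency G diagonal tracks pedigree inbreeding", {
  sim <- small_sim(71, n_lines = 1, genotyped_gens = 3)
  G <- build_G(sim$geno_chip)
  F <- compute_inbreeding(sim$ped)
  expect_lt(abs(mean(diag(G)) - (1 + mean(F[sim$geno_chip$ids]))), 0.05)
})

test_that("blending restores rank and leaves fixed points alone", {
  sim <- small_sim(71, n_lines = 1, genotyped_gens = 3)
  ids <- sim$geno_chip$ids[1:30]
  gs <- subset_genotypes(sim$geno_chip, ids = ids,
                         markers = sim$geno_chip$map$marker[1:20])
  G <- build_G(gs)                       # rank-deficient: 20 markers
  A22 <- build_A22(sim$ped, ids)
  expect_equal(blend_G(G, A22, beta = 0), G)
  A22f <- A22; attr(A22f, "freq_mode") <- "observed"
  bfix <- blend_G(A22f, A22, beta = 0.05)
  expect_equal(matrix(as.numeric(bfix), nrow(bfix)),
               matrix(as.numeric(A22), nrow(A22)), tolerance = 1e-12)
  Gb <- blend_G(G, A22, beta = 0.05)
  evG <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  evB <- min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(evB, evG)
  expect_gt(evB, 0)
  expect_error(blend_G(G, A22[1:5, 1:5]), "dimension")
})

test_that("core selection follows the eigenvalue spectrum and line shares", {
  sim <- small_sim(71, n_lines = 1, genotyped_gens = 3)
  ids <- sim$geno_chip$ids[1:60]
  gs <- subset_genotypes(sim$geno_chip, ids = ids)
  A22 <- build_A22(sim$ped, ids)
  Gb <- blend_G(build_G(gs), A22, 0.05)
  # threshold 1 on a full-rank matrix keeps everyone
  p_all <- select_core(Gb, rep("L1", 60), var_threshold = 1)
  expect_equal(p_all$n_core, 60)
  # two distinct genotype vectors replicated: rank-2 G (0.5-centered so the
  # two patterns stay independent), so 2 core animals at any high threshold
  M <- rbind(matrix(rep(c(0, 0, 2, 2, 1), 6), 6, 5, byrow = TRUE),
             matrix(rep(c(0, 2, 0, 2, 1), 6), 6, 5, byrow = TRUE))
  Gr <- build_G(toy_genotypes(M), freq = "half")
  pr <- select_core(Gr, rep(c("A", "B"), each = 6), var_threshold = 0.98)
  expect_equal(pr$n_core, 2)
  # line proportions respected after largest-remainder rounding
  lines <- rep(c("A", "B", "C"), each = 20)
  props <- c(A = 1, B = 1, C = 1) / 3
  p3 <- select_core(Gb, lines, var_threshold = 0.98,
                    proportions = props, seed = 4)
  tab <- table(lines[match(p3$core, ids)])
  expect_equal(sum(tab), p3$n_core)
  expect_true(all(abs(tab - p3$n_core * props) < 1))
  # reproducible under the seed
  p3b <- select_core(Gb, lines, var_threshold = 0.98,
                     proportions = props, seed = 4)
  expect_identical(p3$core, p3b$core)
  expect_error(select_core(Gb, lines, var_threshold = 1.2), "var_threshold")
})

test_that("APY inverse is exact for all-core and consistent for duplicates", {
  sim <- small_sim(71, n_lines = 1, genotyped_gens = 3)
  ids <- sim$geno_chip$ids[1:80]
  gs <- subset_genotypes(sim$geno_chip, ids = ids)
  Gb <- blend_G(build_G(gs), build_A22(sim$ped, ids), 0.05)
  all_core <- structure(list(core = ids, noncore = character(0),
                             n_core = 80), class = "ml_apy_partition")
  expect_lt(max(abs(apy_inverse(Gb, all_core) - sym_inverse(Gb))), 1e-10)
  # a noncore animal whose G row copies a core animal's gets its prediction:
  # solve a marker-free GBLUP with the APY operator and compare solutions
  core <- ids[1:30]; noncore <- ids[31:80]
  G2 <- Gb
  dup <- noncore[1]; src <- core[3]
  G2[dup, ] <- G2[src, ]; G2[, dup] <- G2[, src]
  G2[dup, dup] <- G2[src, src] + 0.01   # tiny own-variance keeps APY defined
  part <- structure(list(core = core, noncore = noncore, n_core = 30),
                    class = "ml_apy_partition")
  Gi <- apy_inverse(G2, part)
  # records for everyone except the two copies
  has_y <- setdiff(ids, c(dup, src))
  set.seed(5)
  y <- rnorm(length(has_y))
  Z <- matrix(0, length(has_y), length(ids),
              dimnames = list(NULL, ids))
  Z[cbind(seq_along(has_y), match(has_y, ids))] <- 1
  sol <- solve(crossprod(Z) + Gi * 2, crossprod(Z, y))
  expect_equal(unname(sol[dup, 1]), unname(sol[src, 1]), tolerance = 1e-8)
})

test_that("dosage PCA separates diverged lines and handles degeneracy", {
  sim <- small_sim(72, n_lines = 2, genotyped_gens = 3, n_founders = 120)
  pc <- genotype_pca(sim$geno_chip, k = 2)
  ln <- sim$ped$line[match(sim$geno_chip$ids, sim$ped$id)]
  r1 <- range(pc$scores[ln == "TL1", 1])
  r2 <- range(pc$scores[ln == "TL2", 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # zero overlap on PC1
  expect_lte(sum(pc$var_share), 1)
  # identical animals: zero variance on every component
  same <- toy_genotypes(matrix(rep(c(0, 1, 2, 1), each = 5), 5, 4))
  pc0 <- genotype_pca(same, k = 2)
  expect_equal(unname(pc0$scores), matrix(0, 5, 2))
  expect_equal(pc0$var_share, c(0, 0))
  expect_error(genotype_pca(same, k = 10), "rank")
})
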