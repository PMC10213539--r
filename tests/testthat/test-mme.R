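test_that("assembled equations match a hand-built animal model", {
  # 5 animals: 2 founders, 3 offspring; overall mean as the only fixed
  # effect; single trait; no litter effect
  ped <- as_pedigree(data.frame(
    animal = c("S", "D", "A", "B", "C"),
    sire = c("0", "0", "S", "S", "A"),
    dam = c("0", "0", "D", "D", "B")))
  pheno <- data.frame(animal = c("A", "B", "C"),
                      y = c(1.2, 0.4, 2.0), mu = 1)
  spec <- model_spec("y", list(y = ~1), G0 = matrix(0.4), R0 = matrix(0.6),
                     L0 = NULL)
  hinv <- build_hinv("standard", build_A_inverse(ped))
  sys <- assemble_mme(spec, pheno, hinv)
  # hand assembly
  X <- matrix(1, 3, 1)
  Z <- matrix(0, 3, 5); Z[cbind(1:3, 3:5)] <- 1
  Ai <- solve(oracle_tabular_A(ped$sire, ped$dam))
  C_hand <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                  cbind(crossprod(Z, X), crossprod(Z))) / 0.6
  C_hand[2:6, 2:6] <- C_hand[2:6, 2:6] + Ai / 0.4
  rhs_hand <- c(crossprod(X, pheno$y), crossprod(Z, pheno$y)) / 0.6
  expect_equal(as.matrix(sys$C), C_hand, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(sys$rhs, rhs_hand, tolerance = 1e-12)
  sol_hand <- solve(C_hand, rhs_hand)
  res <- solve_mme(sys)
  expect_equal(unname(res$u$y), sol_hand[2:6], tolerance = 1e-10)
  # an animal with no phenotype contributes only through relationships
  expect_true(all(c("S", "D") %in% names(res$u$y)))
})

test_that("ssGBLUP with G equal to A22 reproduces pedigree BLUP", {
  sim <- small_sim(82)
  spec <- sim_model_spec(sim)
  blup <- ssgblup(sim$ped, NULL, sim$pheno, spec)
  A22 <- build_A22(sim$ped, sim$geno_chip$ids)
  GA <- A22; attr(GA, "freq_mode") <- "observed"
  hinv <- build_hinv("standard", build_A_inverse(sim$ped),
                     ginv = sym_inverse(blend_G(GA, A22, 0.05)),
                     a22inv = {
                       x <- sym_inverse(A22); attr(x, "freq_mode") <- NULL; x
                     })
  ss <- solve_mme(assemble_mme(spec, sim$pheno, hinv))
  expect_lt(max(abs(ss$u$trait - blup$u$trait)), 1e-8)
})

test_that("direct and conjugate-gradient solvers agree", {
  sim <- small_sim(82)
  spec <- sim_model_spec(sim)
  hinv <- build_hinv("standard", build_A_inverse(sim$ped))
  sys <- assemble_mme(spec, sim$pheno, hinv)
  d <- solve_mme(sys, method = "direct")
  p <- solve_mme(sys, method = "pcg", tol = 1e-12, maxit = 20000)
  expect_lt(max(abs(d$u$trait - p$u$trait)), 1e-6)
})

test_that("solutions are invariant to record order and CG level shifts", {
  sim <- small_sim(82)
  spec <- sim_model_spec(sim)
  hinv <- build_hinv("standard", build_A_inverse(sim$ped))
  base <- solve_mme(assemble_mme(spec, sim$pheno, hinv))
  # permuting phenotype rows
  set.seed(3)
  perm <- sim$pheno[sample(nrow(sim$pheno)), ]
  res_p <- solve_mme(assemble_mme(spec, perm, hinv))
  expect_equal(res_p$u$trait, base$u$trait, tolerance = 1e-8)
  # adding a constant to one contemporary group's phenotypes
  shifted <- sim$pheno
  cg1 <- shifted$cg == shifted$cg[1]
  shifted$trait[cg1] <- shifted$trait[cg1] + 5
  res_s <- solve_mme(assemble_mme(spec, shifted, hinv))
  expect_lt(max(abs(res_s$u$trait - base$u$trait)), 1e-7)
})

test_that("GEBV are equivariant to consistent unit rescaling", {
  sim <- small_sim(82)
  cmp <- sim$truth$components
  mk_spec <- function(s2) model_spec(
    "trait", list(trait = ~cg), G0 = matrix(cmp$sigma2_u * s2),
    R0 = matrix(cmp$sigma2_e * s2), L0 = matrix(cmp$sigma2_c * s2))
  hinv <- build_hinv("standard", build_A_inverse(sim$ped))
  r1 <- solve_mme(assemble_mme(mk_spec(1), sim$pheno, hinv))
  ph2 <- sim$pheno; ph2$trait <- ph2$trait * 10
  r2 <- solve_mme(assemble_mme(mk_spec(100), ph2, hinv))
  expect_equal(r2$u$trait, 10 * r1$u$trait, tolerance = 1e-7)
})

test_that("multi-trait equations reduce to single-trait runs when disjoint", {
  sim <- small_sim(82)
  cmp <- sim$truth$components
  ph <- sim$pheno
  # second trait: an independent trait recorded on a disjoint animal set
  set.seed(9)
  half <- seq_len(nrow(ph)) %% 2 == 0
  ph$t2 <- NA_real_
  ph$t2[half] <- rnorm(sum(half), 0, 1)
  ph$trait[half] <- NA
  spec2 <- model_spec(c("trait", "t2"),
                      list(trait = ~cg, t2 = ~cg),
                      G0 = diag(c(cmp$sigma2_u, 0.25)),
                      R0 = diag(c(cmp$sigma2_e, 0.55)),
                      L0 = diag(c(cmp$sigma2_c, 0.15)))
  hinv <- build_hinv("standard", build_A_inverse(sim$ped))
  joint <- solve_mme(assemble_mme(spec2, ph, hinv))
  s1 <- model_spec("trait", list(trait = ~cg), G0 = matrix(cmp$sigma2_u),
                   R0 = matrix(cmp$sigma2_e), L0 = matrix(cmp$sigma2_c))
  single <- solve_mme(assemble_mme(s1, ph[!half, ], hinv))
  expect_equal(joint$u$trait, single$u$trait, tolerance = 1e-8)
})

test_that("UPG GEBV reconstruct group expectations and track base means", {
  # two diverged lines with no contemporary-group effects; a shared
  # generation fixed effect leaves the base difference identifiable
  sim <- small_sim(85, n_lines = 2, drift = 0.2, cg_sd = 0,
                   missing_parent_rate = 0.05, n_founders = 80,
                   genotyped_fraction = 1)
  sim$pheno$gen_f <- factor(sim$pheno$gen)
  cmp <- sim$truth$components
  spec <- model_spec("trait", list(trait = ~gen_f),
                     G0 = matrix(cmp$sigma2_u), R0 = matrix(cmp$sigma2_e),
                     L0 = matrix(cmp$sigma2_c))
  fit <- ssgblup(sim$ped, sim$geno_chip, sim$pheno, spec, flavor = "upg1")
  # GEBV = Qg + u
  pedg <- assign_groups(sim$ped)
  Q <- build_Q(pedg)
  gb <- setNames(fit$gebv$gebv, fit$gebv$animal)
  manual <- fit$u$trait + as.numeric(Q %*% fit$g$trait)
  expect_equal(unname(gb[names(fit$u$trait)]), unname(manual),
               tolerance = 1e-10)
  tr <- sim$truth$animals
  true_diff <- mean(tr$tbv[tr$line == "TL1"]) -
    mean(tr$tbv[tr$line == "TL2"])
  est_diff <- mean(gb[tr$animal[tr$line == "TL1"]]) -
    mean(gb[tr$animal[tr$line == "TL2"]])
  expect_lt(abs(est_diff - true_diff), 0.5 * sqrt(cmp$sigma2_u))
  expect_equal(sign(est_diff), sign(true_diff))
})

test_that("UPG1 and UPG2 are distinct models sharing the A* backbone", {
  # at G = A22 the UPG1 operator collapses to A* while UPG2 retains its
  # genomic-total terms; the two flavors are different models whose GEBV
  # agree only loosely when base divergence is strong
  sim <- small_sim(85, n_lines = 2, drift = 0.2, cg_sd = 0,
                   missing_parent_rate = 0.05, n_founders = 80,
                   genotyped_fraction = 1)
  spec <- sim_model_spec(sim)
  pedg <- assign_groups(sim$ped)
  Q <- build_Q(pedg)
  A22 <- build_A22(sim$ped, sim$geno_chip$ids)
  GA <- A22; attr(GA, "freq_mode") <- "observed"
  ast <- build_Astar(pedg)
  gi <- sym_inverse(GA)
  ai <- sym_inverse(A22); attr(ai, "freq_mode") <- NULL
  h1 <- build_hinv("upg1", ast, gi, ai, Q = Q, n_groups = ncol(Q))
  expect_lt(max(abs(h1$M - ast)), 1e-8)   # correction vanishes
  h2 <- build_hinv("upg2", ast, gi, ai, Q = Q, n_groups = ncol(Q))
  expect_gt(max(abs(h2$M - ast)), 1e-4)   # genomic-total terms remain
  r1 <- solve_mme(assemble_mme(spec, sim$pheno, h1, Q = Q))
  r2 <- solve_mme(assemble_mme(spec, sim$pheno, h2, Q = Q))
  expect_true(all(is.finite(r1$gebv$gebv)), all(is.finite(r2$gebv$gebv)))
  expect_gt(cor(r1$gebv$gebv, r2$gebv$gebv), 0.5)
})

test_that("non-positive-definite variance components are rejected", {
  expect_error(model_spec("y", list(y = ~1), G0 = matrix(-1),
                          R0 = matrix(1)), "positive definite")
  expect_error(model_spec(c("a", "b"), list(a = ~1, b = ~1),
                          G0 = matrix(c(1, 2, 2, 1), 2),
                          R0 = diag(2)), "positive definite")
})
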