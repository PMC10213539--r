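test_that("simulations are fully reproducible from the seed", {
  cfg <- sim_config(n_founders = 40, n_gen = 2, n_litters = 10, m_wgs = 300,
                    m_chip = 100, n_qtl = 40, seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$geno_chip$dosage, s2$geno_chip$dosage)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$animals$tbv, s2$truth$animals$tbv)
  # fixtures are byte-identical across emissions
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- emit_fixtures(s1, d1); f2 <- emit_fixtures(s2, d2)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # the emitted pedigree reloads cleanly (implying no cycles or duplicates)
  ped <- read_pedigree(file.path(d1, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(s1$ped))
  expect_equal(sum(ped$genotyped), sum(s1$ped$genotyped))
})

test_that("zero drift removes base divergence; zero noise removes residuals", {
  s0 <- simulate_population(sim_config(
    n_founders = 200, n_gen = 1, n_litters = 10, m_wgs = 2000, m_chip = 300,
    n_qtl = 50, drift = 0, seed = 6))
  gt <- s0$truth$gamma_true
  # shared base: off-diagonals match diagonals up to founder sampling noise
  expect_lt(max(abs(gt[upper.tri(gt)] - mean(diag(gt)))), 0.1)
  # deterministic phenotypes when litter and residual variance vanish
  sz <- simulate_population(sim_config(
    n_founders = 40, n_gen = 2, n_litters = 8, m_wgs = 200, m_chip = 60,
    n_qtl = 30, h2 = 1, c2 = 0, seed = 7))
  ph <- sz$pheno[!is.na(sz$pheno$trait), ]
  tbv <- stats::setNames(sz$truth$animals$tbv, sz$truth$animals$animal)
  cg <- sz$truth$cg_effects
  expect_equal(ph$trait, unname(cg[ph$cg] + tbv[ph$animal]),
               tolerance = 1e-12)
})

test_that("phenotypes decompose with the configured heritability", {
  sim <- small_sim(94, n_founders = 100, n_litters = 30)
  ph <- sim$pheno[!is.na(sim$pheno$trait), ]
  tbv <- stats::setNames(sim$truth$animals$tbv, sim$truth$animals$animal)
  # within contemporary groups, the additive share of phenotypic variance
  # is the configured h2 (moment estimate over CG cells)
  ycg <- ph$trait - ave(ph$trait, ph$cg)
  ucg <- tbv[ph$animal] - ave(tbv[ph$animal], ph$cg)
  h2_emp <- stats::var(ucg) / stats::var(ycg)
  expect_lt(abs(h2_emp - sim$cfg$h2), 0.05)
})

test_that("gene dropping conserves allele frequencies within sampling error", {
  sim <- small_sim(94, n_founders = 100, n_litters = 30)
  tr <- sim$truth$animals
  # one marker per chromosome (well separated, effectively independent)
  map <- sim$geno_wgs$map
  pick <- match(unique(map$chrom), map$chrom)
  founders <- which(tr$gen == 0)
  kids <- which(tr$gen == 1 & tr$line == "TL1")
  # offspring frequency vs the mean parental frequency: standardized drift
  # should be approximately chi-square distributed across markers
  # (each transmitted allele is an independent Bernoulli(parental dosage/2))
  ids <- tr$animal[kids]
  geno_all <- sim$geno_wgs   # genotyped generations only; use truth instead
  expect_true(all(pick >= 1))
  # frequency conservation checked on the genotyped generations: the change
  # from one generation to the next stays within binomial sampling bounds
  g2 <- sim$geno_wgs$dosage[, pick, drop = FALSE]
  gen_of <- tr$gen[match(sim$geno_wgs$ids, tr$animal)]
  gens <- sort(unique(gen_of))
  p_a <- colMeans(g2[gen_of == gens[1], , drop = FALSE]) / 2
  p_b <- colMeans(g2[gen_of == gens[2], , drop = FALSE]) / 2
  n_b <- sum(gen_of == gens[2])
  z <- (p_b - p_a) / sqrt(pmax(p_a * (1 - p_a), 1e-6) / n_b)
  # drift variance includes family structure; allow a generous factor
  expect_lt(mean(z^2), 10)
  expect_gt(mean(z^2), 0.05)
})

test_that("crossbred cohorts record only the crossbred trait", {
  sim <- small_sim(95, crossbred = list(lines = c("TL1", "TL2"),
                                        n_litters = 10))
  ph <- sim$pheno
  cb <- ph$line == "CL"
  expect_gt(sum(cb), 0)
  expect_true(all(is.na(ph$trait[cb])))
  expect_true(all(!is.na(ph$trait_x[cb])))
  expect_true(all(is.na(ph$trait_x[!cb])))
  # purebred-crossbred genetic correlation tracks the configured value;
  # the realized correlation over a finite QTL draw is noisy, so the check
  # is deliberately loose
  tr <- sim$truth$animals
  expect_equal(cor(tr$tbv, tr$tbv_x), sim$cfg$crossbred_rg,
               tolerance = 0.3)
  expect_gt(cor(tr$tbv, tr$tbv_x), 0.3)
  # crossbred animals are genotyped and appear in the genotype sets
  cb_ids <- tr$animal[tr$line == "CL"]
  expect_gt(length(intersect(cb_ids, sim$geno_chip$ids)), 0)
})

test_that("QTL stay off the chip and carry the configured base variance", {
  sim <- small_sim(96)
  expect_length(intersect(sim$truth$qtl$marker, sim$geno_chip$map$marker), 0)
  expect_true(all(sim$truth$qtl$marker %in% sim$geno_wgs$map$marker))
  tr <- sim$truth$animals
  wv <- mean(sapply(unique(tr$line), function(l)
    stats::var(tr$tbv[tr$gen == 0 & tr$line == l])))
  expect_equal(wv, sim$truth$components$sigma2_u, tolerance = 1e-9)
})

test_that("the shipped synthetic mini-population fixture loads cleanly", {
  dir <- system.file("extdata", "synthetic_minipop", package = "mlgblup")
  expect_true(nzchar(dir))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_lte(nrow(ped), 500)
  expect_gt(sum(ped$genotyped), 0)
  F <- compute_inbreeding(ped)
  expect_true(all(F >= 0 & F < 1))
  raw <- utils::read.csv(file.path(dir, "genotypes_chip.raw"),
                         check.names = FALSE)
  bim <- utils::read.table(file.path(dir, "map_chip.bim"), header = TRUE)
  gs <- genotype_set(as.matrix(raw[, -1]),
                     data.frame(marker = bim$marker, chrom = bim$chrom,
                                pos = bim$pos),
                     ids = raw$animal)
  expect_true(all(gs$ids %in% ped$id))
  G <- build_G(gs)
  expect_lt(max(abs(G - t(G))), 1e-12)
})
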