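#' Configuration for the multi-line population simulator
#'
#' Defaults describe the structure the multi-line analyses assume: three
#' purebred lines diverged from a shared ancestral population (line-specific
#' base allele frequencies under a Balding-Nichols drift model), discrete
#' generations of litters, an optional crossbred cohort, chip- and
#' WGS-density marker sets with QTL hidden from the chip, and phenotypes
#' built as fixed contemporary-group effects plus litter, additive and
#' residual components.
#'
#' @param n_lines number of purebred lines.
#' @param line_names line labels.
#' @param n_founders base animals per line (half male, half female).
#' @param n_gen number of discrete offspring generations.
#' @param n_litters litters per line per generation.
#' @param litter_size mean litter size (Poisson, minimum 1).
#' @param n_sires sires sampled per line per generation.
#' @param drift Balding-Nichols drift (Fst-like) of each line's base allele
#'   frequencies from the shared ancestral frequencies, in [0, 1).
#' @param ancestral_freq_range range of the uniform ancestral frequency draw.
#' @param m_wgs,m_chip WGS- and chip-density marker counts (chip markers are
#'   a subset of WGS markers, excluding QTL).
#' @param n_chr number of chromosomes the markers are spread over.
#' @param marker_spacing_bp spacing between adjacent markers, in bp.
#' @param cm_per_mb genetic map rate.  The simulated genome is physically
#'   compressed relative to a real one, so the default rate is scaled up to
#'   preserve realistic per-chromosome map lengths (about 0.75 Morgan per
#'   chromosome under the defaults).
#' @param ld_range_bp range of base-population linkage disequilibrium:
#'   founder haplotypes are drawn from a Gaussian-copula process whose
#'   latent correlation between two positions d bp apart is
#'   `exp(-d / ld_range_bp)`.  The default emulates the long-range LD of
#'   closed nucleus livestock lines, under which a chip-density panel
#'   captures most of the additive variance of common causal variants.
#' @param n_qtl number of QTL (random WGS markers, off-chip).
#' @param qtl_min_maf minimum pooled founder minor-allele frequency for a
#'   marker to be eligible as a QTL (complex production traits are driven
#'   by common variation; near-fixed causal variants are untaggable and
#'   contribute negligible variance).
#' @param h2 narrow-sense heritability of the purebred trait.
#' @param c2 litter-effect share of phenotypic variance.
#' @param sigma2_p phenotypic variance.
#' @param cg_sd SD of contemporary-group (line-by-generation) fixed effects.
#' @param missing_parent_rate probability that a non-founder's recorded
#'   parent slot is masked as unknown (the true parent still transmits
#'   genotypes).
#' @param genotyped_gens the last `genotyped_gens` generations are genotyped.
#' @param genotyped_fraction fraction of animals genotyped within those
#'   generations (genotyping is selective in practice: validation cohorts
#'   are a subset of their contemporary groups, whose remaining members
#'   keep phenotypes in a reduced run).
#' @param crossbred `NULL`, or a list with `lines` (two purebred line
#'   labels), `n_litters` and optional `name` (default "CL"): a crossbred
#'   cohort produced in the final generation, recorded only for the
#'   crossbred trait.
#' @param crossbred_rg genetic correlation between the purebred and
#'   crossbred expressions of the trait.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return An `ml_sim_config` list.
#' @export
sim_config <- function(n_lines = 3, line_names = paste0("TL", seq_len(n_lines)),
                       n_founders = 200, n_gen = 4, n_litters = 60,
                       litter_size = 7.5, n_sires = 25, drift = 0.1,
                       ancestral_freq_range = c(0.05, 0.95),
                       m_wgs = 5000, m_chip = 1000, n_chr = 10,
                       marker_spacing_bp = 15000, cm_per_mb = 10,
                       ld_range_bp = 1e6, n_qtl = 100, qtl_min_maf = 0.1,
                       h2 = 0.3, c2 = 0.1, sigma2_p = 1, cg_sd = 0.5,
                       missing_parent_rate = 0.03, genotyped_gens = 2,
                       genotyped_fraction = 0.6,
                       crossbred = NULL, crossbred_rg = 0.7, seed = 1L) {
  stopifnot(drift >= 0, drift < 1, m_chip + n_qtl <= m_wgs,
            h2 > 0, c2 >= 0, h2 + c2 <= 1, n_founders %% 2 == 0)
  if (!is.null(crossbred)) {
    stopifnot(length(crossbred$lines) == 2, all(crossbred$lines %in% line_names))
    if (is.null(crossbred$name)) crossbred$name <- "CL"
    if (is.null(crossbred$n_litters)) crossbred$n_litters <- n_litters
  }
  structure(as.list(environment()), class = "ml_sim_config")
}

#' Simulate a multi-line population
#'
#' Gene-drops founder haplotypes (drawn from line-specific base frequencies)
#' through a litter-structured multi-generation pedigree, masks a fraction of
#' recorded parents, and generates phenotypes
#' `y = contemporary group + litter + additive + residual` with the
#' configured variance components.  True breeding values are sums of QTL
#' residual components.  Base linkage disequilibrium comes from the
#' copula haplotype process and decays with distance; transmission follows
#' a Haldane crossover model along each chromosome.
#'
#' @param cfg an [sim_config()].
#' @return List of class `ml_simulation`:
#'   `ped` (an `ml_pedigree` with recorded/masked parents),
#'   `geno_chip`, `geno_wgs` (genotyped animals only),
#'   `pheno` (animal, line, generation, cg, litter, trait columns),
#'   `truth` (true parents, TBV per trait, QTL effects, per-line base
#'   frequencies, the implied true Gamma, variance components), and `cfg`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "ml_sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m_wgs
  p_anc <- runif(m, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  nl <- cfg$n_lines
  base_freq <- matrix(0, nl, m, dimnames = list(cfg$line_names, NULL))
  for (l in seq_len(nl)) {
    base_freq[l, ] <- if (cfg$drift == 0) p_anc else {
      F <- cfg$drift
      stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
  }

  # ---- pedigree construction (true parents) ----
  rows <- list()
  add_rows <- function(id, sire, dam, line, gen, sex, litter) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, line = line, gen = gen, sex = sex,
      litter = litter, stringsAsFactors = FALSE)
  }
  for (l in seq_len(nl)) {
    ln <- cfg$line_names[l]
    nf <- cfg$n_founders
    add_rows(sprintf("%s_G0_%03d", ln, seq_len(nf)), NA, NA, ln, 0L,
             rep(c("M", "F"), nf / 2), NA)
    for (t in seq_len(cfg$n_gen)) {
      prev <- rows[[length(rows)]]
      prev <- prev[prev$line == ln & prev$gen == t - 1L, ]
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      sires <- sample(males, min(cfg$n_sires, length(males)))
      dams <- sample(females, min(cfg$n_litters, length(females)))
      kid <- 0L
      ids <- sire_v <- dam_v <- sex_v <- lit_v <- character(0)
      for (j in seq_along(dams)) {
        ls <- max(1L, rpois(1, cfg$litter_size))
        sire_j <- sample(sires, 1)
        kid_ids <- sprintf("%s_G%d_%04d", ln, t, kid + seq_len(ls))
        kid <- kid + ls
        ids <- c(ids, kid_ids)
        sire_v <- c(sire_v, rep(sire_j, ls))
        dam_v <- c(dam_v, rep(dams[j], ls))
        sex_v <- c(sex_v, sample(c("M", "F"), ls, replace = TRUE))
        lit_v <- c(lit_v, rep(sprintf("%s_G%d_L%02d", ln, t, j), ls))
      }
      add_rows(ids, sire_v, dam_v, ln, t, sex_v, lit_v)
    }
  }
  if (!is.null(cfg$crossbred)) {
    cb <- cfg$crossbred
    t <- cfg$n_gen
    pool <- do.call(rbind, rows)
    sires <- pool$id[pool$line == cb$lines[1] & pool$gen == t - 1L &
                       pool$sex == "M"]
    dams <- pool$id[pool$line == cb$lines[2] & pool$gen == t - 1L &
                      pool$sex == "F"]
    dams <- sample(dams, min(cb$n_litters, length(dams)))
    ids <- sire_v <- dam_v <- sex_v <- lit_v <- character(0)
    kid <- 0L
    for (j in seq_along(dams)) {
      ls <- max(1L, rpois(1, cfg$litter_size))
      sire_j <- sample(sires, 1)
      kid_ids <- sprintf("%s_G%d_%04d", cb$name, t, kid + seq_len(ls))
      kid <- kid + ls
      ids <- c(ids, kid_ids)
      sire_v <- c(sire_v, rep(sire_j, ls))
      dam_v <- c(dam_v, rep(dams[j], ls))
      sex_v <- c(sex_v, sample(c("M", "F"), ls, replace = TRUE))
      lit_v <- c(lit_v, rep(sprintf("%s_G%d_L%02d", cb$name, t, j), ls))
    }
    add_rows(ids, sire_v, dam_v, cb$name, t, sex_v, lit_v)
  }
  tped <- do.call(rbind, rows)
  n <- nrow(tped)

  # ---- marker map and genetic map ----
  per_chr <- ceiling(m / cfg$n_chr)
  chrom_idx <- 1 + (seq_len(m) - 1) %/% per_chr
  pos <- (((seq_len(m) - 1) %% per_chr) + 1) * cfg$marker_spacing_bp
  new_chr <- c(TRUE, diff(chrom_idx) != 0)
  gap <- c(0, diff(pos))
  # Haldane recombination fraction between adjacent markers; independent
  # chromosomes via r = 0.5 at chromosome starts
  morgan <- gap * cfg$cm_per_mb * 1e-8
  r_vec <- 0.5 * (1 - exp(-2 * morgan))
  r_vec[new_chr] <- 0.5
  phi_vec <- exp(-gap / cfg$ld_range_bp)
  phi_vec[new_chr] <- 0

  # ---- gene dropping over true parents ----
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  rownames(H1) <- rownames(H2) <- tped$id
  founders <- which(is.na(tped$sire))
  for (l in seq_len(nl)) {
    thresh <- stats::qnorm(base_freq[l, ])
    fl <- founders[tped$line[founders] == cfg$line_names[l]]
    H1[fl, ] <- copula_haps_cpp(thresh, phi_vec, length(fl))
    H2[fl, ] <- copula_haps_cpp(thresh, phi_vec, length(fl))
  }
  nonf <- which(!is.na(tped$sire))
  for (gen_t in sort(unique(tped$gen[nonf]))) {
    blk <- nonf[tped$gen[nonf] == gen_t]
    si <- match(tped$sire[blk], tped$id)
    di <- match(tped$dam[blk], tped$id)
    H1[blk, ] <- drop_gametes_cpp(H1, H2, si, r_vec)
    H2[blk, ] <- drop_gametes_cpp(H1, H2, di, r_vec)
  }

  # ---- QTL effects and true breeding values ----
  pool_freq <- colMeans(H1[founders, , drop = FALSE] +
                         H2[founders, , drop = FALSE]) / 2
  eligible <- which(pmin(pool_freq, 1 - pool_freq) >= cfg$qtl_min_maf)
  if (length(eligible) < cfg$n_qtl)
    stop("not enough polymorphic markers for the requested number of QTL")
  qtl <- sort(sample(eligible, cfg$n_qtl))
  a_raw <- rnorm(cfg$n_qtl)
  dos_q <- H1[, qtl, drop = FALSE] + H2[, qtl, drop = FALSE]
  sigma2_u <- cfg$h2 * cfg$sigma2_p
  # scale so the mean within-line founder TBV variance (the base genetic
  # variance the evaluation model assumes) equals sigma2_u
  within_var <- function(v) {
    mean(sapply(cfg$line_names, function(ln)
      var(v[founders[tped$line[founders] == ln]])))
  }
  tbv_raw <- as.numeric(dos_q %*% a_raw)
  sc <- sqrt(sigma2_u / within_var(tbv_raw))
  a <- a_raw * sc
  tbv <- tbv_raw * sc
  tbv <- tbv - mean(tbv[founders])
  has_x <- !is.null(cfg$crossbred)
  if (has_x) {
    a2_raw <- rnorm(cfg$n_qtl)
    tbv2_raw <- as.numeric(dos_q %*% a2_raw)
    sc2 <- sqrt(sigma2_u / within_var(tbv2_raw))
    rg <- cfg$crossbred_rg
    ax <- rg * a + sqrt(1 - rg^2) * a2_raw * sc2
    tbvx <- as.numeric(dos_q %*% ax)
    tbvx <- tbvx - mean(tbvx[founders])
  }

  # ---- recorded pedigree with masked parents ----
  rec_sire <- tped$sire; rec_dam <- tped$dam
  if (cfg$missing_parent_rate > 0) {
    mask_s <- !is.na(rec_sire) & runif(n) < cfg$missing_parent_rate
    mask_d <- !is.na(rec_dam) & runif(n) < cfg$missing_parent_rate
    rec_sire[mask_s] <- NA
    rec_dam[mask_d] <- NA
  }
  genotyped <- tped$gen > cfg$n_gen - cfg$genotyped_gens
  if (cfg$genotyped_fraction < 1) {
    drop_g <- genotyped & runif(n) > cfg$genotyped_fraction
    genotyped[drop_g] <- FALSE
  }
  ped <- as_pedigree(data.frame(
    animal = tped$id, sire = rec_sire, dam = rec_dam, line = tped$line,
    birth_year = 2000L + tped$gen, genotyped = as.integer(genotyped),
    stringsAsFactors = FALSE))

  # ---- phenotypes ----
  is_cb <- if (has_x) tped$line == cfg$crossbred$name else rep(FALSE, n)
  cg <- paste(tped$line, tped$gen, sep = "_G")
  cg_eff <- stats::setNames(rnorm(length(unique(cg)), 0, cfg$cg_sd),
                            unique(cg))
  sigma2_c <- cfg$c2 * cfg$sigma2_p
  sigma2_e <- (1 - cfg$h2 - cfg$c2) * cfg$sigma2_p
  litters <- unique(tped$litter[!is.na(tped$litter)])
  lit_eff <- stats::setNames(rnorm(length(litters), 0, sqrt(sigma2_c)),
                             litters)
  recorded <- tped$gen > 0L
  yp <- rep(NA_real_, n)
  sel <- recorded & !is_cb
  yp[sel] <- cg_eff[cg[sel]] + lit_eff[tped$litter[sel]] + tbv[sel] +
    rnorm(sum(sel), 0, sqrt(sigma2_e))
  pheno <- data.frame(animal = tped$id, line = tped$line, gen = tped$gen,
                      cg = cg, litter = tped$litter, trait = yp,
                      stringsAsFactors = FALSE)
  if (has_x) {
    yx <- rep(NA_real_, n)
    selx <- recorded & is_cb
    yx[selx] <- cg_eff[cg[selx]] + lit_eff[tped$litter[selx]] + tbvx[selx] +
      rnorm(sum(selx), 0, sqrt(sigma2_e))
    pheno$trait_x <- yx
  }
  pheno <- pheno[recorded, , drop = FALSE]
  rownames(pheno) <- NULL

  # ---- genotype sets ----
  gidx <- which(genotyped)
  chip_pool <- setdiff(seq_len(m), qtl)
  chip <- sort(sample(chip_pool, cfg$m_chip))
  map <- data.frame(
    marker = sprintf("snp%05d", seq_len(m)),
    chrom = sprintf("chr%02d", chrom_idx),
    pos = pos,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  dosage <- H1[gidx, , drop = FALSE] + H2[gidx, , drop = FALSE]
  geno_wgs <- genotype_set(dosage, map, ids = tped$id[gidx], panel = "WGS")
  geno_chip <- genotype_set(dosage[, chip, drop = FALSE],
                            map[chip, , drop = FALSE],
                            ids = tped$id[gidx], panel = "Chip")

  # realized founder allele frequencies per line define the true base and
  # hence the true Gamma (what the GLS estimator targets)
  founder_freq <- t(sapply(cfg$line_names, function(ln) {
    fl <- founders[tped$line[founders] == ln]
    colMeans(H1[fl, , drop = FALSE] + H2[fl, , drop = FALSE]) / 2
  }))
  dev <- founder_freq - 0.5
  gamma_true <- 8 * tcrossprod(dev) / m

  truth <- list(
    animals = data.frame(animal = tped$id, line = tped$line, gen = tped$gen,
                         sex = tped$sex, litter = tped$litter,
                         sire_true = tped$sire, dam_true = tped$dam,
                         tbv = tbv, stringsAsFactors = FALSE),
    qtl = data.frame(marker = map$marker[qtl], index = qtl, effect = a,
                     stringsAsFactors = FALSE),
    base_freq = base_freq,
    founder_freq = founder_freq,
    gamma_true = gamma_true,
    components = list(sigma2_u = sigma2_u, sigma2_c = sigma2_c,
                      sigma2_e = sigma2_e, h2 = cfg$h2, c2 = cfg$c2),
    cg_effects = cg_eff)
  if (has_x) {
    truth$animals$tbv_x <- tbvx
    truth$qtl$effect_x <- ax
    truth$components$rg <- cfg$crossbred_rg
  }
  structure(list(ped = ped, geno_chip = geno_chip, geno_wgs = geno_wgs,
                 pheno = pheno, truth = truth, cfg = cfg),
            class = "ml_simulation")
}

#' @exportS3Method base::print
print.ml_simulation <- function(x, ...) {
  cat("ml_simulation:", nrow(x$ped), "animals in",
      length(unique(x$ped$line)), "lines;", sum(x$ped$genotyped),
      "genotyped;", ncol(x$geno_wgs$dosage), "WGS /",
      ncol(x$geno_chip$dosage), "chip markers\n")
  invisible(x)
}

#' Write simulator fixtures to plain-text files
#'
#' Emits the pedigree, phenotypes, chip genotypes (.raw-like), the marker
#' map (.bim-like TSV), the variance-component/model configuration and the
#' simulation truth needed by downstream checks.  Identical seeds produce
#' byte-identical files.
#'
#' @param sim an `ml_simulation`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
emit_fixtures <- function(sim, outdir) {
  stopifnot(inherits(sim, "ml_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outdir, x)
  ped <- sim$ped
  ped_out <- data.frame(animal = ped$id,
                        sire = ifelse(ped$sire > 0, ped$id[pmax(ped$sire, 1)], "0"),
                        dam = ifelse(ped$dam > 0, ped$id[pmax(ped$dam, 1)], "0"),
                        line = ped$line, birth_year = ped$birth_year,
                        genotyped = as.integer(ped$genotyped))
  write.csv(ped_out, fp("pedigree.csv"), row.names = FALSE, quote = FALSE)
  write.csv(sim$pheno, fp("phenotypes.csv"), row.names = FALSE, quote = FALSE)
  raw <- data.frame(animal = sim$geno_chip$ids, sim$geno_chip$dosage,
                    check.names = FALSE)
  write.csv(raw, fp("genotypes_chip.raw"), row.names = FALSE, quote = FALSE)
  map <- sim$geno_chip$map
  utils::write.table(map[, c("chrom", "marker", "pos", "a1", "a2")],
                     fp("map_chip.bim"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(components = sim$truth$components,
         gamma_true = as.data.frame(sim$truth$gamma_true),
         qtl = sim$truth$qtl,
         seed = sim$cfg$seed),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("pedigree.csv", "phenotypes.csv", "genotypes_chip.raw",
             "map_chip.bim", "truth.json")
  invisible(file.path(outdir, files))
}
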