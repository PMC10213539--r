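#' Single-step evaluation over a simulated or assembled dataset
#'
#' Convenience wrapper running one complete ssGBLUP (or pedigree BLUP)
#' evaluation: builds the pedigree-side operator for the requested H-inverse
#' flavor, the (optionally SNP-weighted, optionally APY-inverted) genomic
#' relationship matrix over the genotyped animals, blends, assembles and
#' solves the mixed-model equations.
#'
#' @param ped an `ml_pedigree`.
#' @param geno an `ml_genotypes` over (a subset of) pedigree animals, or
#'   `NULL` for pedigree BLUP.
#' @param pheno phenotype data frame (see [assemble_mme()]).
#' @param spec an [model_spec()].
#' @param flavor H-inverse flavor: `"standard"`, `"upg1"`, `"upg2"`, `"mf"`.
#' @param rule line-to-group rule for UPG/MF flavors (see [assign_groups()]).
#' @param gamma metafounder relationship matrix for the `"mf"` flavor;
#'   estimated from the markers via [estimate_gamma()] when omitted.
#' @param weights optional per-marker SNP weights (diagonal of `D`).
#' @param blend_beta blending fraction of `A22` into `G` (default 0.05).
#' @param apy `NULL` for a dense inverse of blended `G`, or an
#'   `ml_apy_partition` (see [select_core()]).
#' @param drop_pheno_ids animal ids whose phenotypes are removed before
#'   solving (the "reduced" run of LR validation).
#' @param method,tol passed to [solve_mme()].
#' @return An `ml_evaluation` (see [solve_mme()]); the estimated or supplied
#'   `gamma` is attached as attribute `gamma` for MF runs.
#' @export
ssgblup <- function(ped, geno, pheno, spec, flavor = "standard", rule = NULL,
                    gamma = NULL, weights = NULL, blend_beta = 0.05,
                    apy = NULL, drop_pheno_ids = NULL,
                    method = "direct", tol = 1e-10) {
  stopifnot(inherits(ped, "ml_pedigree"))
  Fvec <- compute_inbreeding(ped)
  Q <- NULL
  n_groups <- 0L
  if (flavor %in% c("upg1", "upg2", "mf")) {
    pedg <- assign_groups(ped, rule)
    n_groups <- length(attr(pedg, "groups"))
  }
  if (flavor == "mf") {
    if (is.null(gamma)) {
      if (is.null(geno)) stop("mf flavor without gamma requires genotypes")
      gamma <- estimate_gamma(ped, geno, rule)
    }
    ainv <- build_AGamma_inverse(pedg, gamma)
  } else if (flavor %in% c("upg1", "upg2")) {
    Q <- build_Q(pedg)
    ainv <- build_Astar(pedg, F = Fvec)
  } else {
    ainv <- build_A_inverse(ped, F = Fvec)
  }

  ginv <- a22inv <- NULL
  if (!is.null(geno)) {
    freq_mode <- if (flavor == "mf") "half" else "observed"
    G <- build_G(geno, freq = freq_mode, weights = weights)
    A22 <- if (flavor == "mf")
      build_A22_gamma(pedg, gamma, geno$ids)
    else build_A22(ped, geno$ids)
    Gb <- blend_G(G, A22, beta = blend_beta)
    ginv <- if (is.null(apy)) sym_inverse(Gb) else apy_inverse(Gb, apy)
    a22inv <- sym_inverse(A22)
    attr(a22inv, "freq_mode") <- NULL
  }
  hinv <- build_hinv(flavor, ainv, ginv = ginv, a22inv = a22inv, Q = Q,
                     n_groups = n_groups)
  if (!is.null(drop_pheno_ids)) {
    sel <- as.character(pheno[[spec$animal_col]]) %in% drop_pheno_ids
    for (tr in spec$traits) pheno[[tr]][sel] <- NA
  }
  sys <- assemble_mme(spec, pheno, hinv, Q = Q)
  res <- solve_mme(sys, method = method, tol = tol)
  if (flavor == "mf") attr(res, "gamma") <- gamma
  res
}

#' Whole/reduced LR validation of one evaluation setting
#'
#' Builds the forward split, runs the evaluation on the whole data and again
#' with the validation animals' phenotypes removed, and returns the LR
#' statistics for the first trait together with both evaluations.
#'
#' @param sim an `ml_simulation` (or a list with `ped`, `pheno` and the
#'   genotype set named by `panel`).
#' @param spec an [model_spec()]; defaults to a single-trait animal model
#'   with the simulation's true variance components and
#'   contemporary-group fixed effect.
#' @param panel `"chip"` or `"wgs"`.
#' @param split an [split_spec()].
#' @param ... further arguments passed to [ssgblup()] (flavor, weights,
#'   apy, ...).
#' @return List of class `ml_lr_run`: `report` (an `ml_lr_report`),
#'   `by_line`, `split`, `whole`, `reduced`.
#' @export
lr_validate <- function(sim, spec = NULL, panel = "chip",
                        split = split_spec(), ...) {
  geno <- if (identical(panel, "chip")) sim$geno_chip else sim$geno_wgs
  if (is.null(spec)) spec <- sim_model_spec(sim)
  sp <- make_split(sim$ped, geno$ids, split)
  whole <- ssgblup(sim$ped, geno, sim$pheno, spec, ...)
  reduced <- ssgblup(sim$ped, geno, sim$pheno, spec,
                     drop_pheno_ids = sp$test, ...)
  tr <- spec$traits[1]
  u_w <- whole$u[[tr]][sp$test]
  u_r <- reduced$u[[tr]][sp$test]
  if (whole$flavor %in% c("upg1", "upg2")) {
    gw <- extract_gebv(whole); gr <- extract_gebv(reduced)
    gw <- gw[gw$trait == tr, ]; gr <- gr[gr$trait == tr, ]
    u_w <- stats::setNames(gw$gebv, gw$animal)[sp$test]
    u_r <- stats::setNames(gr$gebv, gr$animal)[sp$test]
  }
  Fvec <- compute_inbreeding(sim$ped)
  s2u <- sim$truth$components$sigma2_u
  lines <- stats::setNames(sim$ped$line, sim$ped$id)
  rep1 <- lr_statistics(u_w, u_r, F_bar = mean(Fvec[sp$test]),
                        sigma2_u = s2u)
  by_line <- lr_report_by_line(u_w, u_r, lines, F = Fvec, sigma2_u = s2u)
  structure(list(report = rep1, by_line = by_line, split = sp,
                 whole = whole, reduced = reduced),
            class = "ml_lr_run")
}

#' Default single-trait model spec for a simulation
#'
#' Contemporary group (line by generation) as the fixed effect, random
#' litter, and the simulation's true variance components.
#'
#' @param sim an `ml_simulation`.
#' @return An [model_spec()].
#' @export
sim_model_spec <- function(sim) {
  cmp <- sim$truth$components
  model_spec(traits = "trait", fixed = list(trait = ~cg),
             G0 = matrix(cmp$sigma2_u),
             R0 = matrix(max(cmp$sigma2_e, 1e-8)),
             L0 = if (cmp$sigma2_c > 0) matrix(cmp$sigma2_c) else NULL)
}

#' Run the pipeline end-to-end
#'
#' Orchestrates simulate - QC - (GWAS - panels) - evaluation - LR
#' validation for one configuration, writing result tables and a manifest
#' into a run directory.  Every stage calls the exported module functions,
#' so any stage can be re-run in isolation.
#'
#' @param cfg an [sim_config()] describing the population.
#' @param outdir run directory (created if needed).
#' @param flavor H-inverse flavor.
#' @param panel one of `"chip"`, `"top40k"`, `"topsign"`, `"chipplussign"`,
#'   `"ldtags"`, `"allcomb"`.
#' @param use_bayesr_weights logical: weight G by BayesR posterior SNP
#'   variances.
#' @param apy_threshold `NULL`, or the eigenvalue share for APY core sizing
#'   (e.g. 0.98).
#' @param blend_beta blending fraction (default 0.05).
#' @return Invisibly, a list with the LR run, the panels used, and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = tempfile("mlrun"),
                         flavor = "standard", panel = "chip",
                         use_bayesr_weights = FALSE, apy_threshold = NULL,
                         blend_beta = 0.05) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_population(cfg)
  qc <- qc_genotypes(sim$geno_chip, ped = sim$ped)
  geno <- qc$geno
  spec <- sim_model_spec(sim)
  sp <- make_split(sim$ped, geno$ids, split_spec())

  panel <- tolower(panel)
  panel_markers <- NULL
  if (panel != "chip") {
    qcw <- qc_genotypes(sim$geno_wgs, ped = sim$ped)
    disc <- intersect(qcw$geno$ids, sp$training)
    gw <- run_gwas(subset_genotypes(qcw$geno, ids = disc), sim$pheno,
                   trait = spec$traits[1], test_ids = sp$test)
    panels <- build_panels(geno$map$marker, list(gw), qcw$geno)
    nm <- c(chip = "Chip", top40k = "Top40k", topsign = "TopSign",
            chipplussign = "ChipPlusSign", ldtags = "LDTags",
            allcomb = "AllComb")[[panel]]
    panel_markers <- panels[[nm]]
    if (length(panel_markers) == 0L)
      stop("panel ", nm, " is empty for this simulation")
    geno <- subset_genotypes(qcw$geno, markers = panel_markers, panel = nm)
  }

  weights <- NULL
  if (use_bayesr_weights) {
    adj <- adjusted_phenotypes(sim, geno, spec)
    post <- run_bayesr(subset_genotypes(geno, ids = names(adj)), adj,
                       bayesr_config(niter = 4000L, burnin = 1000L,
                                     seed = cfg$seed),
                       sigma2_g = sim$truth$components$sigma2_u)
    weights <- variances_to_weights(post)
  }

  apy <- NULL
  if (!is.null(apy_threshold)) {
    G <- build_G(geno)
    lines <- sim$ped$line[match(geno$ids, sim$ped$id)]
    apy <- select_core(G, lines, var_threshold = apy_threshold,
                       seed = cfg$seed)
  }

  run <- lr_validate(sim, spec, panel = "chip", flavor = flavor,
                     weights = weights, apy = apy, blend_beta = blend_beta)
  # when a non-chip panel was requested, rerun on that genotype set
  if (panel != "chip") {
    sim2 <- sim
    sim2$geno_chip <- geno
    run <- lr_validate(sim2, spec, panel = "chip", flavor = flavor,
                       weights = weights, apy = apy,
                       blend_beta = blend_beta)
  }

  write.csv(run$by_line, file.path(outdir, "lr_report.csv"),
            row.names = FALSE)
  writeLines(run$split$test, file.path(outdir, "split_test_ids.txt"))
  writeLines(run$split$training, file.path(outdir, "split_training_ids.txt"))
  gebv <- extract_gebv(run$whole)
  gebv$line <- sim$ped$line[match(gebv$animal, sim$ped$id)]
  gebv$flavor <- flavor
  utils::write.table(gebv, file.path(outdir, "gebv.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(seed = cfg$seed, flavor = flavor, panel = panel,
                   n_markers = ncol(geno$dosage),
                   n_genotyped = length(geno$ids),
                   n_test = length(run$split$test),
                   blend_beta = blend_beta,
                   apy_threshold = apy_threshold,
                   bayesr_weights = use_bayesr_weights,
                   qc = qc$report,
                   package_version = as.character(utils::packageVersion("mlgblup")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(run = run, panel_markers = panel_markers,
                 manifest = manifest, outdir = outdir))
}

#' Phenotypes adjusted for fixed and litter effects
#'
#' Two-stage helper for marker-effect models: solves the evaluation once,
#' then subtracts the fixed-effect and litter solutions from the observed
#' phenotypes of genotyped animals (one record per animal, first trait).
#'
#' @param sim an `ml_simulation`.
#' @param geno genotype set whose animals receive adjusted records.
#' @param spec an [model_spec()].
#' @return Named numeric vector of adjusted phenotypes.
#' @export
adjusted_phenotypes <- function(sim, geno, spec = sim_model_spec(sim)) {
  tr <- spec$traits[1]
  fit <- ssgblup(sim$ped, NULL, sim$pheno, spec, flavor = "standard")
  ph <- sim$pheno[!is.na(sim$pheno[[tr]]), ]
  mm <- safe_model_matrix(spec$fixed[[tr]], ph, TRUE)
  fixed_part <- as.numeric(mm %*% fit$b[[tr]])
  lit <- fit$c[[tr]][as.character(ph[[spec$litter_col]])]
  lit[is.na(lit)] <- 0
  adj <- ph[[tr]] - fixed_part - lit
  names(adj) <- as.character(ph[[spec$animal_col]])
  adj[names(adj) %in% geno$ids]
}
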