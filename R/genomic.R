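#' Construct a genotype set
#'
#' Container for a dosage matrix (animals x markers, values 0/1/2 or `NA`)
#' plus its marker map.
#'
#' @param dosage numeric matrix of allele dosages; rownames are animal ids
#'   unless `ids` is given.
#' @param map data frame with columns `marker`, `chrom`, `pos` (1-based bp)
#'   and optionally allele labels `a1`, `a2`; one row per dosage column.
#' @param ids character vector of animal ids.
#' @param panel optional panel label.
#' @return An object of class `ml_genotypes` with elements `dosage`, `map`,
#'   `ids`, `panel`.
#' @export
genotype_set <- function(dosage, map, ids = rownames(dosage), panel = "Chip") {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) stop("animal ids required")
  if (nrow(map) != ncol(dosage)) stop("map length must equal marker count")
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  if (any(duplicated(map[c("chrom", "pos")])))
    stop("positions must be strictly increasing within chromosome")
  colnames(dosage) <- map$marker
  rownames(dosage) <- ids
  structure(list(dosage = dosage, map = map, ids = as.character(ids),
                 panel = panel),
            class = "ml_genotypes")
}

#' @exportS3Method base::print
print.ml_genotypes <- function(x, ...) {
  cat("ml_genotypes [", x$panel, "]: ", length(x$ids), " animals x ",
      ncol(x$dosage), " markers\n", sep = "")
  invisible(x)
}

#' Subset a genotype set
#' @param geno an `ml_genotypes`.
#' @param ids animal ids to keep (default all).
#' @param markers marker names to keep (default all).
#' @param panel new panel label (default unchanged).
#' @return An `ml_genotypes`.
#' @export
subset_genotypes <- function(geno, ids = geno$ids, markers = geno$map$marker,
                             panel = geno$panel) {
  ai <- match(ids, geno$ids)
  if (anyNA(ai)) stop("unknown animal id")
  mi <- match(markers, geno$map$marker)
  if (anyNA(mi)) stop("unknown marker")
  genotype_set(geno$dosage[ai, mi, drop = FALSE],
               geno$map[mi, , drop = FALSE], ids = geno$ids[ai], panel = panel)
}

#' Genotype quality control
#'
#' Drops markers failing call-rate, minor-allele-frequency, or
#' observed-vs-expected genotype-frequency filters and monomorphic markers;
#' drops animals with excess missingness; and, when a pedigree is supplied,
#' drops animals whose rate of opposite-homozygote conflicts with a genotyped
#' parent exceeds a threshold.
#'
#' @param geno an `ml_genotypes`.
#' @param thresholds list with elements `call_rate` (default 0.90), `maf`
#'   (default 0.01), `geno_freq_dev` (default 0.15, the largest absolute
#'   deviation of observed from Hardy-Weinberg genotype frequencies),
#'   `animal_missing` (default 0.10), `conflict_rate` (default 0.01).
#' @param ped optional `ml_pedigree` used for parent-progeny conflict checks.
#' @return List with elements `geno` (the filtered set) and `report` (counts
#'   of removals by reason).
#' @export
qc_genotypes <- function(geno, thresholds = list(), ped = NULL) {
  th <- utils::modifyList(list(call_rate = 0.90, maf = 0.01,
                               geno_freq_dev = 0.15, animal_missing = 0.10,
                               conflict_rate = 0.01), thresholds)
  M <- geno$dosage
  n <- nrow(M)
  nonmiss <- colSums(!is.na(M))
  call_rate <- nonmiss / n
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  obs <- function(k) colMeans(M == k, na.rm = TRUE)
  exp_freq <- rbind(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  obs_freq <- rbind(`0` = obs(0), `1` = obs(1), `2` = obs(2))
  dev <- apply(abs(obs_freq - exp_freq), 2, max)
  fail_call <- call_rate < th$call_rate
  fail_mono <- maf == 0 | nonmiss == 0
  fail_maf <- !fail_mono & maf < th$maf
  fail_dev <- dev > th$geno_freq_dev
  drop_marker <- fail_call | fail_mono | fail_maf | fail_dev
  report <- list(
    markers_call_rate = sum(fail_call),
    markers_monomorphic = sum(fail_mono & !fail_call),
    markers_maf = sum(fail_maf & !fail_call),
    markers_geno_freq = sum(fail_dev & !fail_call & !fail_maf & !fail_mono)
  )
  M <- M[, !drop_marker, drop = FALSE]
  if (ncol(M) == 0L) stop("no markers pass QC")
  amiss <- rowMeans(is.na(M))
  drop_animal <- amiss > th$animal_missing
  report$animals_missingness <- sum(drop_animal)
  conflict_dropped <- character(0)
  if (!is.null(ped)) {
    keep_ids <- geno$ids[!drop_animal]
    Mk <- M[!drop_animal, , drop = FALSE]
    codes <- match(keep_ids, ped$id)
    for (slot in c("sire", "dam")) {
      par_code <- ped[[slot]][codes]
      par_id <- ifelse(par_code > 0, ped$id[pmax(par_code, 1)], NA)
      hit <- which(!is.na(par_id) & par_id %in% keep_ids)
      for (i in hit) {
        gi <- Mk[i, ]
        gp <- Mk[match(par_id[i], keep_ids), ]
        comparable <- !is.na(gi) & !is.na(gp)
        if (!any(comparable)) next
        opp <- (gi == 0 & gp == 2) | (gi == 2 & gp == 0)
        if (mean(opp[comparable]) > th$conflict_rate)
          conflict_dropped <- c(conflict_dropped, keep_ids[i])
      }
    }
    conflict_dropped <- unique(conflict_dropped)
    drop_animal <- drop_animal | geno$ids %in% conflict_dropped
  }
  report$animals_parent_conflict <- length(conflict_dropped)
  if (all(drop_animal)) stop("no animals pass QC")
  out <- genotype_set(geno$dosage[!drop_animal, !drop_marker, drop = FALSE],
                      geno$map[!drop_marker, , drop = FALSE],
                      ids = geno$ids[!drop_animal], panel = geno$panel)
  report$markers_kept <- ncol(out$dosage)
  report$animals_kept <- length(out$ids)
  list(geno = out, report = report)
}

#' Observed allele frequencies
#'
#' Frequency of the counted (second) allele per marker, pooled over all
#' genotyped animals across lines: mean dosage / 2 over non-missing calls.
#'
#' @param geno an `ml_genotypes`.
#' @return Named numeric vector of frequencies.
#' @export
allele_frequencies <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Zc D Zc' / (2 * sum p(1-p))` with `Zc = M - 2P` the centered dosage
#' matrix and `D` a diagonal matrix of SNP weights (identity by default).
#' With `freq = "half"` the centering frequency is 0.5 for every marker and
#' the denominator is `m/2` - the scaling the metafounder theory pairs with.
#' Residual missing dosages are mean-imputed (centered value 0).
#'
#' @param geno an `ml_genotypes` (post-QC).
#' @param freq `"observed"` (default) or `"half"`.
#' @param weights optional nonnegative per-marker weights (diagonal of `D`).
#' @return Dense symmetric matrix with dimnames = animal ids and attribute
#'   `freq_mode`.
#' @export
build_G <- function(geno, freq = c("observed", "half"), weights = NULL) {
  freq <- match.arg(freq)
  M <- geno$dosage
  m <- ncol(M)
  p <- if (freq == "half") rep(0.5, m) else allele_frequencies(geno)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers fixed: zero denominator")
  Zc <- sweep(M, 2, 2 * p)
  Zc[is.na(Zc)] <- 0
  if (!is.null(weights)) {
    stopifnot(length(weights) == m, all(weights >= 0))
    G <- tcrossprod(sweep(Zc, 2, weights, `*`), Zc) / denom
  } else {
    G <- tcrossprod(Zc) / denom
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(geno$ids, geno$ids)
  attr(G, "freq_mode") <- freq
  G
}

#' Blend a genomic relationship matrix with pedigree relationships
#'
#' `(1 - beta) * G + beta * A22`; with positive-definite `A22` and
#' `beta > 0` the blend is full rank, avoiding singularity of marker-limited
#' `G`.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships among the same animals, same order.
#' @param beta blending fraction in (0, 1); default 0.05.
#' @return Blended matrix (keeps `G`'s `freq_mode` attribute).
#' @export
blend_G <- function(G, A22, beta = 0.05) {
  if (!all(dim(G) == dim(A22))) stop("dimension mismatch between G and A22")
  stopifnot(beta >= 0, beta < 1)
  out <- (1 - beta) * G + beta * A22
  attr(out, "freq_mode") <- attr(G, "freq_mode")
  out
}

#' Select APY core animals by the eigenvalue spectrum of G
#'
#' The core size is the smallest number of leading eigenvalues of `G`
#' explaining at least `var_threshold` of its total variation; core animals
#' are then sampled uniformly at random within line, with per-line counts
#' proportional to `proportions` (largest-remainder rounding).
#'
#' @param G genomic relationship matrix.
#' @param lines line label per animal (same order as `G`).
#' @param var_threshold cumulative eigenvalue share, in (0, 1]; default 0.98.
#' @param proportions named per-line core fractions summing to 1; default the
#'   line shares of the genotyped set.
#' @param seed integer seed for the core sampling.
#' @return List of class `ml_apy_partition`: `core`, `noncore` (ids),
#'   `n_core`, `eigen_share`.
#' @export
select_core <- function(G, lines, var_threshold = 0.98, proportions = NULL,
                        seed = 1L) {
  if (var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must be in (0, 1]")
  n <- nrow(G)
  ids <- rownames(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  share <- cumsum(ev) / sum(ev)
  n_core <- which(share >= var_threshold - 1e-12)[1]
  lines <- as.character(lines)
  if (is.null(proportions)) {
    tab <- table(lines)
    proportions <- as.numeric(tab) / n
    names(proportions) <- names(tab)
  }
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  raw <- n_core * proportions
  cnt <- floor(raw)
  rem <- n_core - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  core <- character(0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (ln in names(proportions)) {
    pool <- ids[lines == ln]
    k <- min(cnt[[ln]], length(pool))
    core <- c(core, sample(pool, k))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(core = core, noncore = setdiff(ids, core),
                 n_core = length(core), eigen_share = share),
            class = "ml_apy_partition")
}

#' APY sparse-structured inverse of G
#'
#' Algorithm for proven and young: exact inverse of the core block, diagonal
#' noncore block `m_ii = g_ii - g_i,core Gcc^{-1} g_core,i`, and the standard
#' bordered assembly.  With all animals core this is the dense inverse.
#'
#' @param G genomic relationship matrix (blend first if rank-deficient).
#' @param partition an `ml_apy_partition` (see [select_core()]).
#' @return Dense symmetric matrix in the original animal order (attribute
#'   `freq_mode` preserved).
#' @export
apy_inverse <- function(G, partition) {
  ids <- rownames(G)
  core <- partition$core; noncore <- partition$noncore
  stopifnot(setequal(c(core, noncore), ids))
  ci <- match(core, ids); ni <- match(noncore, ids)
  Gcc <- G[ci, ci, drop = FALSE]
  ch <- tryCatch(chol(Gcc), error = function(e)
    stop("singular core block; blend G with A22 first"))
  Gcc_inv <- chol2inv(ch)
  out <- matrix(0, nrow(G), ncol(G), dimnames = dimnames(G))
  if (length(ni) == 0L) {
    out[ci, ci] <- Gcc_inv
  } else {
    Gcn <- G[ci, ni, drop = FALSE]
    W <- Gcc_inv %*% Gcn                       # Gcc^{-1} Gcn
    mii <- diag(G)[ni] - colSums(Gcn * W)
    if (any(mii <= 0))
      stop("nonpositive noncore conditional variance; blend G with A22 first")
    minv <- 1 / mii
    out[ci, ci] <- Gcc_inv + W %*% (minv * t(W))
    out[ci, ni] <- -sweep(W, 2, minv, `*`)
    out[ni, ci] <- t(out[ci, ni])
    out[ni, ni] <- diag(minv, nrow = length(ni))
  }
  out <- (out + t(out)) / 2
  attr(out, "freq_mode") <- attr(G, "freq_mode")
  out
}

#' Principal component analysis of centered dosages
#'
#' @param geno an `ml_genotypes` (post-QC).
#' @param k number of components.
#' @return List with `scores` (animals x k), `var_share` (per-component
#'   share of total dosage variance).
#' @export
genotype_pca <- function(geno, k = 2) {
  M <- geno$dosage
  cm <- colMeans(M, na.rm = TRUE)
  Zc <- sweep(M, 2, cm)
  Zc[is.na(Zc)] <- 0
  if (k > min(dim(Zc))) stop("k exceeds the rank of the centered dosage matrix")
  total <- sum(Zc^2)
  if (total == 0) {                      # e.g. identical animals
    scores <- matrix(0, nrow(Zc), k,
                     dimnames = list(geno$ids, paste0("PC", seq_len(k))))
    return(list(scores = scores, var_share = rep(0, k)))
  }
  sv <- svd(Zc, nu = min(k, min(dim(Zc))), nv = 0)
  share <- sv$d^2 / total
  scores <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  rownames(scores) <- geno$ids
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores[, seq_len(k), drop = FALSE],
       var_share = share[seq_len(k)])
}
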