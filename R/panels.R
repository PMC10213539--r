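#' Single-marker GWAS on adjusted phenotypes
#'
#' Stand-in association scan used to drive variant preselection: phenotypes
#' are pre-adjusted for fixed effects (line is always included as a
#' covariate, pooling lines in a multi-line scan) and then each marker is
#' tested by simple regression of the adjusted phenotype on centered
#' dosages.  Constant markers are excluded from the scan.
#'
#' @param geno an `ml_genotypes` over the discovery animals.
#' @param pheno data frame with an animal id column, the trait column and
#'   any adjustment columns.
#' @param trait trait column name.
#' @param adjust one-sided formula of fixed adjustments (default `~ line`
#'   when a `line` column exists, else intercept only).
#' @param animal_col animal id column name.
#' @param test_ids ids that must not appear in the discovery set (overlap is
#'   an error).
#' @return Data frame of class `ml_gwas`: `marker`, `chrom`, `pos`, `beta`,
#'   `se`, `p`, `trait`, sorted by map position.
#' @export
run_gwas <- function(geno, pheno, trait, adjust = NULL,
                     animal_col = "animal", test_ids = NULL) {
  ids <- intersect(geno$ids, as.character(pheno[[animal_col]]))
  if (!is.null(test_ids) && length(intersect(ids, test_ids)))
    stop("discovery set overlaps the test set")
  ph <- pheno[match(ids, as.character(pheno[[animal_col]])), , drop = FALSE]
  keep <- !is.na(ph[[trait]])
  ph <- ph[keep, , drop = FALSE]
  ids <- ids[keep]
  if (is.null(adjust))
    adjust <- if ("line" %in% names(ph)) ~line else ~1
  mm <- stats::model.matrix(adjust, data = ph)
  y <- stats::lm.fit(mm, ph[[trait]])$residuals
  M <- geno$dosage[match(ids, geno$ids), , drop = FALSE]
  cm <- colMeans(M, na.rm = TRUE)
  Zc <- sweep(M, 2, cm)
  Zc[is.na(Zc)] <- 0
  n <- length(y)
  sxx <- colSums(Zc^2)
  ok <- sxx > 0
  sxy <- as.numeric(crossprod(Zc, y))
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  syy <- sum((y - mean(y))^2)
  # residual SS of the marker regression; guard tiny negatives
  rss <- pmax(syy - beta^2 * sxx, 0)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  out <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                    pos = geno$map$pos, beta = beta, se = se, p = p,
                    trait = trait, stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ml_gwas", "data.frame")
  out
}

#' Windowed top-marker selection (Top40k / TopSign rules)
#'
#' Windows tile each chromosome as half-open intervals
#' `[0, w), [w, 2w), ...` anchored at bp 0.  Mode `top40k` keeps the
#' lowest-p marker of every nonempty window regardless of significance;
#' mode `topsign` keeps the lowest-p marker per window among markers with
#' `p <= p_threshold` (possibly none).  Ties on p are broken by lowest bp.
#'
#' @param gwas an `ml_gwas` (or data frame with `marker`, `chrom`, `pos`,
#'   `p`).
#' @param window window size in bp (default 55000).
#' @param mode `"top40k"` or `"topsign"`.
#' @param p_threshold significance threshold for `topsign` (default 1e-6).
#' @return Character vector of selected marker names.
#' @export
select_top_per_window <- function(gwas, window = 55000, mode = c("top40k", "topsign"),
                                  p_threshold = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(window > 0)
  d <- as.data.frame(gwas)[, c("marker", "chrom", "pos", "p")]
  if (mode == "topsign") d <- d[d$p <= p_threshold, , drop = FALSE]
  if (nrow(d) == 0L) return(character(0))
  d$win <- floor(d$pos / window)
  d <- d[order(d$chrom, d$win, d$p, d$pos), , drop = FALSE]
  keep <- !duplicated(d[, c("chrom", "win")])
  sort_by_map(d$marker[keep], d[keep, , drop = FALSE])
}

#' @noRd
sort_by_map <- function(markers, map) {
  ix <- match(markers, map$marker)
  markers[order(map$chrom[ix], map$pos[ix])]
}

#' Greedy LD pruning to tag markers
#'
#' Left-to-right within chromosome: a marker is kept unless its squared
#' dosage correlation with any already-kept marker within a trailing window
#' exceeds `r2_threshold`.
#'
#' @param geno an `ml_genotypes` (post-QC; the map is position-sorted).
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window_bp trailing window within which LD is checked (default 1e6).
#' @return Character vector of retained (tag) marker names.
#' @export
ld_prune <- function(geno, r2_threshold = 0.1, window_bp = 1e6) {
  M <- geno$dosage
  cm <- colMeans(M, na.rm = TRUE)
  Zc <- sweep(M, 2, cm)
  Zc[is.na(Zc)] <- 0
  ss <- sqrt(colSums(Zc^2))
  keep <- character(0)
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    kept_idx <- integer(0)
    for (j in idx) {
      if (ss[j] == 0) next  # constant marker carries no information
      in_win <- kept_idx[geno$map$pos[kept_idx] > geno$map$pos[j] - window_bp]
      ok <- TRUE
      if (length(in_win)) {
        r <- as.numeric(crossprod(Zc[, in_win, drop = FALSE], Zc[, j])) /
          (ss[in_win] * ss[j])
        if (any(r^2 > r2_threshold)) ok <- FALSE
      }
      if (ok) kept_idx <- c(kept_idx, j)
    }
    keep <- c(keep, geno$map$marker[kept_idx])
  }
  keep
}

#' Combine marker panels
#'
#' Deduplicated union of marker sets, returned in map order.
#'
#' @param parts list of character vectors of marker names.
#' @param map marker map (`marker`, `chrom`, `pos`) providing the ordering.
#' @param name optional panel name recorded as an attribute.
#' @return Character vector of markers, map-sorted, with attribute `panel`.
#' @export
combine_panels <- function(parts, map, name = NULL) {
  u <- unique(unlist(parts, use.names = FALSE))
  missing <- setdiff(u, map$marker)
  if (length(missing))
    stop("markers outside the shared namespace: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- sort_by_map(u, map)
  attr(out, "panel") <- name
  out
}

#' Construct the standard preselection panels
#'
#' Builds the named panels from a chip marker set, a WGS-density GWAS and
#' the WGS genotypes: `Top40k` (windowed top-p), `TopSign` (windowed
#' significant-only), `ChipPlusSign` (TopSign united with the chip),
#' `LDTags` (greedy r2 pruning), `AllComb` (union of all).  Multi-trait
#' GWAS results are merged by taking each panel rule per trait and uniting
#' the selections.
#'
#' @param chip_markers character vector of chip marker names.
#' @param gwas_list list of `ml_gwas` results (one per trait).
#' @param geno_wgs an `ml_genotypes` at WGS density (for LD pruning).
#' @param window,p_threshold,r2_threshold panel parameters (defaults 55 kb,
#'   1e-6, 0.1).
#' @return Named list of marker-name vectors:
#'   `Chip`, `Top40k`, `TopSign`, `ChipPlusSign`, `LDTags`, `AllComb`.
#' @export
build_panels <- function(chip_markers, gwas_list, geno_wgs, window = 55000,
                         p_threshold = 1e-6, r2_threshold = 0.1) {
  map <- geno_wgs$map
  top40k <- combine_panels(lapply(gwas_list, select_top_per_window,
                                  window = window, mode = "top40k"), map)
  topsign <- combine_panels(lapply(gwas_list, select_top_per_window,
                                   window = window, mode = "topsign",
                                   p_threshold = p_threshold), map)
  ldtags <- ld_prune(geno_wgs, r2_threshold = r2_threshold)
  list(
    Chip = combine_panels(list(chip_markers), map, "Chip"),
    Top40k = structure(top40k, panel = "Top40k"),
    TopSign = structure(topsign, panel = "TopSign"),
    ChipPlusSign = combine_panels(list(topsign, chip_markers), map,
                                  "ChipPlusSign"),
    LDTags = combine_panels(list(ldtags), map, "LDTags"),
    AllComb = combine_panels(list(ldtags, top40k, topsign, chip_markers),
                             map, "AllComb")
  )
}
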