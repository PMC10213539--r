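#' Specify a whole/reduced validation split
#'
#' @param min_fullsibs minimum number of full sibs for a last-generation
#'   litter to enter the test set (default 5).
#' @param max_rel training animals must have pedigree relationship strictly
#'   below this value with every test animal (default 0.5).
#' @return An `ml_split_spec`.
#' @export
split_spec <- function(min_fullsibs = 5L, max_rel = 0.5) {
  stopifnot(min_fullsibs >= 1L, max_rel > 0, max_rel <= 2)
  structure(list(min_fullsibs = min_fullsibs, max_rel = max_rel),
            class = "ml_split_spec")
}

#' Build forward-validation training and test sets
#'
#' Test animals are genotyped members of last-generation litters (full-sib
#' groups sharing both parents, in the maximum birth year) with at least
#' `min_fullsibs` members.  Training animals are the remaining genotyped
#' animals whose largest pedigree relationship with any test animal is
#' strictly below `max_rel`.
#'
#' @param ped an `ml_pedigree` with birth years.
#' @param geno_ids ids of genotyped animals.
#' @param spec an [split_spec()].
#' @return List with `test`, `training` (character ids) and `last_year`.
#' @export
make_split <- function(ped, geno_ids, spec = split_spec()) {
  stopifnot(inherits(ped, "ml_pedigree"))
  if (all(is.na(ped$birth_year))) stop("birth_year required for the split")
  last <- max(ped$birth_year, na.rm = TRUE)
  lastgen <- which(!is.na(ped$birth_year) & ped$birth_year == last &
                     ped$sire > 0L & ped$dam > 0L)
  litter <- paste(ped$sire[lastgen], ped$dam[lastgen], sep = "_")
  size <- table(litter)
  keep_litters <- names(size)[size >= spec$min_fullsibs]
  test <- ped$id[lastgen[litter %in% keep_litters]]
  test <- intersect(test, geno_ids)
  if (length(test) == 0L)
    stop("empty test set; consider a smaller min_fullsibs threshold")
  candidates <- setdiff(geno_ids, test)
  # pedigree relationships of every animal with each test animal
  tcodes <- resolve_codes(ped, test)
  E <- matrix(0, nrow(ped), length(tcodes))
  E[cbind(tcodes, seq_along(tcodes))] <- 1
  rel <- A_times(ped, E)
  ccodes <- resolve_codes(ped, candidates)
  maxrel <- apply(rel[ccodes, , drop = FALSE], 1, max)
  training <- candidates[maxrel < spec$max_rel]
  list(test = test, training = training, last_year = last)
}

#' LR-method validation statistics
#'
#' Compares GEBV of validation animals from the whole (`u_w`) and reduced
#' (`u_r`, validation phenotypes removed) evaluations:
#' accuracy `sqrt(cov(u_w, u_r) / ((1 - Fbar) * sigma2_u))`, standardized
#' bias `(mean(u_r) - mean(u_w)) / sigma_u` (expected 0), and dispersion
#' `b1 = cov(u_w, u_r) / var(u_r)` from the regression of `u_w` on `u_r`
#' (expected 1).
#'
#' @param gebv_whole,gebv_reduced named numeric vectors of GEBV over the same
#'   validation animals.
#' @param F_bar mean inbreeding coefficient of the validation animals.
#' @param sigma2_u additive genetic variance used for standardisation.
#' @return List of class `ml_lr_report`: `accuracy`, `bias_std`, `b1`,
#'   `n`, `F_bar`, `negative_cov_flag`.
#' @export
lr_statistics <- function(gebv_whole, gebv_reduced, F_bar = 0, sigma2_u) {
  if (!is.null(names(gebv_whole)) && !is.null(names(gebv_reduced))) {
    common <- intersect(names(gebv_whole), names(gebv_reduced))
    if (length(common) < length(gebv_whole) ||
        length(common) < length(gebv_reduced))
      stop("whole and reduced GEBV must cover the same validation animals")
    gebv_reduced <- gebv_reduced[names(gebv_whole)]
  }
  n <- length(gebv_whole)
  if (n < 10L) stop("fewer than 10 validation animals")
  stopifnot(length(gebv_reduced) == n, sigma2_u > 0, F_bar >= 0, F_bar < 1)
  cv <- cov(gebv_whole, gebv_reduced)
  flag <- cv < 0
  acc <- if (flag) 0 else sqrt(cv / ((1 - F_bar) * sigma2_u))
  bias <- (mean(gebv_reduced) - mean(gebv_whole)) / sqrt(sigma2_u)
  b1 <- cv / var(gebv_reduced)
  structure(list(accuracy = acc, bias_std = bias, b1 = b1, n = n,
                 F_bar = F_bar, negative_cov_flag = flag),
            class = "ml_lr_report")
}

#' @exportS3Method base::print
print.ml_lr_report <- function(x, ...) {
  cat(sprintf("LR validation (n = %d, Fbar = %.3f): acc = %.3f, bias = %+.3f SD, b1 = %.3f\n",
              x$n, x$F_bar, x$accuracy, x$bias_std, x$b1))
  if (x$negative_cov_flag)
    cat("  [negative whole/reduced covariance; accuracy reported as 0]\n")
  invisible(x)
}

#' Per-line LR report table
#'
#' @param gebv_whole,gebv_reduced named GEBV vectors over validation animals.
#' @param lines named line label per validation animal.
#' @param F named inbreeding vector (defaults to 0).
#' @param sigma2_u additive genetic variance.
#' @return Data frame with one row per line plus a pooled `all` row.
#' @export
lr_report_by_line <- function(gebv_whole, gebv_reduced, lines, F = NULL,
                              sigma2_u) {
  ids <- names(gebv_whole)
  if (is.null(F)) F <- stats::setNames(rep(0, length(ids)), ids)
  one <- function(sel, label) {
    r <- lr_statistics(gebv_whole[sel], gebv_reduced[sel],
                       F_bar = mean(F[sel]), sigma2_u = sigma2_u)
    data.frame(line = label, n = r$n, F_bar = r$F_bar, accuracy = r$accuracy,
               bias_std = r$bias_std, b1 = r$b1)
  }
  out <- do.call(rbind, lapply(sort(unique(lines)), function(ln)
    one(ids[lines[ids] == ln], ln)))
  rbind(out, one(ids, "all"))
}
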