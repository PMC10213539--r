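#' Assign unknown-parent groups by line of origin
#'
#' Replaces every missing-parent slot by a reference to a base-population
#' group.  The default rule maps each animal's line to a group of the same
#' name, so all base animals of a line share one group (the line-of-origin
#' convention).
#'
#' @param ped an `ml_pedigree`.
#' @param rule named character vector mapping line labels to group labels,
#'   e.g. `c(TL1 = "TL1", TL2 = "TL2")`.  Defaults to the identity map over
#'   the lines present.
#' @param groups optional ordered character vector of group labels; defaults
#'   to the sorted unique values of `rule`.
#' @return The pedigree with integer columns `sire_group` and `dam_group`
#'   (0 where the parent is known) and attribute `groups` (ordered labels).
#' @export
assign_groups <- function(ped, rule = NULL, groups = NULL) {
  stopifnot(inherits(ped, "ml_pedigree"))
  lines <- unique(ped$line)
  if (is.null(rule)) rule <- stats::setNames(lines, lines)
  uncovered <- setdiff(lines, names(rule))
  if (length(uncovered)) {
    offenders <- ped$id[ped$line %in% uncovered &
                          (ped$sire == 0L | ped$dam == 0L)]
    stop("no group rule for line(s) ", paste(uncovered, collapse = ", "),
         "; affected animals include: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  if (is.null(groups)) groups <- sort(unique(unname(rule)))
  gidx <- match(unname(rule[ped$line]), groups)
  ped$sire_group <- ifelse(ped$sire == 0L, gidx, 0L)
  ped$dam_group  <- ifelse(ped$dam  == 0L, gidx, 0L)
  attr(ped, "groups") <- groups
  ped
}

#' @noRd
check_grouped <- function(ped) {
  if (is.null(attr(ped, "groups")))
    stop("pedigree has no group assignment; call assign_groups() first")
  attr(ped, "groups")
}

#' Expected base-group contributions (Q matrix)
#'
#' Genetic-contribution recursion `q(animal) = (q(sire) + q(dam)) / 2`, where
#' a missing parent contributes the unit row of its group.  Rows of animals
#' whose every base path terminates in a group sum to 1.
#'
#' @param ped a group-assigned pedigree (see [assign_groups()]).
#' @return Dense animals-by-groups matrix with rownames = animal ids.
#' @export
build_Q <- function(ped) {
  groups <- check_grouped(ped)
  n <- nrow(ped); g <- length(groups)
  Q <- matrix(0, n, g, dimnames = list(ped$id, groups))
  for (i in seq_len(n)) {
    qi <- numeric(g)
    if (ped$sire[i] > 0L) qi <- qi + 0.5 * Q[ped$sire[i], ]
    else qi[ped$sire_group[i]] <- qi[ped$sire_group[i]] + 0.5
    if (ped$dam[i] > 0L) qi <- qi + 0.5 * Q[ped$dam[i], ]
    else qi[ped$dam_group[i]] <- qi[ped$dam_group[i]] + 0.5
    Q[i, ] <- qi
  }
  Q
}

#' QP-transformed pedigree inverse with unknown-parent groups (A*)
#'
#' Henderson-rule assembly over animals plus groups: each missing parent's
#' `-1/2` coefficient is routed to its group column, and Mendelian sampling
#' variances are those of the plain (group-free) assembly.  The animal block
#' therefore equals the plain `A^{-1}`, and the result equals the
#' Quaas-Pollak transformation `[A^{-1}, -A^{-1}Q; -Q'A^{-1}, Q'A^{-1}Q]`.
#'
#' @param ped a group-assigned pedigree.
#' @param F optional precomputed inbreeding vector.
#' @return Sparse symmetric matrix of order `n_animals + n_groups`,
#'   dimnames = animal ids followed by group labels.
#' @export
build_Astar <- function(ped, F = compute_inbreeding(ped)) {
  groups <- check_grouped(ped)
  n <- nrow(ped); g <- length(groups)
  d <- mendelian_variance(ped, F)
  b <- 1 / d
  # parent slot index: animal code, or n + group index when missing
  si <- ifelse(ped$sire > 0L, ped$sire, n + ped$sire_group)
  di <- ifelse(ped$dam  > 0L, ped$dam,  n + ped$dam_group)
  idx <- list(ped$code, si, di)
  coef <- c(1, -0.5, -0.5)
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  for (p in 1:3) for (q in 1:3) {
    trip_i <- c(trip_i, idx[[p]])
    trip_j <- c(trip_j, idx[[q]])
    trip_x <- c(trip_x, coef[p] * coef[q] * b)
  }
  M <- sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                    dims = c(n + g, n + g),
                    dimnames = list(c(ped$id, groups), c(ped$id, groups)))
  forceSymmetric(drop0(M))
}

#' Estimate the metafounder relationship matrix Gamma from markers
#'
#' Per group, the base allele frequency of each marker is estimated by
#' generalised least squares over that group's genotyped animals, using their
#' within-group pedigree relationships:
#' `p_hat = (1' A22g^{-1} 1)^{-1} 1' A22g^{-1} m / 2`.  Gamma is then 8 times
#' the across-marker covariance of the per-group estimates.  By default the
#' covariance is taken around the metafounder reference frequency 0.5 (the
#' centering the 0.5-scaled genomic matrix pairs with); sample-mean centering
#' is available as an alternative.
#'
#' @param ped an `ml_pedigree`.
#' @param geno a [genotype_set()] over (a subset of) pedigree animals.
#' @param rule named vector mapping line labels to group labels (see
#'   [assign_groups()]).
#' @param center `"half"` (default) or `"mean"`.
#' @return Symmetric groups-by-groups matrix with class attribute
#'   `ml_gamma`; attribute `base_freq` carries the per-group estimates.
#' @export
estimate_gamma <- function(ped, geno, rule = NULL, center = c("half", "mean")) {
  center <- match.arg(center)
  stopifnot(inherits(ped, "ml_pedigree"))
  ped <- assign_groups(ped, rule)
  groups <- attr(ped, "groups")
  rule <- if (is.null(rule)) stats::setNames(unique(ped$line), unique(ped$line)) else rule
  m <- ncol(geno$dosage)
  p_obs <- colMeans(geno$dosage, na.rm = TRUE) / 2
  if (all(p_obs %in% c(0, 1))) stop("all markers monomorphic")
  P <- matrix(NA_real_, length(groups), m,
              dimnames = list(groups, colnames(geno$dosage)))
  for (gi in seq_along(groups)) {
    glines <- names(rule)[unname(rule) == groups[gi]]
    ids <- intersect(geno$ids, ped$id[ped$line %in% glines])
    if (length(ids) < 2L)
      stop("group ", groups[gi], " has fewer than 2 genotyped descendants")
    A22g <- build_A22(ped, ids)
    one <- rep(1, length(ids))
    w <- solve(A22g, one)
    M <- geno$dosage[match(ids, geno$ids), , drop = FALSE]
    M[is.na(M)] <- 1  # residual missingness -> heterozygote (p = 0.5)
    P[gi, ] <- as.numeric(crossprod(w, M)) / (2 * sum(w))
  }
  dev <- if (center == "half") P - 0.5 else P - rowMeans(P)
  G <- 8 * tcrossprod(dev) / m
  G <- (G + t(G)) / 2
  structure(G, class = c("ml_gamma", "matrix"), base_freq = P)
}

#' Metafounder-augmented pedigree relationships A(Gamma)
#'
#' Appends one pseudo-founder per group to the pedigree, with mutual
#' relationships `Gamma` (self-relationship `Gamma_jj`, i.e. metafounder
#' inbreeding `Gamma_jj - 1`), replaces every missing parent by its group's
#' metafounder, and evaluates the standard tabular recursion over the
#' augmented pedigree.  Dense; intended for desk-scale use and as substrate
#' for the sparse inverse.
#'
#' @param ped a group-assigned pedigree.
#' @param gamma groups-by-groups relationship matrix.
#' @return Dense symmetric matrix of order `n_groups + n_animals`, ordered
#'   metafounders first (dimnames = group labels then animal ids).
#' @export
build_AGamma <- function(ped, gamma) {
  groups <- check_grouped(ped)
  g <- length(groups); n <- nrow(ped)
  gamma <- as.matrix(gamma)
  stopifnot(nrow(gamma) == g, ncol(gamma) == g)
  # augmented codes: metafounders 1..g, animals g+1..g+n
  si <- ifelse(ped$sire > 0L, g + ped$sire, ped$sire_group)
  di <- ifelse(ped$dam  > 0L, g + ped$dam,  ped$dam_group)
  A <- tabular_A_cpp(c(integer(g), si), c(integer(g), di), gamma, g)
  dimnames(A) <- list(c(groups, ped$id), c(groups, ped$id))
  A
}

#' Sparse inverse of the metafounder relationship matrix
#'
#' Henderson-rule assembly over the metafounder-augmented pedigree: the
#' founder (metafounder) block contributes `Gamma^{-1}` (dense, g x g), and
#' each animal contributes `(1, -1/2, -1/2)/d_i` outer products with
#' `d_i = 1 - (a_ss + a_dd)/4`, where the parental self-relationships come
#' from the augmented tabular recursion (so metafounder "inbreeding"
#' `Gamma_jj - 1` propagates).  Metafounder rows are retained.
#'
#' @param ped a group-assigned pedigree.
#' @param gamma groups-by-groups relationship matrix; must be positive
#'   semi-definite.
#' @return Sparse symmetric matrix of order `n_animals + n_groups`, ordered
#'   animals first then metafounders (matching [build_Astar()]).
#' @export
build_AGamma_inverse <- function(ped, gamma) {
  groups <- check_grouped(ped)
  g <- length(groups); n <- nrow(ped)
  gamma <- as.matrix(gamma)
  ev <- eigen(gamma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("Gamma is not positive semi-definite; smallest eigenvalue ", min(ev))
  if (min(ev) < 1e-10)  # exact inversion needs PD; nudge a flat direction
    stop("Gamma is singular (smallest eigenvalue ", min(ev),
         "); the metafounder inverse requires a positive-definite Gamma")
  AG <- build_AGamma(ped, gamma)
  self_rel <- diag(AG)           # metafounders first, then animals
  si <- ifelse(ped$sire > 0L, ped$sire, n + ped$sire_group)
  di <- ifelse(ped$dam  > 0L, ped$dam,  n + ped$dam_group)
  # parental self-relationships in (animals, metafounders) ordering
  self_of <- function(ix) ifelse(ix > n, diag(gamma)[pmax(ix - n, 1L)],
                                 self_rel[g + pmin(ix, n)])
  d <- 1 - 0.25 * (self_of(si) + self_of(di))
  b <- 1 / d
  idx <- list(ped$code, si, di)
  coef <- c(1, -0.5, -0.5)
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  for (p in 1:3) for (q in 1:3) {
    trip_i <- c(trip_i, idx[[p]])
    trip_j <- c(trip_j, idx[[q]])
    trip_x <- c(trip_x, coef[p] * coef[q] * b)
  }
  gi <- solve(gamma)
  gidx <- as.matrix(expand.grid(seq_len(g), seq_len(g)))
  trip_i <- c(trip_i, n + gidx[, 1])
  trip_j <- c(trip_j, n + gidx[, 2])
  trip_x <- c(trip_x, as.numeric(gi))
  M <- sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                    dims = c(n + g, n + g),
                    dimnames = list(c(ped$id, groups), c(ped$id, groups)))
  forceSymmetric(drop0(M))
}

#' Metafounder-adjusted pedigree relationships among a subset (A22(Gamma))
#'
#' @param ped a group-assigned pedigree.
#' @param gamma groups-by-groups relationship matrix.
#' @param ids subset of animal ids (or codes).
#' @return Dense symmetric matrix over the subset.
#' @export
build_A22_gamma <- function(ped, gamma, ids) {
  groups <- check_grouped(ped)
  g <- length(groups)
  codes <- resolve_codes(ped, ids)
  AG <- build_AGamma(ped, gamma)
  AG[g + codes, g + codes, drop = FALSE]
}

#' @exportS3Method base::print
print.ml_gamma <- function(x, digits = 3, ...) {
  cat("Metafounder relationship matrix (", nrow(x), " groups)\n", sep = "")
  print(round(matrix(as.numeric(x), nrow(x), dimnames = dimnames(x)),
              digits), ...)
  invisible(x)
}
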