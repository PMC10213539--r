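#' Symmetric inverse that preserves the centering-mode attribute
#'
#' @param M dense symmetric positive-definite matrix.
#' @return `M^{-1}` with dimnames and the `freq_mode` attribute of `M`.
#' @export
sym_inverse <- function(M) {
  out <- chol2inv(chol(M))
  dimnames(out) <- dimnames(M)
  attr(out, "freq_mode") <- attr(M, "freq_mode")
  out
}

#' Assemble an H-inverse operator for single-step evaluation
#'
#' Combines a pedigree-side inverse with genomic information in one of four
#' flavors:
#' \describe{
#'   \item{standard}{`H^{-1} = A^{-1} + [0, 0; 0, G^{-1} - A22^{-1}]`.}
#'   \item{upg1}{unknown-parent groups in A, A22 and G: base `A*` plus the
#'     Quaas-Pollak-transformed correction
#'     `[C, -C Q2; -Q2' C, Q2' C Q2]` with `C = G^{-1} - A22^{-1}`.}
#'   \item{upg2}{groups related to A and A22 only: base `A*` plus
#'     `[G^{-1} - A22^{-1}, A22^{-1} Q2; Q2' A22^{-1}, -Q2' A22^{-1} Q2]`,
#'     i.e. the genomic part carries no group structure.}
#'   \item{mf}{metafounders: base `A(Gamma)^{-1}` plus
#'     `G0.5^{-1} - A22(Gamma)^{-1}` on the genotyped block; group blocks
#'     untouched (the metafounder structure lives inside `A(Gamma)`).}
#' }
#' The genotyped block is located by the rownames of `ginv` inside the
#' rownames of `ainv`.
#'
#' @param flavor one of `"standard"`, `"upg1"`, `"upg2"`, `"mf"`.
#' @param ainv pedigree-side sparse inverse: `A^{-1}` (standard), `A*`
#'   (upg1/upg2) or `A(Gamma)^{-1}` (mf); the latter two carry
#'   `n_groups` trailing group rows.
#' @param ginv inverse of the (blended) genomic relationship matrix over the
#'   genotyped animals, with a `freq_mode` attribute (see [sym_inverse()]);
#'   `NULL` for a pedigree-only operator.
#' @param a22inv inverse of the pedigree relationships among the genotyped
#'   animals (`A22` or `A22(Gamma)`).
#' @param Q full animals-by-groups contribution matrix (required for upg
#'   flavors).
#' @param n_groups number of trailing group rows in `ainv` (upg/mf flavors).
#' @return Sparse symmetric matrix with attributes `flavor` and `n_groups`.
#' @export
build_hinv <- function(flavor = c("standard", "upg1", "upg2", "mf"),
                       ainv, ginv = NULL, a22inv = NULL, Q = NULL,
                       n_groups = 0L) {
  flavor <- match.arg(flavor)
  H <- as(as(ainv, "generalMatrix"), "CsparseMatrix")
  ids <- rownames(H)
  if (flavor %in% c("upg1", "upg2", "mf")) {
    if (n_groups < 1L) stop("flavor ", flavor, " requires n_groups >= 1")
  } else if (n_groups != 0L) stop("standard flavor takes no group rows")
  n <- nrow(H) - n_groups
  if (!is.null(ginv)) {
    fm <- attr(ginv, "freq_mode")
    if (flavor == "mf" && !identical(fm, "half"))
      stop("mf flavor requires a 0.5-centered G (freq_mode = 'half')")
    if (flavor != "mf" && identical(fm, "half"))
      stop("flavor ", flavor, " requires an observed-frequency G")
    if (is.null(a22inv)) stop("a22inv required when ginv is supplied")
    gidx <- match(rownames(ginv), ids[seq_len(n)])
    if (anyNA(gidx)) stop("genotyped animal absent from pedigree operator")
    if (!identical(rownames(ginv), rownames(a22inv)))
      stop("ginv and a22inv must cover the same animals in the same order")
    Cg <- ginv - a22inv
    add_block <- function(H, ri, ci, B) {
      B <- as.matrix(B)
      tr <- expand.grid(i = ri, j = ci)
      H + sparseMatrix(i = tr$i, j = tr$j, x = as.numeric(B),
                       dims = dim(H), dimnames = dimnames(H))
    }
    H <- add_block(H, gidx, gidx, Cg)
    if (flavor %in% c("upg1", "upg2")) {
      if (is.null(Q)) stop("Q required for UPG flavors")
      Q2 <- as.matrix(Q)[gidx, , drop = FALSE]
      grows <- n + seq_len(n_groups)
      if (flavor == "upg1") {
        CQ <- Cg %*% Q2
        H <- add_block(H, gidx, grows, -CQ)
        H <- add_block(H, grows, gidx, -t(CQ))
        H <- add_block(H, grows, grows, crossprod(Q2, CQ))
      } else {
        AQ <- a22inv %*% Q2
        H <- add_block(H, gidx, grows, AQ)
        H <- add_block(H, grows, gidx, t(AQ))
        H <- add_block(H, grows, grows, -crossprod(Q2, AQ))
      }
    }
  }
  H <- forceSymmetric((H + t(H)) / 2)
  structure(list(M = H, flavor = flavor, n_groups = as.integer(n_groups),
                 ids = ids[seq_len(n)],
                 group_labels = if (n_groups > 0) ids[n + seq_len(n_groups)]
                                else character(0)),
            class = "ml_hinv")
}

#' @exportS3Method base::print
print.ml_hinv <- function(x, ...) {
  cat("ml_hinv [", x$flavor, "]: ", length(x$ids), " animals",
      if (x$n_groups > 0) paste0(" + ", x$n_groups, " groups"), "\n", sep = "")
  invisible(x)
}
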