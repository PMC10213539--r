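#' Specify a multi-trait mixed model
#'
#' Model per trait: `y = Xb + Wc + Zu (+ ZQg) + e` with fixed effects `b`
#' (contemporary groups, covariates), random litter effects `c`, additive
#' effects `u` (with an H-inverse of the chosen flavor) and, for
#' unknown-parent-group flavors, group effects `g` entering the design
#' through the base-contribution matrix `Q`.
#'
#' @param traits ordered character vector of trait column names.
#' @param fixed named list of one-sided formulas (one per trait) over columns
#'   of the phenotype table, e.g. `list(adg = ~ cg, bf = ~ cg + offtest_wt)`.
#' @param G0 additive genetic covariance matrix across traits (symmetric PD).
#' @param R0 residual covariance matrix across traits (symmetric PD).
#' @param L0 litter-effect covariance matrix across traits, or `NULL` to omit
#'   the litter effect.
#' @param animal_col,litter_col column names in the phenotype table.
#' @return An object of class `ml_model_spec`.
#' @export
model_spec <- function(traits, fixed, G0, R0, L0 = NULL,
                       animal_col = "animal", litter_col = "litter") {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  t <- length(traits)
  stopifnot(all(dim(G0) == t), all(dim(R0) == t))
  if (!all(traits %in% names(fixed)))
    stop("a fixed-effect formula is required for every trait")
  check_pd <- function(M, nm) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " is not positive definite")
  }
  check_pd(G0, "G0"); check_pd(R0, "R0")
  if (!is.null(L0)) { L0 <- as.matrix(L0); stopifnot(all(dim(L0) == t)); check_pd(L0, "L0") }
  structure(list(traits = traits, fixed = fixed, G0 = G0, R0 = R0, L0 = L0,
                 animal_col = animal_col, litter_col = litter_col),
            class = "ml_model_spec")
}

#' @noRd
safe_model_matrix <- function(formula, data, active) {
  # evaluate a fixed-effect design on all rows; rows outside `active` may
  # carry NA covariates, which are neutralised (their residual weight is 0)
  vars <- all.vars(formula)
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stop("fixed-effect column not found: ", v)
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      x[is.na(x)] <- levels(x)[1]
    } else {
      x[is.na(x)] <- 0
    }
    data[[v]] <- x
  }
  Matrix::sparse.model.matrix(formula, data = data)
}

#' Assemble multi-trait mixed-model equations
#'
#' Builds the symmetric sparse coefficient matrix and right-hand side for the
#' model in [model_spec()].  Missing trait records are handled through
#' per-record residual patterns: each record contributes the inverse of the
#' residual covariance restricted to its observed traits.  The additive
#' penalty is `G0^{-1} (x) Hp`, where for UPG flavors `Hp` is the H-inverse
#' re-expressed in the coordinates of the model equation (animal solutions
#' are deviations from their group expectation, and records load on group
#' columns through `Q`), so that `GEBV = Qg + u`.
#'
#' @param spec an `ml_model_spec`.
#' @param pheno phenotype data frame: animal id column, one column per trait
#'   (`NA` = missing), fixed-effect columns, litter column if used.
#' @param hinv an `ml_hinv` from [build_hinv()].
#' @param Q full animals-by-groups matrix (upg flavors only).
#' @param group_ridge small diagonal added to group equations for
#'   identifiability (they are otherwise confounded with an intercept);
#'   scaled by the largest diagonal of the system.
#' @return List of class `ml_mme`: coefficient matrix `C`, right-hand side
#'   `rhs`, unknown layout, and metadata needed to extract solutions.
#' @export
assemble_mme <- function(spec, pheno, hinv, Q = NULL, group_ridge = 1e-8) {
  stopifnot(inherits(spec, "ml_model_spec"), inherits(hinv, "ml_hinv"))
  tn <- length(spec$traits)
  nrec <- nrow(pheno)
  ids <- hinv$ids
  n <- length(ids)
  g <- hinv$n_groups
  N <- n + g
  upg <- hinv$flavor %in% c("upg1", "upg2")
  if (upg && is.null(Q)) stop("Q required for UPG flavors")

  acode <- match(as.character(pheno[[spec$animal_col]]), ids)
  if (anyNA(acode)) stop("phenotype row with animal absent from pedigree")

  # penalty in model coordinates: S' H* S with S = [I, Q; 0, I]
  Hp <- hinv$M
  if (upg) {
    S <- rbind(cbind(Diagonal(n), as(as.matrix(Q), "CsparseMatrix")),
               cbind(sparseMatrix(i = integer(0), j = integer(0),
                                  dims = c(g, n)), Diagonal(g)))
    Hp <- t(S) %*% Hp %*% S
  }
  Hp <- forceSymmetric(drop0(Hp, tol = 1e-14))

  use_litter <- !is.null(spec$L0)
  if (use_litter) {
    lit <- factor(pheno[[spec$litter_col]])
    nlit <- nlevels(lit)
    W <- sparseMatrix(i = seq_len(nrec), j = as.integer(lit),
                      dims = c(nrec, nlit))
  } else nlit <- 0L

  # per-trait design matrices over the full record set
  obs <- sapply(spec$traits, function(tr) !is.na(pheno[[tr]]))
  obs <- matrix(obs, nrow = nrec)
  X <- vector("list", tn)
  nfix <- integer(tn)
  for (t in seq_len(tn)) {
    X[[t]] <- safe_model_matrix(spec$fixed[[spec$traits[t]]], pheno, obs[, t])
    nfix[t] <- ncol(X[[t]])
  }
  # additive incidence: animal column; UPG flavors also load Q-row on groups
  Zi <- seq_len(nrec); Zj <- acode; Zx <- rep(1, nrec)
  if (upg) {
    Q2r <- as.matrix(Q)[acode, , drop = FALSE]
    nz <- which(Q2r != 0, arr.ind = TRUE)
    Zi <- c(Zi, nz[, 1]); Zj <- c(Zj, n + nz[, 2]); Zx <- c(Zx, Q2r[nz])
  }
  Z <- sparseMatrix(i = Zi, j = Zj, x = Zx, dims = c(nrec, N))

  # layout: per trait [fixed | litter | additive(N)]
  blk <- nfix + nlit + N
  off <- c(0, cumsum(blk))
  ntot <- off[tn + 1]
  col_fix <- lapply(seq_len(tn), function(t) off[t] + seq_len(nfix[t]))
  col_lit <- lapply(seq_len(tn), function(t)
    if (use_litter) off[t] + nfix[t] + seq_len(nlit) else integer(0))
  col_add <- lapply(seq_len(tn), function(t) off[t] + nfix[t] + nlit + seq_len(N))

  D <- vector("list", tn)
  for (t in seq_len(tn)) {
    parts <- list(X[[t]])
    if (use_litter) parts <- c(parts, list(W))
    parts <- c(parts, list(Z))
    Dt <- do.call(cbind, parts)
    # embed into full layout
    pad_l <- off[t]
    pad_r <- ntot - off[t + 1]
    D[[t]] <- cbind(
      sparseMatrix(i = integer(0), j = integer(0), dims = c(nrec, pad_l)),
      Dt,
      sparseMatrix(i = integer(0), j = integer(0), dims = c(nrec, pad_r)))
  }

  # residual weights per record from the observed-trait pattern
  Wts <- array(0, dim = c(nrec, tn, tn))
  pat_key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  for (key in unique(pat_key)) {
    rows <- which(pat_key == key)
    p <- obs[rows[1], ]
    if (!any(p)) next
    Ri <- matrix(0, tn, tn)
    Ri[p, p] <- solve(spec$R0[p, p, drop = FALSE])
    for (t in seq_len(tn)) for (s in seq_len(tn))
      Wts[rows, t, s] <- Ri[t, s]
  }

  y0 <- sapply(spec$traits, function(tr) {
    z <- pheno[[tr]]; z[is.na(z)] <- 0; z
  })
  y0 <- matrix(y0, nrow = nrec)

  C <- sparseMatrix(i = integer(0), j = integer(0), dims = c(ntot, ntot))
  rhs <- numeric(ntot)
  for (t in seq_len(tn)) for (s in t:tn) {
    w <- Wts[, t, s]
    if (all(w == 0)) next
    B <- crossprod(D[[t]], Diagonal(x = w) %*% D[[s]])
    C <- C + B
    if (s > t) C <- C + t(B)
    rhs <- rhs + as.numeric(crossprod(D[[t]], w * y0[, s]))
    if (s > t) rhs <- rhs + as.numeric(crossprod(D[[s]], w * y0[, t]))
  }

  G0i <- solve(spec$G0)
  for (t in seq_len(tn)) for (s in seq_len(tn)) {
    if (G0i[t, s] == 0) next
    C <- C + embed_block(G0i[t, s] * Hp, col_add[[t]], col_add[[s]], ntot)
  }
  if (use_litter) {
    L0i <- solve(spec$L0)
    for (t in seq_len(tn)) for (s in seq_len(tn)) {
      if (L0i[t, s] == 0) next
      C <- C + embed_block(L0i[t, s] * Diagonal(nlit), col_lit[[t]],
                           col_lit[[s]], ntot)
    }
  }
  if (upg && group_ridge > 0) {
    gcols <- unlist(lapply(col_add, function(cc) cc[n + seq_len(g)]))
    eps <- group_ridge * max(diag(C))
    C <- C + sparseMatrix(i = gcols, j = gcols, x = eps, dims = c(ntot, ntot))
  }
  structure(list(C = forceSymmetric(C), rhs = rhs, spec = spec,
                 flavor = hinv$flavor, ids = ids,
                 group_labels = hinv$group_labels, n = n, g = g,
                 col_fix = col_fix, col_lit = col_lit, col_add = col_add,
                 fix_names = lapply(X, colnames),
                 litter_levels = if (use_litter) levels(lit) else NULL,
                 Q = if (upg) as.matrix(Q) else NULL),
            class = "ml_mme")
}

#' @noRd
embed_block <- function(B, rows, cols, ntot) {
  B <- as(as(B, "generalMatrix"), "TsparseMatrix")
  sparseMatrix(i = rows[B@i + 1L], j = cols[B@j + 1L], x = B@x,
               dims = c(ntot, ntot))
}

#' Solve assembled mixed-model equations
#'
#' Direct sparse Cholesky solve by default, with a Jacobi-preconditioned
#' conjugate-gradient solver as the alternative (or fallback when the
#' factorisation fails).  Deterministic.
#'
#' @param sys an `ml_mme` from [assemble_mme()].
#' @param method `"direct"` or `"pcg"`.
#' @param tol relative-residual convergence tolerance for PCG.
#' @param maxit maximum PCG iterations.
#' @return An `ml_evaluation`: per-trait solution lists `b`, `c`, `u`
#'   (animals, named), `gg` (group solutions), a long-format `gebv` table,
#'   and a `convergence` record.
#' @export
solve_mme <- function(sys, method = c("direct", "pcg"), tol = 1e-10,
                      maxit = 5000L) {
  method <- match.arg(method)
  C <- sys$C; rhs <- sys$rhs
  # unknowns with an empty equation (e.g. fixed-effect levels whose records
  # were all removed in a reduced run) are constrained to zero
  active <- Matrix::diag(C) > 0
  Ca <- C[active, active, drop = FALSE]
  ra <- rhs[active]
  xa <- NULL; conv <- list(method = method, n_inactive = sum(!active))
  if (method == "direct") {
    xa <- tryCatch({
      ch <- Matrix::Cholesky(forceSymmetric(Ca), LDL = TRUE, perm = TRUE)
      out <- as.numeric(Matrix::solve(ch, ra))
      res <- sqrt(sum((as.numeric(Ca %*% out) - ra)^2)) /
        max(sqrt(sum(ra^2)), .Machine$double.eps)
      if (!all(is.finite(out)) || res > 1e-6) NULL else out
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(xa)) {
      conv$method <- "pcg (direct factorisation failed)"
      method <- "pcg"
    }
  }
  if (is.null(xa)) {
    pc <- pcg_solve(Ca, ra, tol = tol, maxit = maxit)
    xa <- pc$x
    conv$iterations <- pc$iterations
    conv$residual <- pc$residual
    if (!pc$converged)
      stop("PCG did not converge in ", maxit, " iterations; residual trace: ",
           paste(signif(utils::tail(pc$trace, 5), 3), collapse = ", "))
  }
  x <- numeric(length(rhs))
  x[active] <- xa
  parse_solution(sys, x, conv)
}

#' @noRd
pcg_solve <- function(C, b, tol = 1e-10, maxit = 5000L) {
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  trace <- numeric(0)
  it <- 0L
  repeat {
    res <- sqrt(sum(r^2)) / max(nb, .Machine$double.eps)
    trace <- c(trace, res)
    if (res < tol || it >= maxit) break
    Ap <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(x = x, iterations = it, residual = utils::tail(trace, 1),
       converged = utils::tail(trace, 1) < tol, trace = trace)
}

#' @noRd
parse_solution <- function(sys, x, conv) {
  tn <- length(sys$spec$traits)
  b <- cc <- u <- gg <- stats::setNames(vector("list", tn), sys$spec$traits)
  for (t in seq_len(tn)) {
    b[[t]] <- stats::setNames(x[sys$col_fix[[t]]], sys$fix_names[[t]])
    if (length(sys$col_lit[[t]]))
      cc[[t]] <- stats::setNames(x[sys$col_lit[[t]]], sys$litter_levels)
    add <- x[sys$col_add[[t]]]
    u[[t]] <- stats::setNames(add[seq_len(sys$n)], sys$ids)
    if (sys$g > 0)
      gg[[t]] <- stats::setNames(add[sys$n + seq_len(sys$g)], sys$group_labels)
  }
  res <- structure(list(b = b, c = cc, u = u, g = gg, flavor = sys$flavor,
                        Q = sys$Q, ids = sys$ids, traits = sys$spec$traits,
                        convergence = conv),
                   class = "ml_evaluation")
  res$gebv <- extract_gebv(res)
  res
}

#' Genomic estimated breeding values from a solved evaluation
#'
#' For the standard and metafounder flavors the additive solutions are the
#' GEBV directly; for unknown-parent-group flavors the group expectation is
#' added back: `GEBV = Qg + u`.
#'
#' @param result an `ml_evaluation`.
#' @param Q optional override of the stored base-contribution matrix.
#' @return Long data frame: `animal`, `trait`, `gebv`.
#' @export
extract_gebv <- function(result, Q = NULL) {
  stopifnot(inherits(result, "ml_evaluation"))
  Q <- if (is.null(Q)) result$Q else as.matrix(Q)
  upg <- result$flavor %in% c("upg1", "upg2")
  if (upg && is.null(Q)) stop("Q required to reconstruct UPG GEBV")
  out <- do.call(rbind, lapply(result$traits, function(tr) {
    val <- result$u[[tr]]
    if (upg) val <- val + as.numeric(Q %*% result$g[[tr]])
    data.frame(animal = result$ids, trait = tr, gebv = unname(val),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @exportS3Method base::print
print.ml_evaluation <- function(x, ...) {
  cat("ml_evaluation [", x$flavor, "]: ", length(x$ids), " animals, traits: ",
      paste(x$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}
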