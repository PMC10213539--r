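#' @useDynLib mlgblup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats cov var rnorm runif rbinom rpois pt sd complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Construct a recoded, topologically sorted pedigree
#'
#' Takes raw animal/sire/dam records (opaque string identifiers) and returns a
#' pedigree in which animals carry dense integer codes `1..n` such that every
#' parent precedes its offspring.  Unknown parents are retained as missing
#' (internal code 0).  Cycles (an animal its own ancestor) and duplicated
#' animal identifiers are hard errors.
#'
#' @param df data frame with at least animal/sire/dam columns.
#' @param col_map named list mapping the roles `animal`, `sire`, `dam`, and
#'   optionally `line`, `birth_year`, `genotyped` to column names of `df`.
#' @param missing character vector of sentinels denoting an unknown parent;
#'   `NA` is always treated as unknown.
#' @return An object of class `ml_pedigree`: a data frame with columns
#'   `code`, `id`, `sire`, `dam` (integer codes, 0 = unknown), `line`,
#'   `birth_year`, `genotyped`, sorted by `code`.
#' @export
as_pedigree <- function(df,
                        col_map = list(animal = "animal", sire = "sire",
                                       dam = "dam", line = "line",
                                       birth_year = "birth_year",
                                       genotyped = "genotyped"),
                        missing = c("0", "")) {
  get_col <- function(role, default = NULL) {
    nm <- col_map[[role]]
    if (!is.null(nm) && nm %in% names(df)) df[[nm]] else default
  }
  id <- as.character(get_col("animal"))
  if (is.null(id)) stop("animal column not found")
  if (anyDuplicated(id))
    stop("duplicate animal id: ", id[duplicated(id)][1])
  n <- length(id)
  clean_parent <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% missing] <- NA_character_
    x
  }
  sire_id <- clean_parent(get_col("sire", rep(NA_character_, n)))
  dam_id  <- clean_parent(get_col("dam",  rep(NA_character_, n)))
  bad <- setdiff(c(sire_id, dam_id), c(id, NA_character_))
  if (length(bad))
    stop("parents absent from animal records: ", paste(utils::head(bad, 5), collapse = ", "))

  pos <- match(id, id)
  s_pos <- match(sire_id, id)  # NA for unknown
  d_pos <- match(dam_id, id)

  # Kahn topological sort
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s_pos[i], d_pos[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- integer(n)
  nq <- 0L
  for (i in which(indeg == 0L)) { nq <- nq + 1L; queue[nq] <- i }
  hd <- 1L
  while (hd <= nq) {
    v <- queue[hd]; hd <- hd + 1L
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) { nq <- nq + 1L; queue[nq] <- k }
    }
  }
  order <- queue[seq_len(nq)]
  if (length(order) < n) {
    on_cycle <- setdiff(seq_len(n), order)
    stop("pedigree cycle detected involving animal: ", id[on_cycle[1]])
  }
  code <- integer(n)
  code[order] <- seq_len(n)

  line <- get_col("line", rep(NA_character_, n))
  by   <- get_col("birth_year", rep(NA_integer_, n))
  gt   <- get_col("genotyped", rep(FALSE, n))
  gt   <- as.logical(as.integer(as.numeric(gt)))

  out <- data.frame(
    code = seq_len(n),
    id = id[order],
    sire = ifelse(is.na(s_pos[order]), 0L, code[s_pos[order]]),
    dam  = ifelse(is.na(d_pos[order]), 0L, code[d_pos[order]]),
    line = as.character(line)[order],
    birth_year = as.integer(by)[order],
    genotyped = gt[order],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ml_pedigree", "data.frame")
  out
}

#' Read a pedigree from a delimited text file
#'
#' @param path path to a delimited file with a header row.
#' @param col_map,missing see [as_pedigree()].
#' @param sep field separator (default comma).
#' @return An `ml_pedigree` (see [as_pedigree()]).
#' @export
read_pedigree <- function(path,
                          col_map = list(animal = "animal", sire = "sire",
                                         dam = "dam", line = "line",
                                         birth_year = "birth_year",
                                         genotyped = "genotyped"),
                          missing = c("0", ""), sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  as_pedigree(df, col_map = col_map, missing = missing)
}

#' @exportS3Method base::print
print.ml_pedigree <- function(x, ...) {
  cat("ml_pedigree:", nrow(x), "animals,",
      sum(x$sire == 0L | x$dam == 0L), "with >=1 unknown parent,",
      sum(x$genotyped), "genotyped\n")
  invisible(x)
}

#' Per-animal inbreeding coefficients
#'
#' Recursive Meuwissen-Luo computation over the recoded pedigree; unknown
#' parents contribute as unrelated, non-inbred base animals, so founders have
#' F = 0 and any animal's F equals half the numerator relationship of its
#' parents.
#'
#' @param ped an `ml_pedigree`.
#' @return Numeric vector of inbreeding coefficients, named by animal id.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "ml_pedigree"))
  F <- ml_inbreeding_cpp(ped$sire, ped$dam)
  names(F) <- ped$id
  F
}

#' Mendelian sampling variances for Henderson-rule assembly
#' @noRd
mendelian_variance <- function(ped, F = compute_inbreeding(ped)) {
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0, F[pmax(s, 1L)], NA)
  Fd <- ifelse(d > 0, F[pmax(d, 1L)], NA)
  ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
         ifelse(s > 0, 0.75 - 0.25 * Fs,
                ifelse(d > 0, 0.75 - 0.25 * Fd, 1)))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson-rule assembly with inbreeding: animal i contributes
#' `(1, -1/2, -1/2) / d_i` outer products over (i, sire, dam), where `d_i` is
#' the Mendelian sampling variance.  At most nine nonzero contributions per
#' animal.
#'
#' @param ped an `ml_pedigree`.
#' @param F optional precomputed inbreeding vector.
#' @return Sparse symmetric matrix (`dsCMatrix`) of order `nrow(ped)` with
#'   dimnames = animal ids.
#' @export
build_A_inverse <- function(ped, F = compute_inbreeding(ped)) {
  stopifnot(inherits(ped, "ml_pedigree"))
  n <- nrow(ped)
  d <- mendelian_variance(ped, F)
  ii <- jj <- xx <- vector("list", 4L)
  s <- ped$sire; dm <- ped$dam; a <- ped$code
  b <- 1 / d
  # coefficient list per animal: (a, +1), (s, -1/2), (d, -1/2)
  idx <- list(a, s, dm)
  coef <- list(rep(1, n), rep(-0.5, n), rep(-0.5, n))
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  for (p in 1:3) for (q in 1:3) {
    keep <- idx[[p]] > 0 & idx[[q]] > 0
    trip_i <- c(trip_i, idx[[p]][keep])
    trip_j <- c(trip_j, idx[[q]][keep])
    trip_x <- c(trip_x, (coef[[p]] * coef[[q]] * b)[keep])
  }
  M <- sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n),
                    dimnames = list(ped$id, ped$id))
  forceSymmetric(drop0(M))
}

#' Products with the numerator relationship matrix without forming it
#'
#' Colleau's indirect method: `A %*% V` via the factorisation
#' `A = T D T'` over the recoded pedigree.
#'
#' @param ped an `ml_pedigree`.
#' @param V numeric matrix (or vector) with one row per animal, in code order.
#' @param F optional precomputed inbreeding vector.
#' @return `A %*% V` as a dense matrix.
#' @export
A_times <- function(ped, V, F = compute_inbreeding(ped)) {
  stopifnot(inherits(ped, "ml_pedigree"))
  V <- as.matrix(V)
  A_times_V_cpp(ped$sire, ped$dam, as.numeric(F), V)
}

#' Pedigree relationships among a subset of animals (A22)
#'
#' Exact pairwise numerator relationships among a named subset (typically the
#' genotyped animals), computed column-by-column by Colleau's indirect method;
#' no approximation.
#'
#' @param ped an `ml_pedigree`.
#' @param ids character vector of animal ids (or integer codes) in the subset.
#' @return Dense symmetric matrix with dimnames = subset ids, in the order
#'   given.
#' @export
build_A22 <- function(ped, ids) {
  stopifnot(inherits(ped, "ml_pedigree"))
  codes <- resolve_codes(ped, ids)
  n <- nrow(ped); k <- length(codes)
  if (k == 0L) stop("empty subset")
  F <- compute_inbreeding(ped)
  E <- matrix(0, n, k)
  E[cbind(codes, seq_len(k))] <- 1
  AV <- A_times_V_cpp(ped$sire, ped$dam, as.numeric(F), E)
  A22 <- AV[codes, , drop = FALSE]
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ped$id[codes], ped$id[codes])
  A22
}

#' Dense tabular numerator relationship matrix
#'
#' Reference tabular-method computation (used at desk scale and as substrate
#' for metafounder-augmented relationships elsewhere).
#'
#' @param ped an `ml_pedigree`.
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
tabular_A <- function(ped) {
  stopifnot(inherits(ped, "ml_pedigree"))
  A <- tabular_A_cpp(ped$sire, ped$dam, matrix(0, 0, 0), 0L)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' @noRd
resolve_codes <- function(ped, ids) {
  if (is.numeric(ids)) {
    codes <- as.integer(ids)
    if (any(codes < 1L | codes > nrow(ped))) stop("code out of range")
  } else {
    codes <- match(as.character(ids), ped$id)
    if (anyNA(codes))
      stop("unknown animal in subset: ", ids[which(is.na(codes))[1]])
  }
  codes
}

#' Truncate a pedigree by birth year
#'
#' Removes animals born before `year`; retained animals whose parents were
#' removed are re-founded (parents set to unknown).  This mirrors the common
#' practice of cutting deep pedigrees before estimating base-population
#' parameters; re-founding orphaned animals is one interpretation of that
#' practice, flagged as such.
#'
#' @param ped an `ml_pedigree` with `birth_year` available.
#' @param year animals with `birth_year < year` are dropped.
#' @return A new `ml_pedigree`.
#' @export
truncate_pedigree <- function(ped, year) {
  stopifnot(inherits(ped, "ml_pedigree"))
  if (all(is.na(ped$birth_year))) stop("birth_year not available")
  keep <- !is.na(ped$birth_year) & ped$birth_year >= year
  df <- data.frame(animal = ped$id[keep],
                   sire = ped$id[ifelse(ped$sire > 0, ped$sire, NA)][keep],
                   dam = ped$id[ifelse(ped$dam > 0, ped$dam, NA)][keep],
                   line = ped$line[keep], birth_year = ped$birth_year[keep],
                   genotyped = as.integer(ped$genotyped[keep]),
                   stringsAsFactors = FALSE)
  kept_ids <- df$animal
  df$sire[!(df$sire %in% kept_ids)] <- NA
  df$dam[!(df$dam %in% kept_ids)] <- NA
  as_pedigree(df)
}
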