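# Independent reference implementations used as oracles.  These are written
# from the textbook definitions in plain R and deliberately share no code
# with the package internals they check.

# tabular numerator relationship matrix over a recoded pedigree
# (sire/dam integer codes, 0 = unknown, parents precede offspring)
oracle_tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0
        if (s > 0) v <- v + 0.5 * A[s, j]
        if (d > 0) v <- v + 0.5 * A[d, j]
        A[i, j] <- A[j, i] <- v
      }
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

# tabular recursion over a metafounder-augmented pedigree: first g codes are
# pseudo-founders with relationship block `gamma`
oracle_tabular_A_gamma <- function(sire, dam, gamma) {
  g <- nrow(gamma)
  n <- length(sire)
  A <- matrix(0, g + n, g + n)
  A[seq_len(g), seq_len(g)] <- gamma
  for (i in seq_len(n)) {
    ii <- g + i
    s <- sire[i]; d <- dam[i]   # already augmented codes in 1..g+n
    for (j in seq_len(ii - 1)) {
      A[ii, j] <- A[j, ii] <- 0.5 * (A[s, j] + A[d, j])
    }
    A[ii, ii] <- 1 + 0.5 * A[s, d]
  }
  A
}

# expected base-group contributions by plain memoised recursion over ids
oracle_Q <- function(ped) {
  groups <- attr(ped, "groups")
  memo <- list()
  rec <- function(i) {
    key <- as.character(i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    half <- function(par, grp) {
      if (par > 0) 0.5 * rec(par) else {
        e <- numeric(length(groups)); e[grp] <- 0.5; e
      }
    }
    q <- half(ped$sire[i], ped$sire_group[i]) +
      half(ped$dam[i], ped$dam_group[i])
    memo[[key]] <<- q
    q
  }
  t(vapply(seq_len(nrow(ped)), rec, numeric(length(groups))))
}

# Monte-Carlo gene-dropping estimate of base-group origin proportions for
# one animal: follow a random ancestral path per drop
oracle_genedrop_Q <- function(ped, code, ndrops = 1e5) {
  groups <- attr(ped, "groups")
  counts <- numeric(length(groups))
  for (r in seq_len(ndrops)) {
    i <- code
    repeat {
      if (stats::runif(1) < 0.5) {
        nxt <- ped$sire[i]; grp <- ped$sire_group[i]
      } else {
        nxt <- ped$dam[i]; grp <- ped$dam_group[i]
      }
      if (nxt == 0L) { counts[grp] <- counts[grp] + 1; break }
      i <- nxt
    }
  }
  counts / ndrops
}

# random valid pedigree generator for property tests
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            missing_rate = 0, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  sex <- rep(c("M", "F"), length.out = n)
  for (i in seq((n_founders + 1L), n)) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- males[sample.int(length(males), 1)]
    dam[i] <- females[sample.int(length(females), 1)]
    if (missing_rate > 0) {
      if (runif(1) < missing_rate) sire[i] <- 0L
      if (runif(1) < missing_rate) dam[i] <- 0L
    }
  }
  df <- data.frame(animal = sprintf("A%04d", seq_len(n)),
                   sire = ifelse(sire > 0, sprintf("A%04d", sire), "0"),
                   dam = ifelse(dam > 0, sprintf("A%04d", dam), "0"),
                   line = rep("L1", n),
                   birth_year = 2000L + (seq_len(n) > n_founders),
                   genotyped = 0L, stringsAsFactors = FALSE)
  as_pedigree(df)
}

# tiny deterministic genotype fixture
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL, ids = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(ids)) ids <- sprintf("id%02d", seq_len(nrow(dosage)))
  genotype_set(dosage, data.frame(marker = sprintf("mk%03d", seq_len(m)),
                                  chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE), ids = ids)
}
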