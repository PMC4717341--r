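#' Pairwise sequence differences
#'
#' Counts nucleotide differences for every pair of sequences under pairwise
#' deletion: a site enters a pair's comparison only when both sequences carry
#' an unambiguous A/C/G/T there. The mean number of pairwise differences
#' k-hat is the raw (per-pair, not per-site) diversity: the sum of the
#' per-pair difference counts divided by the number of pairs, choose(n, 2).
#'
#' @param x a [alignment()] object with at least 2 sequences.
#' @return A list with `k_hat`, the symmetric integer matrix `diffs` and the
#'   matrix `compared` of per-pair compared-site counts.
#' @export
pairwise_differences <- function(x) {
  stopifnot(inherits(x, "coi_alignment"))
  code <- x$code
  n <- nrow(code)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  diffs <- matrix(0L, n, n, dimnames = list(x$ids, x$ids))
  compared <- diffs
  for (i in seq_len(n - 1L)) {
    a <- code[i, ]
    for (j in (i + 1L):n) {
      b <- code[j, ]
      ok <- !is.na(a) & !is.na(b)
      nc <- sum(ok)
      nd <- sum(a[ok] != b[ok])
      compared[i, j] <- compared[j, i] <- nc
      diffs[i, j] <- diffs[j, i] <- nd
    }
  }
  up <- upper.tri(diffs)
  list(k_hat = sum(diffs[up]) / choose(n, 2), diffs = diffs,
       compared = compared)
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity: the mean over sequence pairs of the
#' proportion of differing sites among the sites compared in that pair
#' (pairwise deletion). With no missing data this is exactly k-hat / L.
#' Pairs sharing no unambiguously called site are excluded with a warning;
#' if all pairs are excluded the value is undefined (`NA`).
#'
#' @param x a [alignment()] object with at least 2 sequences.
#' @return Nucleotide diversity per site (numeric scalar).
#' @export
nucleotide_diversity <- function(x) {
  pd <- pairwise_differences(x)
  up <- upper.tri(pd$diffs)
  d <- pd$diffs[up]
  nc <- pd$compared[up]
  usable <- nc > 0L
  if (!all(usable))
    warning(sum(!usable), " pair(s) with no comparable sites excluded from pi",
            call. = FALSE)
  if (!any(usable)) return(NA_real_)
  mean(d[usable] / nc[usable])
}

#' Segregating (polymorphic) sites
#'
#' A site is segregating when at least two distinct unambiguous bases occur
#' among the sequences at that alignment column; ambiguity codes, N and gaps
#' never create or suppress polymorphism.
#'
#' @param x a [alignment()] object with at least 2 sequences.
#' @return A list with the count `S` and `sites`, the 1-based positions.
#' @export
segregating_sites <- function(x) {
  stopifnot(inherits(x, "coi_alignment"))
  if (nrow(x$code) < 2L) stop("need at least 2 sequences", call. = FALSE)
  counts <- .base_counts(x$code)
  n_states <- rowSums(counts > 0L)
  sites <- which(n_states >= 2L)
  list(S = length(sites), sites = sites)
}

# L x 4 matrix of per-site counts of A,C,G,T among unambiguous bases
.base_counts <- function(code) {
  vapply(1:4, function(b) colSums(code == b, na.rm = TRUE),
         numeric(ncol(code)))
}

#' Per-sequence singleton counts
#'
#' `U[i]` is the number of segregating sites at which sequence i carries an
#' unambiguous base found in no other sequence. These are the ingredients of
#' the Ramos-Onsins-Rozas R2 statistic; note that at a site where n-1
#' sequences share a derived base, the lone ancestral carrier also holds a
#' singleton state.
#'
#' @param x a [alignment()] object with at least 2 sequences.
#' @return Integer vector of length n, named by sample id.
#' @export
singleton_counts <- function(x) {
  stopifnot(inherits(x, "coi_alignment"))
  code <- x$code
  n <- nrow(code)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  counts <- .base_counts(code)
  seg <- which(rowSums(counts > 0L) >= 2L)
  U <- integer(n)
  names(U) <- x$ids
  if (length(seg) == 0L) return(U)
  unique_state <- counts == 1L            # L x 4
  for (i in seq_len(n)) {
    b <- code[i, seg]
    ok <- !is.na(b)
    U[i] <- sum(unique_state[cbind(seg[ok], b[ok])])
  }
  U
}

# Tajima's (1989) constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D contrasts the mean number of pairwise differences k-hat with the
#' Watterson expectation S/a1; negative values indicate an excess of rare
#' variants (expansion or sweep), positive values an excess of intermediate
#' frequencies. The p-value assumes D ~ N(0, 1), two-sided. With S = 0 the
#' statistic is undefined and reported as `NA` (never imputed as 0).
#'
#' @param x a [alignment()] object; n >= 4 recommended for the normal
#'   approximation, n >= 2 required.
#' @return A list with `D`, two-sided `p`, and the inputs `S` and `k_hat`.
#' @export
tajimas_d <- function(x) {
  stopifnot(inherits(x, "coi_alignment"))
  n <- nrow(x$code)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  S <- segregating_sites(x)$S
  k_hat <- pairwise_differences(x)$k_hat
  if (S == 0L)
    return(list(D = NA_real_, p = NA_real_, S = 0L, k_hat = k_hat))
  cst <- tajima_constants(n)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0)   # variance collapses for n <= 3: D undefined, not 0
    return(list(D = NA_real_, p = NA_real_, S = S, k_hat = k_hat))
  D <- (k_hat - S / cst$a1) / sqrt(v)
  list(D = D, p = 2 * stats::pnorm(-abs(D)), S = S, k_hat = k_hat)
}

#' Ramos-Onsins-Rozas R2 statistic
#'
#' R2 = sqrt(mean((U_i - k_hat/2)^2)) / S, where U_i are the per-sequence
#' singleton counts. Low values arise when singletons sit where a star-like
#' (recently expanded) genealogy puts them; significance is assessed against
#' a neutral coalescent null conditioned on n and S (see [r2_test()]).
#' Undefined (`NA`) when S = 0.
#'
#' @param x a [alignment()] object with at least 2 sequences.
#' @return R2 (numeric scalar), `NA` if no segregating sites.
#' @export
r2_statistic <- function(x) {
  S <- segregating_sites(x)$S
  if (S == 0L) return(NA_real_)
  U <- singleton_counts(x)
  k_hat <- pairwise_differences(x)$k_hat
  sqrt(mean((U - k_hat / 2)^2)) / S
}

#' R2 expansion test with coalescent null
#'
#' Significance of the observed R2 is obtained from `B` standard neutral
#' constant-size coalescent simulations conditioned on the observed sample
#' size and number of segregating sites (fixed-S mutation dropping; no theta
#' estimate needed). The p-value is lower-tail - low R2 signals population
#' expansion - with the (r + 1)/(B + 1) Monte-Carlo correction so p is never
#' exactly zero.
#'
#' @param x a [alignment()] object.
#' @param B number of coalescent replicates (default 1000, minimum 100).
#' @return A list with `R2`, `p` and `B`. `NA`s when S = 0.
#' @export
r2_test <- function(x, B = 1000L) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  obs <- r2_statistic(x)
  if (is.na(obs)) return(list(R2 = NA_real_, p = NA_real_, B = B))
  n <- nrow(x$code)
  S <- segregating_sites(x)$S
  null <- r2_null_distribution(n, S, B)
  list(R2 = obs, p = (1 + sum(null <= obs)) / (B + 1), B = B)
}

#' Per-alignment diversity summary
#'
#' One row of summary statistics for an alignment: sample size, length,
#' segregating sites, mean pairwise differences, nucleotide diversity,
#' Tajima's D with its normal p-value and R2 with its coalescent p-value.
#'
#' @param x a [alignment()] object.
#' @param r2_reps coalescent replicates for the R2 p-value; `0` skips the
#'   simulation (the R2 statistic itself is still reported).
#' @return A one-row `data.frame` with columns `n, L, S, k_hat, pi, D, p_D,
#'   R2, p_R2`.
#' @export
diversity_stats <- function(x, r2_reps = 1000L) {
  stopifnot(inherits(x, "coi_alignment"))
  st <- .stats_code(x$code, r2_reps = r2_reps)
  data.frame(n = nrow(x$code), L = x$L, S = st[["S"]],
             k_hat = st[["k_hat"]], pi = st[["pi"]], D = st[["D"]],
             p_D = st[["p_D"]], R2 = st[["R2"]], p_R2 = st[["p_R2"]])
}

# single-pass core on the integer code matrix; the pipeline's hot path
.stats_code <- function(code, r2_reps = 0L) {
  n <- nrow(code)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  np <- as.integer(n * (n - 1L) / 2)
  d <- numeric(np); nc <- numeric(np)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    a <- code[i, ]
    ok_a <- !is.na(a)
    for (j in (i + 1L):n) {
      b <- code[j, ]
      ok <- ok_a & !is.na(b)
      k <- k + 1L
      nc[k] <- sum(ok)
      d[k] <- sum(a[ok] != b[ok])
    }
  }
  k_hat <- sum(d) / np
  usable <- nc > 0
  if (!all(usable))
    warning(sum(!usable), " pair(s) with no comparable sites excluded from pi",
            call. = FALSE)
  pi <- if (any(usable)) mean(d[usable] / nc[usable]) else NA_real_

  counts <- .base_counts(code)
  seg <- which(rowSums(counts > 0L) >= 2L)
  S <- length(seg)

  D <- p_D <- R2 <- p_R2 <- NA_real_
  if (S > 0L) {
    cst <- tajima_constants(n)
    v <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (v > 0) {
      D <- (k_hat - S / cst$a1) / sqrt(v)
      p_D <- 2 * stats::pnorm(-abs(D))
    }
    unique_state <- counts == 1L
    U <- numeric(n)
    for (i in seq_len(n)) {
      b <- code[i, seg]
      ok <- !is.na(b)
      U[i] <- sum(unique_state[cbind(seg[ok], b[ok])])
    }
    R2 <- sqrt(mean((U - k_hat / 2)^2)) / S
    if (r2_reps > 0L) {
      null <- r2_null_distribution(n, S, r2_reps)
      p_R2 <- (1 + sum(null <= R2)) / (r2_reps + 1)
    }
  }
  c(S = S, k_hat = k_hat, pi = pi, D = D, p_D = p_D, R2 = R2, p_R2 = p_R2)
}
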