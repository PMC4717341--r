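# Standard neutral constant-size coalescent for n lineages.
# Returns the 2n-2 non-root branches as disjoint leaf sets with lengths in
# coalescent units (a pair coalesces at rate 1). Lineage sets stay disjoint,
# so a merge is a concatenation.
.coal_branches <- function(n) {
  sets <- as.list(seq_len(n))
  len <- numeric(n)
  out_sets <- vector("list", 2L * n - 2L)
  out_len <- numeric(2L * n - 2L)
  k <- 0L
  j <- n
  while (j > 1L) {
    t <- stats::rexp(1L, rate = j * (j - 1) / 2)
    len <- len + t
    pr <- sample.int(j, 2L)
    for (p in pr) {
      k <- k + 1L
      out_sets[[k]] <- sets[[p]]
      out_len[k] <- len[p]
    }
    merged <- c(sets[[pr[1L]]], sets[[pr[2L]]])
    keep <- setdiff(seq_len(j), pr)
    sets <- c(sets[keep], list(merged))
    len <- c(len[keep], 0)
    j <- j - 1L
  }
  list(sets = out_sets, len = out_len)
}

#' Neutral coalescent replicate with a fixed number of segregating sites
#'
#' Simulates one standard neutral constant-size coalescent genealogy for `n`
#' lineages (exponential waiting times with rate j(j-1)/2 while j lineages
#' remain; uniformly random pair merged) and drops exactly `S` mutations on
#' it, each landing on a branch with probability proportional to branch
#' length (infinite-sites: one biallelic site per mutation, derived state
#' carried by the leaves below the branch). This is the null model behind
#' the R2 test, conditioned on the observed n and S rather than on theta.
#'
#' @param n number of sampled lineages (>= 2).
#' @param S number of segregating sites to place (>= 1).
#' @return An object of class `coal_replicate`: list with `n`, `S`,
#'   `tree_length` (total branch length, coalescent units), `derived` (an
#'   `n x S` logical incidence matrix: which leaves carry the derived state
#'   at each site) and `branch_sets`/`branch_len` describing the genealogy.
#' @examples
#' set.seed(1)
#' rep <- simulate_coalescent_fixed_s(10, 5)
#' colSums(rep$derived)  # derived counts, all in 1..n-1
#' @export
simulate_coalescent_fixed_s <- function(n, S) {
  stopifnot(n >= 2L, S >= 1L)
  br <- .coal_branches(n)
  hit <- sample.int(length(br$len), size = S, replace = TRUE, prob = br$len)
  derived <- matrix(FALSE, n, S)
  for (s in seq_len(S)) derived[br$sets[[hit[s]]], s] <- TRUE
  structure(list(n = n, S = S, tree_length = sum(br$len), derived = derived,
                 branch_sets = br$sets, branch_len = br$len),
            class = "coal_replicate")
}

# R2 computed directly from derived-allele counts of a fixed-S replicate.
# Folded singleton attribution: a site with derived count 1 gives one
# singleton to its carrier; derived count n-1 gives one to the lone
# ancestral carrier.
.r2_from_replicate <- function(n, S, derived) {
  d <- colSums(derived)
  k_hat <- sum(d * (n - d)) / choose(n, 2)
  U <- numeric(n)
  for (s in which(d == 1L)) U[which(derived[, s])] <- U[which(derived[, s])] + 1
  for (s in which(d == n - 1L)) U[which(!derived[, s])] <- U[which(!derived[, s])] + 1
  sqrt(mean((U - k_hat / 2)^2)) / S
}

#' Null distribution of R2 under the fixed-S neutral coalescent
#'
#' @param n sample size.
#' @param S segregating sites.
#' @param B number of replicates.
#' @return Numeric vector of `B` simulated R2 values.
#' @export
r2_null_distribution <- function(n, S, B) {
  stopifnot(n >= 2L, S >= 1L, B >= 1L)
  vapply(seq_len(B), function(b) {
    br <- .coal_branches(n)
    hit <- sample.int(length(br$len), size = S, replace = TRUE, prob = br$len)
    derived <- matrix(FALSE, n, S)
    for (s in seq_len(S)) derived[br$sets[[hit[s]]], s] <- TRUE
    .r2_from_replicate(n, S, derived)
  }, numeric(1L))
}

#' Convert a coalescent replicate to an alignment
#'
#' Materialises the replicate's biallelic sites as an A/T alignment (A =
#' ancestral, T = derived) padded with monomorphic A-sites up to length `L`,
#' so the fixed-S null can be pushed through the exact same code path as
#' observed data.
#'
#' @param rep a [simulate_coalescent_fixed_s()] replicate.
#' @param L total alignment length (>= `rep$S`).
#' @export
replicate_to_alignment <- function(rep, L = rep$S) {
  stopifnot(inherits(rep, "coal_replicate"), L >= rep$S)
  mat <- matrix("A", rep$n, L)
  mat[, seq_len(rep$S)][rep$derived] <- "T"
  alignment(paste0("sim", seq_len(rep$n)),
            apply(mat, 1L, paste, collapse = ""))
}
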