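# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals: everything works directly on the
# character matrix with explicit per-site loops.

BASES <- c("A", "C", "G", "T")

aln_chars <- function(x) x$mat

bf_pair_tables <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  comp <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    dd <- 0; cc <- 0
    for (s in seq_len(ncol(mat))) {
      a <- mat[i, s]; b <- mat[j, s]
      if ((a %in% BASES) && (b %in% BASES)) {
        cc <- cc + 1
        if (a != b) dd <- dd + 1
      }
    }
    d[i, j] <- d[j, i] <- dd
    comp[i, j] <- comp[j, i] <- cc
  }
  list(d = d, comp = comp)
}

bf_khat <- function(mat) {
  pt <- bf_pair_tables(mat)
  n <- nrow(mat)
  sum(pt$d[upper.tri(pt$d)]) / (n * (n - 1) / 2)
}

bf_pi <- function(mat) {
  pt <- bf_pair_tables(mat)
  up <- upper.tri(pt$d)
  d <- pt$d[up]; cc <- pt$comp[up]
  keep <- cc > 0
  if (!any(keep)) return(NA_real_)
  mean(d[keep] / cc[keep])
}

bf_segsites <- function(mat) {
  out <- integer(0)
  for (s in seq_len(ncol(mat))) {
    col <- mat[, s]
    states <- unique(col[col %in% BASES])
    if (length(states) >= 2) out <- c(out, s)
  }
  out
}

bf_singletons <- function(mat) {
  seg <- bf_segsites(mat)
  n <- nrow(mat)
  U <- integer(n)
  for (s in seg) {
    col <- mat[, s]
    for (i in seq_len(n)) {
      if (!(col[i] %in% BASES)) next
      if (sum(col == col[i], na.rm = TRUE) == 1) U[i] <- U[i] + 1L
    }
  }
  U
}

bf_tajima <- function(mat) {
  n <- nrow(mat)
  S <- length(bf_segsites(mat))
  if (S == 0) return(NA_real_)
  k <- bf_khat(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)      # degenerate variance (n <= 3)
  (k - S / a1) / sqrt(v)
}

bf_r2 <- function(mat) {
  S <- length(bf_segsites(mat))
  if (S == 0) return(NA_real_)
  U <- bf_singletons(mat)
  k <- bf_khat(mat)
  sqrt(sum((U - k / 2)^2) / nrow(mat)) / S
}

# random test alignment with optional ambiguity/gap contamination
random_alignment <- function(n, L, p_miss = 0.1, alphabet = BASES) {
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (p_miss > 0) {
    miss <- matrix(stats::runif(n * L) < p_miss, n, L)
    mat[miss] <- sample(c("N", "-", "R", "Y", "W"), sum(miss), replace = TRUE)
  }
  alignment(paste0("s", seq_len(n)), apply(mat, 1, paste, collapse = ""))
}

# minimum spanning tree weight by exhaustive enumeration (<= 6 nodes)
bf_mst_weight <- function(d) {
  H <- nrow(d)
  if (H == 1) return(0)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (pick in utils::combn(nrow(edges), H - 1, simplify = FALSE)) {
    parent <- seq_len(H)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    ok <- TRUE
    for (e in pick) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(d[edges[pick, , drop = FALSE]]))
  }
  best
}

# metadata for a simple B birds x m mites design
toy_metadata <- function(ids, species = "sp", birds_of = NULL) {
  data.frame(sample_id = ids, species = species,
             bird_id = if (is.null(birds_of)) ids else birds_of,
             locality = "here", stringsAsFactors = FALSE)
}
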