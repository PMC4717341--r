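test_that("degenerate and two-sequence cases have their closed forms", {
  ident <- alignment(c("a", "b", "c"), rep("ACGTACGTAC", 3))
  expect_equal(pairwise_differences(ident)$k_hat, 0)
  expect_equal(nucleotide_diversity(ident), 0)
  expect_equal(segregating_sites(ident)$S, 0L)
  td <- tajimas_d(ident)
  expect_true(is.na(td$D))          # undefined, never imputed as 0
  expect_true(is.na(r2_statistic(ident)))

  two <- alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(pairwise_differences(two)$k_hat, 1)
  expect_equal(nucleotide_diversity(two), 0.1)
  # n = 2: every segregating site is a singleton in both sequences
  expect_equal(unname(singleton_counts(two)), c(1L, 1L))
  expect_equal(r2_statistic(two), 0.5)
  # Tajima's variance collapses below n = 4: undefined, not zero
  expect_true(is.na(tajimas_d(two)$D))
})

test_that("R2 is exactly 0.5 for n = 2 whatever S >= 1", {
  set.seed(11)
  for (rep in 1:20) {
    x <- random_alignment(2, 40, p_miss = 0.05)
    S <- segregating_sites(x)$S
    if (S == 0) next
    expect_equal(r2_statistic(x), 0.5)
  }
})

test_that("D is exactly zero when k_hat equals the Watterson expectation", {
  # n = 4 with 8 singleton sites and 3 doubleton sites: sum of pairwise
  # differences = 3*8 + 4*3 = 36, k_hat = 6 = S/a1 = 11/(11/6)
  mat <- matrix("A", 4, 11)
  for (s in 1:8) mat[(s - 1) %% 4 + 1, s] <- "T"
  mat[1:2, 9:11] <- "T"
  x <- alignment(paste0("s", 1:4), apply(mat, 1, paste, collapse = ""))
  expect_equal(segregating_sites(x)$S, 11L)
  expect_equal(pairwise_differences(x)$k_hat, 6)
  expect_equal(tajimas_d(x)$D, 0, tolerance = 1e-12)
})

test_that("a star alignment gives one private mutation per sequence", {
  L <- 20
  base <- rep("A", L)
  seqs <- vapply(1:6, function(i) {
    s <- base; s[i] <- "T"; paste(s, collapse = "")
  }, "")
  x <- alignment(paste0("s", 1:6), seqs)
  expect_equal(unname(singleton_counts(x)), rep(1L, 6))
  expect_equal(segregating_sites(x)$S, 6L)
})

test_that("all statistics match brute-force oracles on random alignments", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    L <- sample(10:50, 1)
    x <- random_alignment(n, L, p_miss = stats::runif(1, 0, 0.2))
    mat <- aln_chars(x)
    pt <- bf_pair_tables(mat)
    pd <- pairwise_differences(x)
    expect_equal(unname(pd$diffs), unname(pt$d), ignore_attr = TRUE)
    expect_equal(pd$k_hat, bf_khat(mat), tolerance = 1e-12)
    expect_equal(segregating_sites(x)$sites, bf_segsites(mat))
    expect_equal(unname(singleton_counts(x)), bf_singletons(mat))
    p1 <- suppressWarnings(nucleotide_diversity(x))
    expect_equal(p1, bf_pi(mat), tolerance = 1e-12)
    D <- tajimas_d(x)$D
    expect_equal(D, bf_tajima(mat), tolerance = 1e-12)
    expect_equal(r2_statistic(x), bf_r2(mat), tolerance = 1e-12)
    # summary row is consistent with the individual operations
    st <- diversity_stats(x, r2_reps = 0)
    expect_equal(st$k_hat, pd$k_hat)
    expect_equal(st$S, segregating_sites(x)$S)
    expect_equal(st$pi, p1)
    expect_equal(st$D, D)
  }
})

test_that("Tajima's D on a small fixed alignment matches an independent evaluation", {
  x <- alignment(paste0("s", 1:4),
                 c("AAAAAAAAAA", "ATAAAAAAAA", "ATTAAAAAAA", "ATTTAAAAAA"))
  # n = 4, S = 3, k = (1+2+3+1+2+1)/6 = 5/3; constants evaluated by hand
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- 5/9; b2 <- 2 * 23 / (9 * 4 * 3)
  c1 <- b1 - 1/a1
  c2 <- b2 - 6 / (4 * a1) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (5/3 - 3/a1) / sqrt(e1 * 3 + e2 * 3 * 2)
  expect_equal(tajimas_d(x)$D, expected, tolerance = 1e-12)
})

test_that("masking can only remove differences, never add them", {
  set.seed(55)
  for (rep in 1:15) {
    x <- random_alignment(6, 30, p_miss = 0)
    pd0 <- pairwise_differences(x)
    mat <- aln_chars(x)
    hit <- matrix(stats::runif(length(mat)) < 0.15, nrow(mat))
    mat[hit] <- "N"
    y <- alignment(x$ids, apply(mat, 1, paste, collapse = ""))
    pd1 <- pairwise_differences(y)
    expect_true(all(pd1$diffs <= pd0$diffs))
    # masking a monomorphic column never changes S
    mono <- setdiff(seq_len(x$L), segregating_sites(x)$sites)
    if (length(mono)) {
      mat2 <- aln_chars(x)
      mat2[, mono[1]] <- "N"
      z <- alignment(x$ids, apply(mat2, 1, paste, collapse = ""))
      expect_equal(segregating_sites(z)$S, segregating_sites(x)$S)
    }
  }
})

test_that("a perfect star gives the smallest attainable p-value", {
  # one private mutation per sequence: U_i = 1 = k_hat/2, so R2 = 0,
  # below every simulated replicate
  L <- 30
  seqs <- vapply(1:10, function(i) {
    s <- rep("A", L); s[i] <- "T"; paste(s, collapse = "")
  }, "")
  x <- alignment(paste0("s", 1:10), seqs)
  expect_equal(r2_statistic(x), 0)
  set.seed(71)
  expect_equal(r2_test(x, B = 200)$p, 1 / 201)
})

test_that("the R2 test detects a strongly star-like expansion", {
  # severe recent expansion: g = 1000 at tau = 0.005 keeps essentially all
  # lineage history in the external branches
  set.seed(72)
  rej <- replicate(30, {
    sim <- simulate_species("sp", 30, B = 10, m = 5, f = 5, theta = 1,
                            L = 507, mode = "expansion", g = 1000,
                            tau = 0.005)
    a <- alignment(names(sim$seqs), unname(sim$seqs))
    if (segregating_sites(a)$S == 0) return(NA)
    r2_test(a, B = 200)$p <= 0.05
  })
  expect_gte(mean(rej, na.rm = TRUE), 0.95)
})

test_that("R2 coalescent p-values are valid and seed-deterministic", {
  set.seed(77)
  x <- random_alignment(8, 40, p_miss = 0)
  set.seed(123)
  t1 <- r2_test(x, B = 200)
  set.seed(123)
  t2 <- r2_test(x, B = 200)
  expect_identical(t1, t2)
  expect_gt(t1$p, 0)
  expect_lte(t1$p, 1)
  # an observed R2 below every replicate gets the smallest possible p
  expect_gte(t1$p, 1 / 201)
})
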