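test_that("haplotype collapsing handles the degenerate extremes", {
  x <- alignment(paste0("s", 1:5), rep("ACGTACGT", 5))
  ht <- collapse_haplotypes(x)
  expect_equal(length(ht$freq), 1L)
  expect_equal(unname(ht$freq), 5L)
  expect_equal(ht$membership$H1, paste0("s", 1:5))

  set.seed(21)
  y <- random_alignment(5, 12, p_miss = 0)
  while (any(duplicated(apply(aln_chars(y), 1, paste, collapse = ""))))
    y <- random_alignment(5, 12, p_miss = 0)
  expect_equal(unname(collapse_haplotypes(y)$freq), rep(1L, 5))
})

test_that("ambiguous positions are ignored when matching haplotypes", {
  x <- alignment(c("a", "b", "c"),
                 c("ACGTACGT", "ACGTACGN", "ACGTACGA"))
  ht <- collapse_haplotypes(x)
  # b matches a (the first-founded haplotype); c differs from a at site 8
  expect_equal(unname(ht$assignment), c("H1", "H1", "H2"))
})

test_that("a single haplotype yields an empty network", {
  x <- alignment(paste0("s", 1:4), rep("ACGT", 4))
  nw <- build_network(collapse_haplotypes(x))
  expect_equal(nrow(nw$tree_edges), 0L)
  expect_equal(nrow(nw$alt_edges), 0L)
  expect_equal(nw$hub, "H1")
})

test_that("network is a spanning tree with brute-force-minimal weight", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    x <- random_alignment(n, 15, p_miss = 0.05)
    ht <- collapse_haplotypes(x)
    H <- length(ht$freq)
    nw <- build_network(ht)
    expect_equal(nrow(nw$tree_edges), H - 1L)
    if (H >= 2 && H <= 6) {
      d <- matrix(0, H, H)
      reps <- aln_chars(ht$haplotypes)
      pt <- bf_pair_tables(reps)
      expect_equal(sum(nw$tree_edges$weight), bf_mst_weight(pt$d))
    }
    # every alternative link has weight equal to the path bottleneck,
    # hence swapping it in yields another minimum spanning tree
    if (nrow(nw$alt_edges) > 0) {
      pt <- bf_pair_tables(aln_chars(ht$haplotypes))
      for (e in seq_len(nrow(nw$alt_edges))) {
        i <- match(nw$alt_edges$from[e], nw$nodes$haplotype)
        j <- match(nw$alt_edges$to[e], nw$nodes$haplotype)
        expect_equal(nw$alt_edges$weight[e], pt$d[i, j])
      }
    }
  }
})

test_that("a mutational chain gives a path with no alternative links", {
  L <- 20
  seqs <- vapply(0:4, function(k) {
    s <- rep("A", L)
    if (k > 0) s[seq_len(k)] <- "T"
    paste(s, collapse = "")
  }, "")
  x <- alignment(paste0("s", 0:4), seqs)
  nw <- build_network(collapse_haplotypes(x))
  expect_equal(nrow(nw$tree_edges), 4L)
  expect_true(all(nw$tree_edges$weight == 1))
  expect_equal(nrow(nw$alt_edges), 0L)
  # path of >= 4 haplotypes can never be a perfect star
  ns <- network_summary(nw, collapse_haplotypes(x))
  expect_lt(ns$star_score, 1)
})

test_that("collapse and network are invariant to input order", {
  set.seed(44)
  x <- random_alignment(8, 20, p_miss = 0.05)
  perm <- sample(8)
  y <- x[perm]
  a <- collapse_haplotypes(x); b <- collapse_haplotypes(y)
  expect_equal(sort(unname(a$freq)), sort(unname(b$freq)))
  na <- build_network(a); nb <- build_network(b)
  expect_equal(sum(na$tree_edges$weight), sum(nb$tree_edges$weight))
  # same partition of samples into haplotypes
  part <- function(h) unname(lapply(h$membership, sort))
  expect_setequal(part(a), part(b))
})

test_that("a perfect star scores 1 and summaries count bird sharing", {
  L <- 20
  seqs <- c(paste(rep("A", L), collapse = ""),
            vapply(1:4, function(i) {
              s <- rep("A", L); s[i] <- "T"; paste(s, collapse = "")
            }, ""))
  ids <- paste0("s", 1:5)
  # hub carried by 3 extra mites so it is modal
  x <- alignment(c(ids, "s6", "s7"), c(seqs, seqs[1], seqs[1]))
  md <- toy_metadata(x$ids, birds_of = c("b1", "b1", "b2", "b2", "b3",
                                         "b1", "b3"))
  ht <- collapse_haplotypes(x, md)
  nw <- build_network(ht)
  ns <- network_summary(nw, ht)
  expect_equal(ns$star_score, 1)
  expect_equal(ns$n_haplotypes, 5L)
  expect_equal(ns$max_within_bird_sharing, 2L)   # s1 and s6 share H1 on b1
})
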