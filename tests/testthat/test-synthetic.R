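test_that("a single founder lineage makes all mites of a bird identical", {
  set.seed(1)
  sim <- simulate_species("sp", M = 10, B = 6, m = 4, f = 1, theta = 0.02,
                          L = 200)
  for (b in unique(sim$metadata$bird_id)) {
    ids <- sim$metadata$sample_id[sim$metadata$bird_id == b]
    expect_equal(length(unique(sim$seqs[ids])), 1L)
  }
})

test_that("theta = 0 yields a monomorphic species and NA statistics downstream", {
  set.seed(2)
  sim <- simulate_species("sp", M = 10, B = 5, m = 3, f = 2, theta = 0,
                          L = 100)
  a <- alignment(names(sim$seqs), unname(sim$seqs))
  st <- diversity_stats(a, r2_reps = 200)
  expect_equal(st$S, 0L)
  expect_equal(st$pi, 0)
  expect_true(is.na(st$D) && is.na(st$R2) && is.na(st$p_R2))
})

test_that("equilibrium diversity matches its coalescent expectation", {
  theta <- 0.01
  set.seed(3)
  pis <- replicate(200, {
    sim <- simulate_species("sp", M = 10, B = 8, m = 2, f = 2, theta = theta,
                            L = 507)
    suppressWarnings(nucleotide_diversity(
      alignment(names(sim$seqs), unname(sim$seqs))))
  })
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("within-bird haplotype sharing increases as founders decrease", {
  share_prob <- function(f, reps = 120) {
    mean(replicate(reps, {
      sim <- simulate_species("sp", 10, B = 4, m = 4, f = f, theta = 0.05,
                              L = 300)
      a <- alignment(names(sim$seqs), unname(sim$seqs))
      ht <- collapse_haplotypes(a, sim$metadata)
      any(vapply(ht$bird_composition,
                 function(tb) length(tb) && max(tb) >= 2, logical(1)))
    }))
  }
  set.seed(4)
  p1 <- share_prob(1)
  p4 <- share_prob(4)
  expect_equal(p1, 1)
  expect_gt(p1, p4)
})

test_that("the default preset assembles a complete, consistent system", {
  cfg <- default_preset()
  expect_equal(nrow(cfg$species), 17L)
  expect_equal(sum(cfg$species$mode == "expansion"), 2L)
  sys <- simulate_system(cfg, seed = 11)
  expect_equal(length(sys$datasets), 17L)
  expect_equal(length(sys$alignment$ids),
               sum(cfg$species$B * cfg$species$m))
  expect_equal(nrow(sys$metadata), length(sys$alignment$ids))
  # theta strictly increases with load when beta > 0
  expect_true(all(diff(sys$truth$theta[order(sys$truth$M)]) > 0))
})

test_that("fixtures round-trip through the readers and are seed-stable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- default_preset(n_species = 4)
  sys <- simulate_system(cfg, seed = 8)
  p1 <- write_fixture(sys, dir1)
  p2 <- write_fixture(simulate_system(cfg, seed = 8), dir2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))

  aln <- read_alignment(p1[["alignment"]])
  md <- read_metadata(p1[["metadata"]])
  loads <- read_loads(p1[["loads"]])
  expect_identical(aln$mat, sys$alignment$mat)
  expect_equal(md$sample_id, sys$metadata$sample_id)
  expect_equal(unname(loads[names(sys$loads)]), unname(sys$loads))
  ds <- build_species_datasets(aln, md, loads)
  expect_equal(names(ds), names(sys$datasets))
  truth <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$species$theta, sys$truth$theta)
})

test_that("diversity tracks load across simulated systems when beta > 0", {
  set.seed(6)
  hits <- replicate(20, {
    sys <- simulate_system(default_preset(n_species = 10), seed =
                             sample.int(1e6, 1))
    pis <- vapply(sys$datasets, function(d)
      suppressWarnings(nucleotide_diversity(d$alignment)), numeric(1))
    stats::cor(sys$loads[names(pis)], pis, method = "spearman") > 0
  })
  expect_gte(mean(hits), 0.95)
})
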