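test_that("FASTA parsing validates, case-folds and maps U to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">m1", "acgtu", ">m2", "ACGTT"), f)
  aln <- read_alignment(f)
  expect_s3_class(aln, "coi_alignment")
  expect_equal(aln$ids, c("m1", "m2"))
  expect_equal(aln$L, 5L)
  expect_equal(paste(aln$mat[1, ], collapse = ""), "ACGTT")

  writeLines(c(">a", strrep("A", 507), ">b", strrep("C", 507)), f)
  expect_equal(read_alignment(f)$L, 507L)
})

test_that("ragged, duplicated and empty FASTA inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", strrep("A", 507), ">b", strrep("C", 500)), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">a", "ACGT", ">a", "ACGG"), f)
  expect_error(read_alignment(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_alignment(f), "empty")
})

test_that("write/read round-trip preserves ids and sequences", {
  set.seed(41)
  aln <- random_alignment(6, 80, p_miss = 0.05)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_identical(back$ids, aln$ids)
  expect_identical(back$mat, aln$mat)
})

test_that("window slicing respects 1-based inclusive bounds", {
  aln <- alignment(c("a", "b"), c("ACGTAC", "ACCTAG"))
  w <- slice_window(aln, 2, 4)
  expect_equal(w$L, 3L)
  expect_equal(paste(w$mat[2, ], collapse = ""), "CCT")
  expect_error(slice_window(aln, 0, 3), "window")
  expect_error(slice_window(aln, 5, 3), "window")
})

test_that("metadata schema is enforced", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tspecies\tbird_id\tlocality\textra",
               "m1\tsp1\tb1\tES\tx", "m2\tsp1\tb1\tES\ty",
               "m3\tsp2\tb2\tRU\tz"), f)
  md <- read_metadata(f)
  expect_equal(nrow(md), 3L)
  expect_true("extra" %in% names(md))

  writeLines(c("sample_id\tspecies\tlocality", "m1\tsp1\tES"), f)
  expect_error(read_metadata(f), "bird_id")
  writeLines(c("sample_id\tspecies\tbird_id\tlocality",
               "m1\tsp1\tb1\tES", "m1\tsp1\tb2\tES"), f)
  expect_error(read_metadata(f), "duplicate")
})

test_that("loads table is validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tmedian_load", "sp1\t12.5", "sp2\t49"), f)
  loads <- read_loads(f)
  expect_equal(unname(loads["sp2"]), 49)
  writeLines(c("species\tmedian_load", "sp1\t-3"), f)
  expect_error(read_loads(f), "positive")
})

test_that("species datasets partition matched samples and flag problems", {
  set.seed(7)
  aln <- random_alignment(9, 30, p_miss = 0)
  md <- toy_metadata(paste0("s", 1:9),
                     species = c(rep("spA", 4), rep("spB", 4), "spC"),
                     birds_of = c("b1", "b1", "b2", "b2",
                                  "b3", "b3", "b4", "b4", "b5"))
  loads <- c(spA = 10, spB = 20, spC = 5)
  expect_warning(ds <- build_species_datasets(aln, md, loads),
                 "excluded")           # spC has a single sequence
  expect_named(ds, c("spA", "spB"))
  # conservation: every matched sample lands in exactly one dataset
  all_ids <- unname(unlist(lapply(ds, function(d) d$alignment$ids)))
  expect_equal(sort(all_ids), sort(paste0("s", 1:8)))
  expect_equal(anyDuplicated(all_ids), 0L)

  expect_error(build_species_datasets(aln, md, loads[c("spA", "spC")]),
               "spB")

  md2 <- rbind(md, toy_metadata("ghost", species = "spA", birds_of = "b9"))
  warns <- capture_warnings(ds2 <- build_species_datasets(aln, md2, loads))
  expect_match(warns, "join report", all = FALSE)
  expect_equal(attr(ds2, "join_report")$unmatched_metadata, "ghost")
})
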