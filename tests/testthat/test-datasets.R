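test_that("admission filters check length, pairs and MFE in order", {
  crit <- filter_criteria()

  # 50 nt: one short of the window, everything else passing
  short <- generate_hairpin(hairpin_spec(stem_len = 20, loop_len = 4,
                                         bulge_rate = 0, flank_len = 3),
                            seed = 1)
  expect_identical(nchar(short$residues), 50L)
  expect_identical(admit_pseudo_hairpin(short, crit)$reason, "length")

  # 17 pairs, length inside the window
  few <- generate_hairpin(hairpin_spec(stem_len = 17, loop_len = 4,
                                       bulge_rate = 0, flank_len = 10),
                          seed = 2)
  expect_identical(admit_pseudo_hairpin(few, crit)$reason, "pairs")

  # L = 60, 20 pairs, mfe about -40: all three criteria hold
  ok <- generate_hairpin(hairpin_spec(stem_len = 20, loop_len = 4,
                                      bulge_rate = 0, flank_len = 8),
                         seed = 3)
  expect_identical(nchar(ok$residues), 60L)
  res <- admit_pseudo_hairpin(ok, crit)
  expect_true(res$pass)
  expect_identical(res$reason, "ok")

  # mfe boundary is inclusive; above it fails
  weak <- ok; weak$mfe <- -14.9
  expect_identical(admit_pseudo_hairpin(weak, crit)$reason, "mfe")
  edge <- ok; edge$mfe <- -15
  expect_true(admit_pseudo_hairpin(edge, crit)$pass)

  expect_error(admit_pseudo_hairpin(annotated_rna("x", "ACGU"), crit),
               "structure")
})

test_that("relaxing any admission criterion never flips pass to fail", {
  set.seed(27)
  for (rep in 1:25) {
    rna <- generate_hairpin(hairpin_spec(stem_len = sample(10:30, 1),
                                         flank_len = sample(0:20, 1),
                                         bulge_rate = 0.2), seed = NULL)
    crit <- filter_criteria(min_len = sample(40:70, 1),
                            max_len = sample(80:150, 1),
                            min_pairs = sample(5:25, 1),
                            max_mfe = -sample(5:40, 1))
    relaxed <- filter_criteria(min_len = crit$min_len - 5,
                               max_len = crit$max_len + 5,
                               min_pairs = crit$min_pairs - 3,
                               max_mfe = crit$max_mfe + 5)
    if (admit_pseudo_hairpin(rna, crit)$pass) {
      expect_true(admit_pseudo_hairpin(rna, relaxed)$pass)
    }
  }
})

test_that("balance_subsample is a seeded, order-stable subset", {
  recs <- as.list(letters[1:20])
  expect_identical(balance_subsample(recs[1:10], 10, seed = 3), recs[1:10])
  expect_identical(balance_subsample(recs, 8, seed = 5),
                   balance_subsample(recs, 8, seed = 5))
  expect_error(balance_subsample(recs, 21, seed = 1), "exceeds")

  # seeded-shuffle-take-8 reference: sample.int(n, k) is the first k steps
  # of the same Fisher-Yates walk as sample.int(n)
  set.seed(42)
  keep <- sort(sample.int(20)[1:8])
  expect_identical(balance_subsample(recs, 8, seed = 42), recs[keep])

  # subset property with exact cardinality
  sub <- balance_subsample(recs, 8, seed = 7)
  expect_length(sub, 8L)
  expect_true(all(unlist(sub) %in% unlist(recs)))
})

test_that("external redundancy reduction wraps the clustering tool", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGUACGU", ">b", "ACGUACGU", ">c", "GGGGCCCC"), fa)

  # stub tool: keeps the first record of every identical-sequence group
  stub <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               'while [ $# -gt 0 ]; do case "$1" in -i) IN=$2; shift 2;;',
               "-o) OUT=$2; shift 2;; -c) shift 2;; *) shift;; esac; done",
               "awk '/^>/{id=$0; getline seq; if (!(seq in seen)) {seen[seq]=1; print id; print seq}}' \"$IN\" > \"$OUT\""),
             stub)
  Sys.chmod(stub, "0755")
  expect_identical(reduce_redundancy_external(fa, 0.8, stub), c("a", "c"))

  # skip path retains everything with a warning
  expect_warning(ids <- reduce_redundancy_external(fa, 0.8, stub, skip = TRUE),
                 "skipped")
  expect_identical(ids, c("a", "b", "c"))
  expect_warning(
    ids2 <- reduce_redundancy_external(fa, 0.8, "absent-cdhit",
                                       skip_if_missing = TRUE),
    "not found")
  expect_identical(ids2, c("a", "b", "c"))

  expect_error(reduce_redundancy_external(fa, 1.2, stub), "outside")
  expect_error(reduce_redundancy_external(fa, 0.8, "absent-cdhit"),
               "not found")
})
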