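test_that("ntuple_ssc counts sliding windows in frozen order", {
  expect_length(ntuple_ssc(random_statuses(30), n = 2), 100L)

  f <- ntuple_ssc(c("A", "A", "A"), n = 1)
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)

  f <- ntuple_ssc(c("G-C", "A", "C-G"), n = 2)
  expect_equal(unname(f["G-C|A"]), 0.5)
  expect_equal(unname(f["A|C-G"]), 0.5)
  expect_equal(sum(f != 0), 2L)

  expect_error(ntuple_ssc(c("A", "C"), n = 3), "length")
  expect_error(ntuple_ssc(c("A", "B"), n = 1), "unknown")
})

test_that("ntuple_ssc equals a brute-force dictionary count", {
  set.seed(5)
  for (L in 1:8) {
    for (n in seq_len(min(L, 3))) {
      st <- random_statuses(L)
      expect_equal(ntuple_ssc(st, n), oracle_ntuple(st, n))
    }
  }
})

test_that("theta_factors are mean squared energy differences per tier", {
  # constant statuses: all differences vanish
  expect_equal(unname(theta_factors(rep("G-C", 6), lam = 4)), rep(0, 4))

  # F = (0, -2): theta_1 = (0 - (-2))^2 over one term
  expect_equal(unname(theta_factors(c("A", "A-U"), lam = 1)), 4)

  # F = (-3, -2, -3): theta_1 = ((-1)^2 + (1)^2)/2 = 1, theta_2 = 0
  th <- theta_factors(c("G-C", "A-U", "G-C"), lam = 2)
  expect_equal(unname(th), c(1, 0))

  expect_error(theta_factors(c("A", "C"), lam = 2), "smaller than")
  expect_true(all(theta_factors(random_statuses(50), 20) >= 0))
})

test_that("theta invariance under pair-orientation relabeling", {
  flip <- function(s) {
    ifelse(nchar(s) == 1L, s,
           paste0(substr(s, 3, 3), "-", substr(s, 1, 1)))
  }
  set.seed(6)
  for (rep in 1:20) {
    st <- random_statuses(sample(5:40, 1))
    lam <- sample(seq_len(length(st) - 1L), 1)
    expect_equal(theta_factors(st, lam), theta_factors(flip(st), lam))
  }
})

test_that("pse_ssc normalizes to 1 with the documented dimension", {
  st <- random_statuses(60)

  v <- pse_ssc(st, psessc_params(2, 13, 0.5), record_id = "r")
  expect_length(v$values, 113L)
  expect_equal(sum(v$values), 1, tolerance = 1e-12)

  # w = 0: tuple block unchanged, lambda zeros appended
  v0 <- pse_ssc(st, psessc_params(2, 5, 0))
  expect_equal(v0$values[1:100], ntuple_ssc(st, 2))
  expect_equal(unname(v0$values[101:105]), rep(0, 5))

  # theta components carry signal for non-constant statuses and w > 0
  st_var <- c(rep("A", 5), rep("G-C", 5))
  vv <- pse_ssc(st_var, psessc_params(1, 3, 0.5))
  expect_true(any(vv$values[11:13] > 0))
})

test_that("trinucleotide_composition counts overlapping 3-mers", {
  f <- trinucleotide_composition(annotated_rna("x", "AAAA"))
  expect_length(f, 64L)
  expect_equal(unname(f["AAA"]), 1)

  f <- trinucleotide_composition("ACGU")
  expect_equal(unname(f[c("ACG", "CGU")]), c(0.5, 0.5))
  expect_equal(sum(f), 1)

  expect_error(trinucleotide_composition("AC"), "length")
})

test_that("randomization P-value follows the (c+1)/(N+1) estimator", {
  rna <- annotated_rna("x", "GGGGGAAAACCCCC", mfe = -50)

  # observed MFE below every shuffle: P = 1/(N+1)
  high <- stub_backend(function(r) 0)
  expect_equal(randomization_pvalue(rna, high, shuffles = 99, seed = 4), 0.01)

  # degenerate constant-energy backend: all shuffles tie, P = 1
  const <- stub_backend(function(r) -50)
  expect_equal(randomization_pvalue(rna, const, shuffles = 50, seed = 4), 1)

  # determinism under a fixed seed with a composition-sensitive backend
  gc_run <- stub_backend(function(r) {
    -max(nchar(gsub("[AU]", "", r$residues)), 1) -
      as.numeric(charToRaw(substr(r$residues, 1, 1)))
  })
  rna2 <- annotated_rna("y", "GGCAUCGGAUCGU", mfe = -60)
  p1 <- randomization_pvalue(rna2, gc_run, shuffles = 30, seed = 9)
  p2 <- randomization_pvalue(rna2, gc_run, shuffles = 30, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)

  expect_error(randomization_pvalue(rna, high, shuffles = 0), "shuffles")
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    sort(paste0(ch[-length(ch)], ch[-1L]))
  }
  set.seed(12)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
    sh <- shuffle_residues(s, "dinucleotide")
    expect_identical(dinucs(sh), dinucs(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 30, 30), substr(s, 30, 30))
  }
})

test_that("ex_pse_ssc concatenates MFE, P-value and 3-mer block", {
  rna <- generate_hairpin(hairpin_spec(stem_len = 15), seed = 31)
  st <- assign_statuses(rna)

  v <- ex_pse_ssc(rna, st, psessc_params(1, 17, 0.2), b_value = 0.03)
  expect_length(v$values, 93L)  # 10 + 17 + 66
  expect_equal(length(v$values) - length(pse_ssc(st, psessc_params(1, 17, 0.2))$values),
               66L)
  expect_identical(unname(v$values["mfe"]), rna$mfe)  # pass-through
  expect_equal(unname(v$values["pvalue"]), 0.03)

  no_mfe <- annotated_rna("x", rna$residues, structure = rna$structure)
  expect_error(ex_pse_ssc(no_mfe, st, psessc_params(1, 17, 0.2), b_value = 0.5),
               "MFE")
  expect_error(ex_pse_ssc(rna, st, psessc_params(1, 17, 0.2)), "P-value")
})
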