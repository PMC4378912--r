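# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: exhaustive enumeration instead of dynamic
# programming, dictionary counting instead of integer coding, the textbook
# MCC instead of the class-normalized form.

# Maximum pair count over ALL nested structures, by exhaustive recursive
# enumeration of pairing choices (no memoization).
oracle_max_pairs <- function(residues, min_loop = 3L) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  ok_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (k > j) break
      if (!ok_pair(chars[i], chars[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(chars) < min_loop + 2L) return(0L)
  rec(1L, length(chars))
}

# Textbook Matthews correlation coefficient from TP/TN/FP/FN; NA when any
# marginal is empty.
oracle_mcc <- function(tp, tn, fp, fn) {
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(d)
}

# Dictionary-based n-tuple frequency counter over status sequences.
oracle_ntuple <- function(statuses, n) {
  nw <- length(statuses) - n + 1L
  keys <- vapply(seq_len(nw), function(i) {
    paste(statuses[i:(i + n - 1L)], collapse = "|")
  }, character(1))
  counts <- table(keys)
  out <- stats::setNames(numeric(10^n), psessc:::ntuple_names(n))
  out[names(counts)] <- as.numeric(counts) / nw
  out
}

# Trapezoidal area under an ROC polygon.
oracle_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Random valid status sequence of length L (uniform over the alphabet; not
# necessarily realizable as a planted hairpin, which the feature formulas do
# not require).
random_statuses <- function(L) {
  sample(status_alphabet(), L, replace = TRUE)
}

# Deterministic fake folding backend with a caller-supplied MFE rule.
stub_backend <- function(mfe_fun) {
  structure(list(
    name = "stub",
    fold = function(rna) {
      rna$structure <- strrep(".", nchar(rna$residues))
      rna$mfe <- mfe_fun(rna)
      rna
    }
  ), class = "folding_backend")
}

# A covering record whose statuses realize all 10 alphabet symbols exactly:
# stem of the six pair types (A-U, U-A, G-C, C-G, G-U, U-G reading the 5'
# arm) around an ACGU loop.
covering_record <- function() {
  annotated_rna("cover", "AUGCGUACGUGUGCAU",
                structure = "((((((....))))))")
}
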