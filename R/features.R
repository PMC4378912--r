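#' PseSSC parameter set
#'
#' @param n Counted rank of local status tuples (1-4 in the reference grid;
#'   any n >= 1 is accepted).
#' @param lam Highest correlation tier lambda (>= 1); must stay below the
#'   sequence length when features are computed.
#' @param w Weight factor in `[0, 1]` balancing local composition against
#'   the long-range correlation factors.
#' @return Object of class `psessc_params`.
#' @export
psessc_params <- function(n = 2L, lam = 13L, w = 0.5) {
  n <- as.integer(n); lam <- as.integer(lam); w <- as.numeric(w)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  if (is.na(lam) || lam < 1L) stop("lam must be an integer >= 1", call. = FALSE)
  if (is.na(w) || w < 0 || w > 1) stop("w must lie in [0, 1]", call. = FALSE)
  structure(list(n = n, lam = lam, w = w), class = "psessc_params")
}

#' @export
print.psessc_params <- function(x, ...) {
  cat(sprintf("<psessc_params> n=%d lambda=%d w=%g (PseSSC dim %d)\n",
              x$n, x$lam, x$w, 10^x$n + x$lam))
  invisible(x)
}

# Names of all status n-tuples, first position most significant, in the
# frozen alphabet order; components joined with "|". Cached per n: the
# 10^4-name vector for n = 4 is not worth rebuilding per record.
.ntuple_name_cache <- new.env(parent = emptyenv())
ntuple_names <- function(n) {
  key <- as.character(n)
  if (!is.null(.ntuple_name_cache[[key]])) return(.ntuple_name_cache[[key]])
  ab <- status_alphabet()
  out <- ab
  if (n > 1L) {
    for (k in 2:n) out <- paste(rep(out, each = 10L), ab, sep = "|")
  }
  .ntuple_name_cache[[key]] <- out
  out
}

#' n-tuple structure status composition
#'
#' Sliding-window counts of each status n-tuple over the `L - n + 1` windows
#' of a status sequence, normalized by the window count. Component order is
#' lexicographic over the frozen status-alphabet order with the first tuple
#' position most significant.
#'
#' @param statuses A `status_sequence` (or plain character vector of status
#'   symbols).
#' @param n Tuple size.
#' @return Named numeric vector of length `10^n` summing to 1.
#' @export
ntuple_ssc <- function(statuses, n = 2L) {
  n <- as.integer(n)
  L <- length(statuses)
  if (L < n) {
    stop(sprintf("sequence length %d < tuple size n = %d", L, n), call. = FALSE)
  }
  ab <- status_alphabet()
  idx <- match(statuses, ab)
  if (anyNA(idx)) {
    stop(sprintf("unknown structure status: %s",
                 statuses[which(is.na(idx))[1L]]), call. = FALSE)
  }
  idx <- idx - 1L
  nw <- L - n + 1L
  code <- integer(nw)
  for (t in seq_len(n)) {
    code <- code * 10L + idx[t:(t + nw - 1L)]
  }
  counts <- tabulate(code + 1L, nbins = 10L^n)
  stats::setNames(counts / nw, ntuple_names(n))
}

#' Tiered free-energy correlation factors
#'
#' `theta_j` is the mean squared difference of status free energies between
#' all positions `j` apart: the j-th tier of long-range structure-order
#' information.
#'
#' @inheritParams ntuple_ssc
#' @param lam Highest tier (must satisfy `lam < L`).
#' @param table A [free_energy_table].
#' @return Numeric vector `theta_1 ... theta_lam`, all `>= 0`.
#' @export
theta_factors <- function(statuses, lam, table = free_energy_table()) {
  lam <- as.integer(lam)
  L <- length(statuses)
  if (lam >= L) {
    stop(sprintf("lambda = %d must be smaller than the sequence length L = %d",
                 lam, L), call. = FALSE)
  }
  if (lam < 1L) stop("lam must be >= 1", call. = FALSE)
  f <- status_free_energy(statuses, table)
  theta <- vapply(seq_len(lam), function(j) {
    mean((f[seq_len(L - j)] - f[seq_len(L - j) + j])^2)
  }, numeric(1))
  stats::setNames(theta, paste0("theta_", seq_len(lam)))
}

#' Pseudo structure status composition (PseSSC)
#'
#' The `10^n + lambda` feature vector: normalized n-tuple status frequencies
#' followed by weighted correlation factors, all divided by the shared
#' denominator `sum(f) + w * sum(theta)` so the components sum to 1.
#'
#' @inheritParams ntuple_ssc
#' @param params A [psessc_params].
#' @param table A [free_energy_table].
#' @param record_id Identifier stored in the result.
#' @param label Optional class label carried through.
#' @return A `feature_vector` of kind `"PseSSC"`.
#' @export
pse_ssc <- function(statuses, params = psessc_params(),
                    table = free_energy_table(),
                    record_id = "", label = NULL) {
  f <- ntuple_ssc(statuses, params$n)
  theta <- theta_factors(statuses, params$lam, table)
  denom <- sum(f) + params$w * sum(theta)
  values <- c(f, params$w * theta) / denom
  feature_vector(record_id, "PseSSC", params, values, label)
}

#' Overlapping tri-nucleotide composition
#'
#' @param rna An [annotated_rna] (or residue string) of length >= 3.
#' @return Named numeric vector of the 64 tri-nucleotide frequencies
#'   (lexicographic `A < C < G < U`), summing to 1.
#' @export
trinucleotide_composition <- function(rna) {
  residues <- if (inherits(rna, "annotated_rna")) rna$residues else rna
  L <- nchar(residues)
  if (L < 3L) stop(sprintf("sequence length %d < 3", L), call. = FALSE)
  bases <- c("A", "C", "G", "U")
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1L]], bases) - 1L
  nw <- L - 2L
  code <- idx[1:nw] * 16L + idx[2:(nw + 1L)] * 4L + idx[3:(nw + 2L)]
  counts <- tabulate(code + 1L, nbins = 64L)
  g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)
  stats::setNames(counts / nw, paste0(g$b1, g$b2, g$b3))
}

#' Mononucleotide or dinucleotide shuffle of a residue string
#'
#' Mononucleotide shuffling permutes the residues uniformly. Dinucleotide
#' shuffling (Altschul-Erikson) preserves the exact dinucleotide counts by
#' sampling a random Eulerian walk on the base-transition multigraph.
#'
#' @param residues Residue string.
#' @param kind `"mono"` or `"dinucleotide"`.
#' @return Shuffled residue string. Uses the current RNG stream.
#' @export
shuffle_residues <- function(residues, kind = c("mono", "dinucleotide")) {
  kind <- match.arg(kind)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (kind == "mono") {
    return(paste(sample(chars), collapse = ""))
  }
  L <- length(chars)
  if (L < 3L) return(residues)
  verts <- unique(chars)
  edges <- lapply(stats::setNames(verts, verts), function(v) {
    chars[which(chars[-L] == v) + 1L]
  })
  last <- chars[L]
  repeat {
    # pick a random terminal edge for every non-final vertex; accept when the
    # chosen edges form a tree rooted at the final symbol
    pick <- lapply(edges, function(e) if (length(e)) sample(e, 1L) else character(0))
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character(0)
      repeat {
        if (cur == last) break
        if (cur %in% seen || length(pick[[cur]]) == 0L) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- pick[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  ordered <- lapply(stats::setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v == last || length(e) == 0L) return(sample(e))
    drop_one <- which(e == pick[[v]])[1L]
    c(sample(e[-drop_one]), pick[[v]])
  })
  walk <- character(L)
  walk[1L] <- chars[1L]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  for (k in 2:L) {
    v <- walk[k - 1L]
    walk[k] <- ordered[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
  }
  paste(walk, collapse = "")
}

#' Monte Carlo randomization-test P-value of folding stability
#'
#' Shuffles the sequence `shuffles` times (preserving mono- or dinucleotide
#' composition), folds each permutation with the backend, and counts how many
#' shuffled minimum free energies are at least as low (stable) as the
#' observed one. The estimator `P = (c + 1) / (shuffles + 1)` never returns
#' 0 and is reproducible for a fixed seed.
#'
#' @param rna An [annotated_rna]; `mfe` is used when present, otherwise the
#'   backend computes it.
#' @param backend A `folding_backend`.
#' @param shuffles Number of random permutations (>= 1).
#' @param seed RNG seed.
#' @param kind Shuffle type, `"mono"` (default) or `"dinucleotide"`.
#' @return P-value in `(0, 1]`.
#' @export
randomization_pvalue <- function(rna, backend = baseline_backend(),
                                 shuffles = 100L, seed = 1L,
                                 kind = c("mono", "dinucleotide")) {
  kind <- match.arg(kind)
  shuffles <- as.integer(shuffles)
  if (shuffles < 1L) stop("shuffles must be >= 1", call. = FALSE)
  stopifnot(inherits(backend, "folding_backend"))
  obs <- rna$mfe
  if (is.null(obs)) obs <- backend$fold(rna)$mfe
  c_le <- 0L
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  for (s in seq_len(shuffles)) {
    perm <- shuffle_residues(rna$residues, kind)
    m <- backend$fold(annotated_rna(paste0(rna$id, "_shuf", s), perm))$mfe
    if (m <= obs) c_le <- c_le + 1L
  }
  (c_le + 1) / (shuffles + 1)
}

#' Extended pseudo structure status composition (ExPseSSC)
#'
#' Concatenates the PseSSC vector with the record's MFE (`a`), a
#' randomization-test P-value (`b`) and the 64 tri-nucleotide frequencies,
#' for a total dimension of `10^n + lambda + 66`.
#'
#' @param rna An [annotated_rna] with `mfe` present.
#' @param statuses Its `status_sequence`.
#' @param params A [psessc_params].
#' @param table A [free_energy_table].
#' @param b_value Precomputed randomization P-value (see
#'   [randomization_pvalue]); required.
#' @return A `feature_vector` of kind `"ExPseSSC"`.
#' @export
ex_pse_ssc <- function(rna, statuses, params = psessc_params(n = 1L, lam = 17L, w = 0.2),
                       table = free_energy_table(), b_value = NULL) {
  if (is.null(rna$mfe)) {
    stop(sprintf("record '%s': MFE required for ExPseSSC (fold the record first)",
                 rna$id), call. = FALSE)
  }
  if (is.null(b_value)) {
    stop(sprintf("record '%s': randomization P-value (b) required for ExPseSSC",
                 rna$id), call. = FALSE)
  }
  base <- pse_ssc(statuses, params, table, record_id = rna$id,
                  label = rna$label)
  values <- c(base$values,
              mfe = rna$mfe, pvalue = as.numeric(b_value),
              trinucleotide_composition(rna))
  feature_vector(rna$id, "ExPseSSC", params, values, rna$label)
}

#' Feature vector container
#' @param record_id Record identifier.
#' @param kind `"PseSSC"` or `"ExPseSSC"`.
#' @param params The generating [psessc_params].
#' @param values Named numeric components.
#' @param label Optional class label.
#' @return Object of class `feature_vector`.
#' @export
feature_vector <- function(record_id, kind, params, values, label = NULL) {
  kind <- match.arg(kind, c("PseSSC", "ExPseSSC"))
  expected <- 10^params$n + params$lam + if (kind == "ExPseSSC") 66L else 0L
  if (length(values) != expected) {
    stop(sprintf("%s dimension %d != expected %d", kind, length(values),
                 expected), call. = FALSE)
  }
  structure(list(record_id = record_id, kind = kind, params = params,
                 values = values, label = label), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s %s dim %d (n=%d lambda=%d w=%g)%s\n",
              x$record_id, x$kind, length(x$values), x$params$n,
              x$params$lam, x$params$w,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Featurize a set of folded records
#'
#' Convenience driver: assigns statuses and computes one feature vector per
#' record. For ExPseSSC, P-values are taken from `b_values` when supplied,
#' otherwise computed by [randomization_pvalue] with `backend` (seeded per
#' record from `seed`).
#'
#' @param rnas List of [annotated_rna] with structures (and MFE for
#'   ExPseSSC).
#' @param kind `"PseSSC"` or `"ExPseSSC"`.
#' @param params A [psessc_params].
#' @param table A [free_energy_table].
#' @param convention Status convention, see [assign_statuses].
#' @param b_values Optional numeric vector of precomputed P-values (recycled
#'   names not used; positional).
#' @param backend Folding backend for P-value computation.
#' @param shuffles,seed Randomization-test controls.
#' @return List of `feature_vector`s.
#' @export
featurize <- function(rnas, kind = c("PseSSC", "ExPseSSC"),
                      params = psessc_params(), table = free_energy_table(),
                      convention = "own-first", b_values = NULL,
                      backend = baseline_backend(), shuffles = 100L,
                      seed = 1L) {
  kind <- match.arg(kind)
  lapply(seq_along(rnas), function(k) {
    rna <- rnas[[k]]
    st <- assign_statuses(rna, convention = convention)
    if (kind == "PseSSC") {
      pse_ssc(st, params, table, record_id = rna$id, label = rna$label)
    } else {
      if (is.null(rna$mfe)) rna$mfe <- pseudo_mfe(rna, table)
      b <- if (!is.null(b_values)) b_values[[k]] else {
        randomization_pvalue(rna, backend, shuffles = shuffles,
                             seed = seed + k, kind = "mono")
      }
      ex_pse_ssc(rna, st, params, table, b_value = b)
    }
  })
}
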