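#' Synthetic hairpin specification
#'
#' Describes a planted stem-loop: `stem_len` base pairs, a terminal loop,
#' optional bulges interrupting the stem, a G-C content dial for the stem
#' pairs, and unpaired flanking tails. Planted structures are emitted
#' directly in dot-bracket form, so status-assignment ground truth is exact
#' and no folder is needed.
#'
#' @param stem_len Number of stem base pairs (>= 1).
#' @param loop_len Terminal loop length in nt (>= 3).
#' @param bulge_rate Per-stem-position probability of inserting an unpaired
#'   bulge base on either arm.
#' @param gc_bias Probability a stem pair is G-C/C-G; the remainder splits
#'   4:1 between Watson-Crick A-U/U-A and wobble G-U/U-G.
#' @param flank_len Unpaired tail length on each side, nt.
#' @param seed Optional RNG seed for [generate_hairpin]/[generate_decoy].
#' @return Object of class `hairpin_spec`.
#' @export
hairpin_spec <- function(stem_len = 22L, loop_len = 4L, bulge_rate = 0.05,
                         gc_bias = 0.5, flank_len = 5L, seed = NULL) {
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  flank_len <- as.integer(flank_len)
  if (stem_len < 1L) stop("stem_len must be >= 1", call. = FALSE)
  if (loop_len < 3L) stop("loop_len must be >= 3 (minimal hairpin loop)",
                          call. = FALSE)
  if (flank_len < 0L) stop("flank_len must be >= 0", call. = FALSE)
  if (bulge_rate < 0 || bulge_rate > 1) stop("bulge_rate must lie in [0, 1]",
                                             call. = FALSE)
  if (gc_bias < 0 || gc_bias > 1) stop("gc_bias must lie in [0, 1]",
                                       call. = FALSE)
  structure(list(stem_len = stem_len, loop_len = loop_len,
                 bulge_rate = bulge_rate, gc_bias = gc_bias,
                 flank_len = flank_len, seed = seed),
            class = "hairpin_spec")
}

# Stem pair-type sampler and the matching marginal base distribution, so
# unpaired regions (loops, flanks, bulges) are composition-matched to the
# stems in expectation -- positives and decoys then differ by structure, not
# by base composition.
sample_pair_types <- function(k, gc_bias) {
  grp <- stats::runif(k)
  out <- character(k)
  gc <- grp < gc_bias
  au <- !gc & grp < gc_bias + (1 - gc_bias) * 0.8
  wob <- !gc & !au
  out[gc] <- sample(c("G-C", "C-G"), sum(gc), replace = TRUE)
  out[au] <- sample(c("A-U", "U-A"), sum(au), replace = TRUE)
  out[wob] <- sample(c("G-U", "U-G"), sum(wob), replace = TRUE)
  out
}

marginal_base_probs <- function(gc_bias) {
  g <- gc_bias
  c(A = (1 - g) * 0.8 / 2, C = g / 2,
    G = (g + (1 - g) * 0.2) / 2, U = (1 - g) / 2)
}

sample_bases <- function(k, gc_bias) {
  if (k == 0L) return(character(0))
  p <- marginal_base_probs(gc_bias)
  sample(names(p), k, replace = TRUE, prob = p)
}

# Assemble sequence + dot-bracket from stem pair types, with bulges.
build_stem_loop <- function(pair_types, loop_len, bulge_rate, gc_bias,
                            flank_len, gap_after = integer(0), gap_len = 0L) {
  left_seq <- character(0); left_db <- character(0)
  right_seq <- character(0); right_db <- character(0)  # 3' arm, 5'->3' order built last
  for (i in seq_along(pair_types)) {
    left_seq <- c(left_seq, substr(pair_types[i], 1L, 1L))
    left_db <- c(left_db, "(")
    right_seq <- c(substr(pair_types[i], 3L, 3L), right_seq)
    right_db <- c(")", right_db)
    if (i %in% gap_after) {  # interior-loop interruption (decoys)
      left_seq <- c(left_seq, sample_bases(gap_len, gc_bias))
      left_db <- c(left_db, rep(".", gap_len))
      right_seq <- c(sample_bases(gap_len, gc_bias), right_seq)
      right_db <- c(rep(".", gap_len), right_db)
    } else if (bulge_rate > 0 && i < length(pair_types)) {
      if (stats::runif(1) < bulge_rate) {
        left_seq <- c(left_seq, sample_bases(1L, gc_bias))
        left_db <- c(left_db, ".")
      }
      if (stats::runif(1) < bulge_rate) {
        right_seq <- c(sample_bases(1L, gc_bias), right_seq)
        right_db <- c(".", right_db)
      }
    }
  }
  loop <- sample_bases(loop_len, gc_bias)
  fl <- sample_bases(flank_len, gc_bias)
  fr <- sample_bases(flank_len, gc_bias)
  list(
    residues = paste(c(fl, left_seq, loop, right_seq, fr), collapse = ""),
    structure = paste(c(rep(".", flank_len), left_db, rep(".", loop_len),
                        right_db, rep(".", flank_len)), collapse = ""))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

#' Generate one synthetic hairpin (positive)
#'
#' A planted nested stem-loop: `stem_len` pairs drawn from the spec's pair
#' mix, bulges at `bulge_rate`, terminal loop and flanks drawn from the
#' stem-matched marginal base distribution. The dot-bracket is emitted
#' directly; the pseudo-MFE is the sum of status free energies over the
#' planted pairs.
#'
#' @param spec A [hairpin_spec].
#' @param id Record identifier.
#' @param seed Overrides `spec$seed` when given.
#' @param table A [free_energy_table] for the pseudo-MFE.
#' @return An [annotated_rna] with `label = "positive"`.
#' @export
generate_hairpin <- function(spec = hairpin_spec(), id = "hairpin",
                             seed = spec$seed, table = free_energy_table()) {
  stopifnot(inherits(spec, "hairpin_spec"))
  with_seed(seed, {
    types <- sample_pair_types(spec$stem_len, spec$gc_bias)
    parts <- build_stem_loop(types, spec$loop_len, spec$bulge_rate,
                             spec$gc_bias, spec$flank_len)
    rna <- annotated_rna(id, parts$residues, structure = parts$structure,
                         mfe = sum(status_free_energy(types, table)),
                         label = "positive")
    rna
  })
}

#' Generate one synthetic decoy (negative)
#'
#' A composition-matched pseudo hairpin with a weaker planted structure: the
#' (shorter) stem is interrupted by an interior loop at its midpoint, so
#' decoys sit near the pair-count admission boundary while sharing the
#' positives' mononucleotide composition in expectation. Unpaired regions
#' use the same marginal base distribution as [generate_hairpin].
#'
#' @inheritParams generate_hairpin
#' @param gap_len Interior-loop size inserted per arm at the stem midpoint
#'   (0 disables the interruption).
#' @return An [annotated_rna] with `label = "negative"`.
#' @export
generate_decoy <- function(spec = hairpin_spec(stem_len = 8L, flank_len = 19L),
                           id = "decoy", seed = spec$seed, gap_len = 3L,
                           table = free_energy_table()) {
  stopifnot(inherits(spec, "hairpin_spec"))
  with_seed(seed, {
    types <- sample_pair_types(spec$stem_len, spec$gc_bias)
    gap_after <- if (gap_len > 0L && spec$stem_len >= 4L) {
      spec$stem_len %/% 2L
    } else integer(0)
    parts <- build_stem_loop(types, spec$loop_len, spec$bulge_rate,
                             spec$gc_bias, spec$flank_len,
                             gap_after = gap_after, gap_len = gap_len)
    annotated_rna(id, parts$residues, structure = parts$structure,
                  mfe = sum(status_free_energy(types, table)),
                  label = "negative")
  })
}

#' Generate a labelled synthetic benchmark set
#'
#' `n_pos` planted hairpins and `n_neg` decoys from one seeded RNG stream;
#' record ids are `pos_0001`..., `neg_0001`....
#'
#' @param n_pos,n_neg Class sizes.
#' @param pos_spec,neg_spec [hairpin_spec]s for the two classes. Defaults:
#'   positives with 22-pair stems, decoys with 8-pair interrupted stems and
#'   longer flanks (similar overall length).
#' @param seed RNG seed for the whole set.
#' @param table A [free_energy_table].
#' @return List of [annotated_rna] records, positives first.
#' @export
simulate_hairpin_set <- function(n_pos = 200L, n_neg = 200L,
                                 pos_spec = hairpin_spec(),
                                 neg_spec = hairpin_spec(stem_len = 8L,
                                                         flank_len = 19L),
                                 seed = 1L, table = free_energy_table()) {
  with_seed(seed, {
    pos <- lapply(seq_len(n_pos), function(k) {
      generate_hairpin(pos_spec, id = sprintf("pos_%04d", k), seed = NULL,
                       table = table)
    })
    neg <- lapply(seq_len(n_neg), function(k) {
      generate_decoy(neg_spec, id = sprintf("neg_%04d", k), seed = NULL,
                     table = table)
    })
    c(pos, neg)
  })
}
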