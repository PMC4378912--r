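#' Pseudo-hairpin admission criteria
#'
#' The benchmark filters for miRNA-like pseudo hairpins: length 51-137 nt,
#' at least 18 base pairings in the hairpin, and a secondary-structure free
#' energy of at most -15 kcal/mol. All boundaries are inclusive.
#'
#' @param min_len,max_len Length bounds in nt.
#' @param min_pairs Minimum base-pair count.
#' @param max_mfe Maximum (i.e. least stable allowed) free energy, kcal/mol.
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_len = 51L, max_len = 137L, min_pairs = 18L,
                            max_mfe = -15) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (min_pairs < 0L) stop("min_pairs must be >= 0", call. = FALSE)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_pairs = as.integer(min_pairs),
                 max_mfe = as.numeric(max_mfe)),
            class = "filter_criteria")
}

#' Admit or reject a candidate pseudo hairpin
#'
#' Checks, in order: length within `[min_len, max_len]`, pair count from the
#' structure's pair table `>= min_pairs`, and `mfe <= max_mfe`. The first
#' violated criterion is reported as the failure reason.
#'
#' @param rna An [annotated_rna] with structure and MFE present.
#' @param crit A [filter_criteria].
#' @return List with `pass` (logical) and `reason` (`"ok"`, `"length"`,
#'   `"pairs"` or `"mfe"`).
#' @export
admit_pseudo_hairpin <- function(rna, crit = filter_criteria()) {
  if (is.null(rna$structure)) {
    stop(sprintf("record '%s' has no structure", rna$id), call. = FALSE)
  }
  if (is.null(rna$mfe)) {
    stop(sprintf("record '%s' has no MFE", rna$id), call. = FALSE)
  }
  L <- nchar(rna$residues)
  if (L < crit$min_len || L > crit$max_len) {
    return(list(pass = FALSE, reason = "length"))
  }
  if (count_pairs(rna$structure) < crit$min_pairs) {
    return(list(pass = FALSE, reason = "pairs"))
  }
  if (rna$mfe > crit$max_mfe) {
    return(list(pass = FALSE, reason = "mfe"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Balanced random subsample
#'
#' Uniform subset without replacement, seeded; the selected records keep
#' their original relative order.
#'
#' @param records List of records.
#' @param target_count Subset size (<= number of records).
#' @param seed RNG seed.
#' @return List of `target_count` records.
#' @export
balance_subsample <- function(records, target_count, seed = 1L) {
  n <- length(records)
  target_count <- as.integer(target_count)
  if (target_count > n) {
    stop(sprintf("target_count %d exceeds record count %d", target_count, n),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  keep <- sort(sample.int(n, target_count))
  records[keep]
}

#' Redundancy reduction through an external clustering tool
#'
#' Pure wrapper around a CD-HIT-style executable (`cmd -i in.fasta -o
#' out.fasta -c identity`): runs it and returns the ids of the retained
#' representative sequences. The clustering algorithm itself is out of
#' scope. When `skip = TRUE`, or the tool is absent and `skip_if_missing =
#' TRUE`, the stage is skipped with a warning and all ids are retained.
#'
#' @param fasta_path Input FASTA path.
#' @param identity Sequence-identity cutoff in `(0, 1]` (the benchmark uses
#'   0.8; CD-HIT's own floor for nucleotide input is 0.75).
#' @param command Clustering executable.
#' @param skip Skip the stage entirely.
#' @param skip_if_missing Skip (with warning) instead of erroring when the
#'   executable is absent.
#' @return Character vector of retained record ids.
#' @export
reduce_redundancy_external <- function(fasta_path, identity = 0.8,
                                       command = "cd-hit-est", skip = FALSE,
                                       skip_if_missing = FALSE) {
  all_ids <- vapply(read_fasta(fasta_path), function(r) r$id, character(1))
  if (skip) {
    warning("redundancy reduction skipped by flag; all records retained",
            call. = FALSE)
    return(all_ids)
  }
  if (identity <= 0 || identity > 1) {
    stop(sprintf("identity cutoff %g outside (0, 1]", identity), call. = FALSE)
  }
  exe <- Sys.which(command)
  if (!nzchar(exe) && !file.exists(command)) {
    if (skip_if_missing) {
      warning(sprintf("clustering tool '%s' not found; stage skipped, all records retained",
                      command), call. = FALSE)
      return(all_ids)
    }
    stop(sprintf("clustering tool '%s' not found: configure `cdhit-cmd` or skip the stage",
                 command), call. = FALSE)
  }
  out <- tempfile(fileext = ".fasta")
  on.exit(unlink(out), add = TRUE)
  status <- suppressWarnings(
    system2(if (nzchar(exe)) exe else command,
            args = c("-i", fasta_path, "-o", out, "-c", identity),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L)) {
    stop(sprintf("clustering tool '%s' failed (exit %s) at identity cutoff %g",
                 command, status, identity), call. = FALSE)
  }
  vapply(read_fasta(out), function(r) r$id, character(1))
}
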