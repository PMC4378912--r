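#' Folding backends
#'
#' A folding backend is a deterministic contract: given residues it returns a
#' balanced dot-bracket structure of the same length plus a free energy in
#' kcal/mol. The production backend shells out to an external thermodynamic
#' folder (RNAfold-style Vienna output); the baseline backend is a
#' self-contained maximum-base-pairing folder used for tests and the
#' synthetic pipeline. The baseline energy is NOT thermodynamic: it is the
#' sum of status free energies over the 5' side of each pair (A-U pairs
#' contribute -2, G-C -3, G-U -1 kcal/mol).
#'
#' @param min_loop Minimum hairpin loop size in nt (positions `i`, `j` may
#'   pair only when `j - i > min_loop`). Default 3, the standard minimal
#'   loop.
#' @param table A [free_energy_table] for the pseudo-MFE.
#' @return An object of class `folding_backend` with elements `name` and
#'   `fold` (a function `annotated_rna -> annotated_rna`).
#' @export
baseline_backend <- function(min_loop = 3L, table = free_energy_table()) {
  force(min_loop); force(table)
  structure(list(
    name = "baseline",
    fold = function(rna) baseline_fold(rna, min_loop = min_loop, table = table)
  ), class = "folding_backend")
}

#' Maximum base-pairing fold of one record
#'
#' Nussinov dynamic programming over canonical + wobble pairs with a minimum
#' loop constraint; deterministic traceback (a position pairs with the
#' largest admissible partner achieving the optimum). The pseudo-MFE is the
#' sum of status free energies over the 5' side of each pair.
#'
#' @param rna An [annotated_rna].
#' @inheritParams baseline_backend
#' @return The record with `structure` and `mfe` filled.
#' @export
baseline_fold <- function(rna, min_loop = 3L, table = free_energy_table()) {
  if (nchar(rna$residues) == 0L) stop("empty sequence", call. = FALSE)
  db <- .nussinov_fold_cpp(rna$residues, as.integer(min_loop))
  out <- annotated_rna(rna$id, rna$residues, structure = db,
                       label = rna$label, desc = rna$desc)
  out$mfe <- pseudo_mfe(out, table)
  out
}

# Sum of 5'-side pair-status free energies; 0 for a pairless structure.
pseudo_mfe <- function(rna, table = free_energy_table()) {
  pt <- build_pair_table(rna$structure)
  st <- assign_statuses(rna, pt)
  five <- which(!is.na(pt) & seq_along(pt) < pt)
  if (length(five) == 0L) return(0)
  sum(status_free_energy(st[five], table))
}

#' External folder backend
#'
#' Wraps an RNAfold-style executable: records are streamed to it as FASTA on
#' standard input in one batch, and its standard output is parsed as Vienna
#' records (`>id`, sequence, `structure (MFE)`) by [read_vienna].
#'
#' @param command Path or name of the folder executable; extra arguments may
#'   be given in `args`.
#' @param args Character vector of arguments passed to the command.
#' @return A `folding_backend`.
#' @export
external_backend <- function(command, args = character(0)) {
  if (is.null(command) || !nzchar(command)) {
    stop("no external folder configured: set `folder-cmd` to the folding executable",
         call. = FALSE)
  }
  force(command); force(args)
  structure(list(
    name = paste(c("external:", command), collapse = ""),
    fold = function(rna) external_fold(list(rna), command, args)[[1L]]
  ), class = "folding_backend")
}

#' Fold a batch of records through an external folder
#'
#' @param rnas List of [annotated_rna].
#' @inheritParams external_backend
#' @return List of records with structure and MFE populated, input order.
#' @export
external_fold <- function(rnas, command, args = character(0)) {
  exe <- Sys.which(command)
  if (!nzchar(exe) && !file.exists(command)) {
    stop(sprintf("external folder '%s' not found: set `folder-cmd` to an executable on PATH",
                 command), call. = FALSE)
  }
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".vienna")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(rnas, fin)
  status <- suppressWarnings(
    system2(if (nzchar(exe)) exe else command, args = args,
            stdin = fin, stdout = fout, stderr = FALSE))
  if (!identical(status, 0L)) {
    stop(sprintf("external folder '%s' exited with status %s", command, status),
         call. = FALSE)
  }
  folded <- tryCatch(read_vienna(fout), error = function(e) {
    stop(sprintf("cannot parse external folder output: %s", conditionMessage(e)),
         call. = FALSE)
  })
  if (length(folded) != length(rnas)) {
    stop(sprintf("external folder returned %d records for %d inputs",
                 length(folded), length(rnas)), call. = FALSE)
  }
  for (k in seq_along(rnas)) {
    if (nchar(folded[[k]]$structure) != nchar(rnas[[k]]$residues)) {
      stop(sprintf("record '%s': folder structure length %d != sequence length %d (raw line: %s)",
                   rnas[[k]]$id, nchar(folded[[k]]$structure),
                   nchar(rnas[[k]]$residues), folded[[k]]$structure),
           call. = FALSE)
    }
    folded[[k]]$label <- rnas[[k]]$label
    folded[[k]]$desc <- rnas[[k]]$desc
  }
  folded
}

#' Fold records with a backend
#' @param rnas List of [annotated_rna].
#' @param backend A `folding_backend`.
#' @return List of folded records.
#' @export
fold_rnas <- function(rnas, backend = baseline_backend()) {
  stopifnot(inherits(backend, "folding_backend"))
  lapply(rnas, backend$fold)
}
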