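#' Construct an annotated RNA record
#'
#' The basic record flowing through the pipeline: an identified RNA sequence
#' with an optional dot-bracket secondary structure, an optional minimum free
#' energy (MFE, kcal/mol) and an optional class label.
#'
#' @param id Character identifier (first whitespace-delimited token of a FASTA
#'   header). A longer description may be kept in `desc`; it is ignored by all
#'   computation.
#' @param residues Character scalar over `A`, `C`, `G`, `U` (input `T`/`t` and
#'   lowercase are normalized by the readers, not here).
#' @param structure Optional dot-bracket string over `.`, `(`, `)` of the same
#'   length as `residues`.
#' @param mfe Optional finite numeric free energy in kcal/mol.
#' @param label Optional class: `"positive"`, `"negative"` or `"unknown"`.
#' @param desc Optional free-text description.
#' @return An object of class `annotated_rna`.
#' @export
annotated_rna <- function(id, residues, structure = NULL, mfe = NULL,
                          label = NULL, desc = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  bad <- gsub("[ACGU]", "", residues)
  if (nzchar(bad)) {
    stop(sprintf("record '%s': invalid residue symbol '%s' (alphabet is A/C/G/U)",
                 id, substr(bad, 1L, 1L)), call. = FALSE)
  }
  if (!is.null(structure)) {
    if (nchar(structure) != nchar(residues)) {
      stop(sprintf("record '%s': structure length %d != sequence length %d",
                   id, nchar(structure), nchar(residues)), call. = FALSE)
    }
    if (grepl("[^.()]", structure)) {
      stop(sprintf("record '%s': structure contains symbols outside {., (, )} (pseudoknot notations are not supported)",
                   id), call. = FALSE)
    }
  }
  if (!is.null(mfe)) {
    mfe <- as.numeric(mfe)
    if (length(mfe) != 1L || !is.finite(mfe)) {
      stop(sprintf("record '%s': mfe must be a single finite number", id),
           call. = FALSE)
    }
  }
  if (!is.null(label)) {
    label <- match.arg(label, c("positive", "negative", "unknown"))
  }
  structure(list(id = id, residues = residues, structure = structure,
                 mfe = mfe, label = label, desc = desc),
            class = "annotated_rna")
}

#' @export
print.annotated_rna <- function(x, ...) {
  cat(sprintf("<annotated_rna> %s (%d nt%s%s%s)\n", x$id, nchar(x$residues),
              if (is.null(x$structure)) "" else ", folded",
              if (is.null(x$mfe)) "" else sprintf(", MFE %.2f", x$mfe),
              if (is.null(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' @export
length.annotated_rna <- function(x) nchar(x$residues)

# Normalize raw FASTA sequence text: uppercase, T -> U. Any other symbol is a
# hard error because every downstream formula assumes the 4-letter alphabet.
normalize_residues <- function(seq, id) {
  seq <- chartr("acgut", "ACGUU", seq)
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("record '%s': invalid residue symbol '%s' after normalization",
                 id, substr(bad, 1L, 1L)), call. = FALSE)
  }
  seq
}

read_text_lines <- function(con) {
  if (is.character(con) && length(con) == 1L && nzchar(con) &&
      !grepl("\n", con) && !startsWith(con, ">")) {
    if (!file.exists(con)) {
      stop(sprintf("cannot open file '%s': no such file", con), call. = FALSE)
    }
    lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  } else if (inherits(con, "connection")) {
    lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(paste(con, collapse = "\n"), "\n", fixed = TRUE))
  }
  sub("\r$", "", lines)
}

split_header <- function(line) {
  header <- sub("^>", "", line)
  id <- sub("\\s.*$", "", header)
  desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else NULL
  if (!nzchar(id)) stop("FASTA/Vienna header with empty id", call. = FALSE)
  list(id = id, desc = desc)
}

#' Read a FASTA file of RNA sequences
#'
#' Lowercase is uppercased and `T` is mapped to `U` (DNA-alphabet inputs are
#' common); any residue outside A/C/G/U after normalization aborts with an
#' error naming the record. Record order is preserved.
#'
#' @param con Path, connection, or character vector of file content.
#' @return List of [annotated_rna] records (structure absent).
#' @export
read_fasta <- function(con) {
  lines <- read_text_lines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1L] != 1L) {
    stop("not FASTA: first non-empty line must begin with '>'", call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    h <- split_header(lines[starts[k]])
    body <- if (ends[k] > starts[k]) {
      paste(lines[(starts[k] + 1L):ends[k]], collapse = "")
    } else ""
    body <- gsub("\\s", "", body)
    out[[k]] <- annotated_rna(h$id, normalize_residues(body, h$id),
                              desc = h$desc)
  }
  out
}

#' Read Vienna dot-bracket records
#'
#' Each record is a `>id` header line, a sequence line, and a structure line.
#' The structure line may end in a parenthesized MFE, as printed by RNAfold,
#' e.g. `(((...))) ( -1.20)`; the MFE is the last parenthesized token and any
#' whitespace before it is tolerated.
#'
#' @inheritParams read_fasta
#' @return List of [annotated_rna] records with `structure` (and `mfe` when
#'   present) populated.
#' @export
read_vienna <- function(con) {
  lines <- read_text_lines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^>", lines[i])) {
      stop(sprintf("Vienna parse error at line %d: expected '>' header, got '%s'",
                   i, lines[i]), call. = FALSE)
    }
    h <- split_header(lines[i])
    if (i + 2L > length(lines)) {
      stop(sprintf("Vienna record '%s': truncated (need sequence and structure lines)",
                   h$id), call. = FALSE)
    }
    seq <- normalize_residues(gsub("\\s", "", lines[i + 1L]), h$id)
    sline <- lines[i + 2L]
    parsed <- parse_structure_line(sline, h$id)
    if (nchar(parsed$structure) != nchar(seq)) {
      stop(sprintf("record '%s': structure length %d != sequence length %d",
                   h$id, nchar(parsed$structure), nchar(seq)), call. = FALSE)
    }
    out[[length(out) + 1L]] <- annotated_rna(h$id, seq,
                                             structure = parsed$structure,
                                             mfe = parsed$mfe, desc = h$desc)
    i <- i + 3L
  }
  out
}

# Split "(((...))) (-1.20)" into structure + MFE. The MFE, when present, is
# the last parenthesized token on the line.
parse_structure_line <- function(line, id) {
  line <- trimws(line)
  m <- regmatches(line, regexec("^([.()]+)(\\s+\\((.*)\\))?$", line))[[1L]]
  if (length(m) == 0L || !nzchar(m[2L])) {
    stop(sprintf("record '%s': unparsable structure line '%s'", id, line),
         call. = FALSE)
  }
  mfe <- NULL
  if (nzchar(m[3L])) {
    mfe <- suppressWarnings(as.numeric(trimws(m[4L])))
    if (is.na(mfe)) {
      stop(sprintf("record '%s': unparsable MFE suffix '(%s)'", id, m[4L]),
           call. = FALSE)
    }
  }
  list(structure = m[2L], mfe = mfe)
}

#' Write records as FASTA
#' @param rnas List of [annotated_rna].
#' @param path Output file path or connection.
#' @export
write_fasta <- function(rnas, path) {
  lines <- unlist(lapply(rnas, function(r) {
    header <- if (is.null(r$desc)) r$id else paste(r$id, r$desc)
    c(paste0(">", header), r$residues)
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
}

#' Write records as Vienna dot-bracket
#'
#' MFE, when present, is printed to two decimals in a trailing parenthesized
#' token, the dialect [read_vienna] consumes.
#' @inheritParams write_fasta
#' @export
write_vienna <- function(rnas, path) {
  lines <- unlist(lapply(rnas, function(r) {
    if (is.null(r$structure)) {
      stop(sprintf("record '%s' has no structure; fold it first", r$id),
           call. = FALSE)
    }
    sline <- if (is.null(r$mfe)) r$structure else {
      sprintf("%s (%.2f)", r$structure, r$mfe)
    }
    header <- if (is.null(r$desc)) r$id else paste(r$id, r$desc)
    c(paste0(">", header), r$residues, sline)
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
}

#' Write a feature table as TSV
#'
#' First column `id`, second `label` (empty when unknown), then one column per
#' feature with the vector's own feature names (status-tuple names for
#' composition components, `theta_1`... for correlation factors, `mfe`,
#' `pvalue` and tri-nucleotide names for the extended block). Values are
#' printed with 17 significant digits so the table round-trips bit-identically
#' through [read_feature_table].
#'
#' @param vectors List of [feature_vector] objects sharing identical
#'   parameters and dimension.
#' @param path Output file path or connection.
#' @export
write_feature_table <- function(vectors, path) {
  if (length(vectors) == 0L) {
    writeLines("id\tlabel", path)
    return(invisible(NULL))
  }
  dims <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(dims)) != 1L) {
    stop(sprintf("mixed feature dimensions: %s",
                 paste(unique(dims), collapse = ", ")), call. = FALSE)
  }
  kinds <- unique(vapply(vectors, function(v) v$kind, character(1)))
  if (length(kinds) != 1L) stop("mixed feature kinds", call. = FALSE)
  header <- c("id", "label", names(vectors[[1L]]$values))
  rows <- vapply(vectors, function(v) {
    lab <- if (is.null(v$label) || identical(v$label, "unknown")) "" else v$label
    paste(c(v$record_id, lab, sprintf("%.17g", v$values)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
}

#' Read a feature table written by [write_feature_table]
#' @param path Input file path or connection.
#' @return Data frame with `id`, `label` and one numeric column per feature.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L || !identical(names(df)[1:2], c("id", "label"))) {
    stop("not a feature table: first columns must be id, label", call. = FALSE)
  }
  if (ncol(df) > 2L) {
    df[-(1:2)] <- lapply(df[-(1:2)], as.numeric)
  }
  df
}
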