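#' The 10-symbol structure-status alphabet
#'
#' Four unpaired bases plus six orientation-distinguished base pairs. The
#' order is frozen package-wide: composition components, feature-table columns
#' and model bundles all index features in this order.
#'
#' @return Character vector of the 10 status symbols.
#' @export
status_alphabet <- function() {
  c("A", "C", "G", "U", "A-U", "U-A", "G-C", "C-G", "G-U", "U-G")
}

#' Default status free-energy table
#'
#' Hydrogen-bond-count surrogate energies: Watson-Crick A-U/U-A pairs (2
#' bonds) -2 kcal/mol, G-C/C-G (3 bonds) -3 kcal/mol, wobble G-U/U-G -1
#' kcal/mol, unpaired bases 0. Symmetric under pair-orientation reversal.
#'
#' @param overrides Optional named numeric vector of status -> energy
#'   replacements (names must be status symbols).
#' @return Named numeric vector over the full alphabet, class
#'   `free_energy_table`.
#' @export
free_energy_table <- function(overrides = NULL) {
  tab <- c("A" = 0, "C" = 0, "G" = 0, "U" = 0,
           "A-U" = -2, "U-A" = -2, "G-C" = -3, "C-G" = -3,
           "G-U" = -1, "U-G" = -1)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(tab))
    if (length(bad)) {
      stop(sprintf("unknown status in free-energy overrides: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    tab[names(overrides)] <- as.numeric(overrides)
  }
  structure(tab, class = "free_energy_table")
}

#' Read a free-energy table from a key-value config file
#'
#' Lines of `status<TAB or spaces>value`; `#` comments and blank lines are
#' skipped. Unlisted statuses keep their defaults.
#' @param path File path.
#' @return A [free_energy_table].
#' @export
read_free_energy_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(free_energy_table())
  parts <- strsplit(trimws(lines), "\\s+")
  ok <- lengths(parts) == 2L
  if (!all(ok)) {
    stop(sprintf("bad free-energy config line: '%s'", lines[!ok][1L]),
         call. = FALSE)
  }
  vals <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2L])),
                 numeric(1))
  if (anyNA(vals)) stop("non-numeric free-energy value in config", call. = FALSE)
  free_energy_table(stats::setNames(vals, vapply(parts, `[`, "", 1L)))
}

#' Free energy of a structure status
#' @param status Status symbol(s) from [status_alphabet()].
#' @param table A [free_energy_table].
#' @return Numeric energy (kcal/mol), vectorized over `status`.
#' @export
status_free_energy <- function(status, table = free_energy_table()) {
  unknown <- setdiff(unique(status), names(table))
  if (length(unknown)) {
    stop(sprintf("unknown structure status: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unname(table[status])
}

#' Build a pair table from dot-bracket notation
#'
#' Stack-matches nested brackets. Pseudoknot notations (`[`, `{`, `<`) are
#' rejected: the pipeline only consumes nested structures.
#'
#' @param structure Dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector of length `L`, 1-based partner index per position,
#'   `NA` for unpaired; class `pair_table`.
#' @export
build_pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    stop(sprintf("invalid structure symbol '%s' at position %d (pseudoknot notations are not supported)",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced structure: unmatched ')' at position %d", i),
             call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced structure: unmatched '(' at position %d",
                 stack[length(stack)]), call. = FALSE)
  }
  structure(partner, class = "pair_table")
}

#' Count base pairs in a pair table or dot-bracket string
#' @param x A `pair_table` or dot-bracket string.
#' @return Integer number of pairs.
#' @export
count_pairs <- function(x) {
  if (is.character(x)) x <- build_pair_table(x)
  sum(!is.na(x)) %/% 2L
}

canonical_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Assign per-position structure statuses
#'
#' Unpaired position i keeps its base as status; paired position i gets the
#' composite status joining its own base with its partner's. Under the
#' default `own-first` convention the status at i is `base[i]-base[partner]`,
#' so the two partners of a pair carry each other's reversal (a G:C pair
#' reads `G-C` on the 5' side and `C-G` on the 3' side). The alternative
#' `five-prime-first` convention labels both partners with the 5' base first.
#'
#' @param rna An [annotated_rna] with structure present.
#' @param table Optional precomputed `pair_table` consistent with
#'   `rna$structure`.
#' @param convention `"own-first"` (default) or `"five-prime-first"`.
#' @return Character vector of statuses, class `status_sequence`.
#' @export
assign_statuses <- function(rna, table = NULL,
                            convention = c("own-first", "five-prime-first")) {
  convention <- match.arg(convention)
  if (is.null(rna$structure)) {
    stop(sprintf("record '%s' has no structure", rna$id), call. = FALSE)
  }
  if (is.null(table)) table <- build_pair_table(rna$structure)
  bases <- strsplit(rna$residues, "", fixed = TRUE)[[1L]]
  if (length(table) != length(bases)) {
    stop(sprintf("record '%s': pair table length %d != sequence length %d",
                 rna$id, length(table), length(bases)), call. = FALSE)
  }
  statuses <- bases
  paired <- which(!is.na(table))
  if (length(paired)) {
    own <- bases[paired]
    prt <- bases[table[paired]]
    duo <- paste0(own, prt)
    bad <- which(!duo %in% canonical_pairs)
    if (length(bad)) {
      stop(sprintf("record '%s': non-canonical pair %s:%s at positions %d and %d",
                   rna$id, own[bad[1L]], prt[bad[1L]],
                   paired[bad[1L]], table[paired][bad[1L]]), call. = FALSE)
    }
    if (convention == "own-first") {
      statuses[paired] <- paste0(own, "-", prt)
    } else {
      five <- pmin(paired, table[paired])
      statuses[paired] <- paste0(bases[five], "-", bases[table[five]])
    }
  }
  structure(statuses, class = "status_sequence")
}
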