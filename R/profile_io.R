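#' Amino-acid column ordering of PSI-BLAST PSSM output
#'
#' The fixed 20-letter ordering used for PSSM columns throughout the package:
#' `A R N D C Q E G H I L K M F P S T W Y V`. Profiles produced by other tools
#' must be remapped to this ordering before use.
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM profile object
#'
#' A PSSM profile is the L x 20 integer matrix of position-specific
#' substitution scores produced by an iterative profile search (PSI-BLAST
#' log-odds block), together with the query sequence it was computed for.
#' Row i, column j holds the score of residue i against amino-acid type j in
#' the [AA_ORDER] column ordering.
#'
#' @param protein_id Single string identifying the protein.
#' @param scores Integer matrix, L rows x 20 columns.
#' @param residue_letters Single string of length L: the query residues
#'   (ambiguity codes such as X, B, Z are accepted and kept).
#' @return An object of class `pssm_profile` with fields `protein_id`,
#'   `scores`, `residue_letters` and `aa_order`.
#' @examples
#' p <- pssm_profile("toy", matrix(0L, 3, 20), "MKV")
#' dim(p$scores)
#' @export
pssm_profile <- function(protein_id, scores, residue_letters) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) {
    stop("empty profile: a PSSM needs at least one residue row", call. = FALSE)
  }
  if (ncol(scores) != 20L) {
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores), call. = FALSE)
  }
  if (any(scores != round(scores))) {
    stop("PSSM scores must be integers", call. = FALSE)
  }
  storage.mode(scores) <- "integer"
  if (!is.character(residue_letters) || length(residue_letters) != 1L ||
      nchar(residue_letters) != nrow(scores)) {
    stop("residue_letters must be a single string of length L = ",
         nrow(scores), call. = FALSE)
  }
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(
    list(protein_id = protein_id, scores = scores,
         residue_letters = residue_letters, aa_order = AA_ORDER),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile", x$protein_id, ":", nrow(x$scores), "residues x 20 amino-acid columns\n")
  cat("score range [", min(x$scores), ",", max(x$scores), "]\n")
  invisible(x)
}

# A residue row starts with a 1-based position index and a single letter.
.is_pssm_row <- function(lines) {
  grepl("^\\s*[0-9]+\\s+[A-Za-z](\\s|$)", lines)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the ASCII matrix dialect written by PSI-BLAST (`-Q` / checkpoint
#' style output): header lines, then one row per residue starting with a
#' 1-based position index and the residue letter, followed by at least 20
#' integer columns. Only the first 20 integers per row (the log-odds block)
#' are kept; trailing weighted-percentage columns and statistics lines are
#' ignored.
#'
#' @param path Path to the PSSM file.
#' @param protein_id Protein identifier; defaults to the file name without
#'   its extension.
#' @return A [pssm_profile].
#' @seealso [write_psiblast_pssm()], [read_profile_tsv()]
#' @export
parse_psiblast_pssm <- function(path, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  is_row <- .is_pssm_row(lines)
  if (!any(is_row)) {
    stop("empty profile: no residue rows found in '", path, "'", call. = FALSE)
  }
  row_lines <- which(is_row)
  npos <- length(row_lines)
  positions <- integer(npos)
  letters <- character(npos)
  scores <- matrix(NA_integer_, npos, 20L)
  for (r in seq_len(npos)) {
    ln <- row_lines[r]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    positions[r] <- as.integer(tok[1L])
    letters[r] <- tok[2L]
    vals <- tok[-(1:2)]
    is_int <- grepl("^-?[0-9]+$", vals)
    # the log-odds block is the leading run of plain integers
    if (length(vals) < 20L || !all(is_int[1:20])) {
      stop("malformed PSSM row at line ", ln, " of '", path,
           "': fewer than 20 integer score columns", call. = FALSE)
    }
    scores[r, ] <- as.integer(vals[1:20])
  }
  if (!identical(positions, seq_len(npos))) {
    bad <- which(positions != seq_len(npos))[1L]
    stop("non-consecutive residue positions in '", path, "': expected ",
         bad, " at row ", bad, ", found ", positions[bad], call. = FALSE)
  }
  pssm_profile(protein_id, scores, paste(letters, collapse = ""))
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Emits a minimal file in the same layout [parse_psiblast_pssm()] reads
#' (two header lines, then position / residue / 20 integer scores per row),
#' so synthetic profiles are byte-compatible with real PSI-BLAST runs.
#'
#' @param profile A [pssm_profile].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  letters <- strsplit(profile$residue_letters, "")[[1]]
  header <- c(
    "Last position-specific scoring matrix computed",
    paste0("      ", paste(sprintf("%3s", AA_ORDER), collapse = " "))
  )
  rows <- vapply(seq_len(nrow(profile$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, letters[i]),
           paste(sprintf("%3d", profile$scores[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Serialize a profile as tab-separated text
#'
#' Round-trippable TSV serialization: a `#id` header line, then one line per
#' residue carrying the residue letter and its 20 integer scores.
#'
#' @param profile A [pssm_profile].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_profile_tsv()]
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  letters <- strsplit(profile$residue_letters, "")[[1]]
  lines <- c(
    paste0("#id\t", profile$protein_id),
    vapply(seq_len(nrow(profile$scores)), function(i) {
      paste(c(letters[i], profile$scores[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile written by [write_profile_tsv()]
#'
#' @param path Path to the TSV profile file.
#' @return A [pssm_profile] identical to the one written.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "#id\t")) {
    stop("not a profile TSV (missing '#id' header): '", path, "'", call. = FALSE)
  }
  protein_id <- sub("^#id\t", "", lines[1L])
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(body) != 21L)
  if (length(bad)) {
    stop("malformed profile TSV row at line ", bad[1L] + 1L, " of '", path,
         "'", call. = FALSE)
  }
  letters <- vapply(body, `[`, character(1), 1L)
  scores <- t(vapply(body, function(x) as.integer(x[-1L]), integer(20)))
  pssm_profile(protein_id, scores, paste(letters, collapse = ""))
}
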