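#' Protein records
#'
#' A `protein_record` is the atomic input of the feature pipeline: one
#' identifier plus one amino-acid sequence over the 20-letter alphabet.
#' Lowercase input is uppercased; the ambiguity/rare codes B, J, Z, U and O
#' are mapped to `X`, and `X` positions are excluded from composition
#' denominators downstream. Any other character is rejected.
#'
#' @param id single non-empty string.
#' @param sequence single string of amino-acid letters, length >= 1.
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence` (normalized, uppercase).
#' @examples
#' protein_record("P1", "mkvLLA")
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(sprintf("<protein_record> %s (%d aa)\n%s\n", x$id, nchar(x$sequence), seq))
  invisible(x)
}

# Uppercase, map nonstandard codes to X, reject anything else.
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must have length >= 1")
  chars <- strsplit(sequence, "")[[1]]
  bad <- !(chars %in% c(.aa_alphabet_split, .aa_nonstandard, "X"))
  if (any(bad)) {
    stop(sprintf("invalid residue(s) in sequence: %s",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  chars[chars %in% .aa_nonstandard] <- "X"
  paste(chars, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Wrapped lines are joined, bodies are uppercased and the header token before
#' the first whitespace becomes the record id. Duplicate ids and empty files
#' are errors.
#'
#' @param path path to a FASTA file.
#' @return list of [protein_record()] objects, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 example", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- as.character(set)
  mapply(protein_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record()] objects.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    body <- substring(r$sequence,
                      seq(1, nchar(r$sequence), by = width),
                      pmin(seq(width, nchar(r$sequence) + width - 1, by = width),
                           nchar(r$sequence)))
    c(paste0(">", r$id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}
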