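#' Sequence records
#'
#' A `seq_record` is a lightweight container for a single named sequence:
#' an identifier, an optional free-text description, the residues as an
#' uppercase character string, and an optional genomic `offset` used when the
#' record is a slice of a larger chromosome (the residue at string position 1
#' then corresponds to genomic coordinate `offset + 1`).
#'
#' DNA records may contain IUPAC ambiguity codes; `U` is converted to `T`
#' with a warning. All user-facing coordinates in this package are 1-based
#' and inclusive.
#'
#' @param id Record identifier (single string, no whitespace).
#' @param residues Sequence string (case-insensitive on input).
#' @param description Optional description (stored after the id on FASTA
#'   headers).
#' @param type `"dna"` or `"protein"`; guessed from the alphabet when `NULL`.
#' @param offset Genomic coordinate of the base preceding string position 1
#'   (default 0, i.e. the record starts at coordinate 1).
#' @return An object of class `seq_record`.
#' @examples
#' r <- seq_record("x", "acgt")
#' r$residues # "ACGT"
#' @export
seq_record <- function(id, residues, description = "", type = NULL,
                       offset = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("seq_record: residues must be non-empty")
  if (is.null(type)) {
    type <- if (grepl("^[ACGTUNRYSWKMBDHV-]+$", residues)) "dna" else "protein"
  }
  type <- match.arg(type, c("dna", "protein"))
  if (type == "dna" && grepl("U", residues, fixed = TRUE)) {
    warning("seq_record '", id, "': U mapped to T")
    residues <- gsub("U", "T", residues, fixed = TRUE)
  }
  structure(list(id = id, description = as.character(description),
                 residues = residues, type = type, offset = as.numeric(offset)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("seq_record '%s' (%s, %d %s)%s\n", x$id, x$type, n,
              if (x$type == "dna") "nt" else "aa",
              if (x$offset != 0) sprintf(", offset %s", format(x$offset, big.mark = ","))
              else ""))
  show <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("  ", show, "\n", sep = "")
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

seq_len_nt <- function(x) nchar(x$residues)

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC DNA alphabet plus `-`.
#'
#' @param x A character string of DNA.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                 "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# extract 1-based inclusive substring from a record honouring its offset
record_slice <- function(record, start, end) {
  s <- start - record$offset
  e <- end - record$offset
  n <- seq_len_nt(record)
  if (s < 1 || e > n || s > e)
    stop(sprintf("coordinates %s-%s outside record '%s' (offset %s, length %d)",
                 format(start, big.mark = ","), format(end, big.mark = ","),
                 record$id, format(record$offset, big.mark = ","), n))
  substr(record$residues, s, e)
}
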