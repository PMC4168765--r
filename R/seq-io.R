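#' Read a FASTA file into a list of sequence records
#'
#' Thin wrapper over [Biostrings::readBStringSet()]: residues are uppercased,
#' whitespace is stripped, `U` is mapped to `T` with a warning on DNA
#' records, and headers are split into id (first word) and description
#' (remainder).
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"`, `"protein"`, or `NULL` to guess per record.
#' @return A named list of [seq_record] objects, in file order. An empty
#'   file yields an empty list.
#' @export
read_fasta <- function(path, type = NULL) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0) return(list())
  first <- readLines(path, n = 50L, warn = FALSE)
  nonempty <- which(nzchar(trimws(first)))
  if (length(nonempty) == 0) return(list())
  if (!startsWith(trimws(first[nonempty[1]]), ">"))
    stop(sprintf("read_fasta: %s line %d: expected FASTA header ('>')",
                 path, nonempty[1]))
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    bad <- names(set)[Biostrings::width(set) == 0][1]
    stop("read_fasta: empty record '", bad, "' in ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]), description = descs[i],
               type = type)
  })
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param records A [seq_record], or a list of them.
#' @param path Output path.
#' @param line_width Residues per sequence line (default 60).
#' @return Invisibly, `path`. Round trip with [read_fasta()] is the identity
#'   on (id, description, residues).
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  stopifnot(length(records) > 0, line_width >= 1)
  seqs <- vapply(records, function(r) r$residues, character(1))
  hdrs <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Apply known sequence edits to a record
#'
#' Edits (substitutions, deletions, insertions) are specified against the
#' unedited sequence with 1-based positions and applied from the highest
#' position downwards, so earlier edits never shift the coordinates of later
#' ones. The reference allele of each edit is checked against the sequence
#' and a mismatch is an error. This is the mechanism used to pre-edit
#' predicted transcript sequences for known variants (e.g. a reported CAG
#' deletion or a strain SNP) before comparing them with observed reads.
#'
#' @param record A [seq_record].
#' @param edits A data frame with columns `position`, `kind`
#'   (`"substitution"`, `"deletion"` or `"insertion"`), `ref`, `alt`; see
#'   [read_edits_tsv()]. For insertions `ref` is the single base after which
#'   `alt` is inserted; for deletions `alt` must be empty.
#' @return The edited [seq_record] (id suffixed with nothing; description
#'   annotated with the number of edits).
#' @export
apply_sequence_edits <- function(record, edits) {
  stopifnot(inherits(record, "seq_record"))
  if (is.null(edits) || nrow(edits) == 0) return(record)
  req <- c("position", "kind", "ref", "alt")
  if (!all(req %in% names(edits)))
    stop("edits must have columns: ", paste(req, collapse = ", "))
  edits$kind <- as.character(edits$kind)
  bad <- setdiff(unique(edits$kind), c("substitution", "deletion", "insertion"))
  if (length(bad)) stop("unknown edit kind: ", paste(bad, collapse = ", "))
  edits$ref <- toupper(ifelse(is.na(edits$ref), "", edits$ref))
  edits$alt <- toupper(ifelse(is.na(edits$alt), "", edits$alt))
  edits <- edits[order(-edits$position), , drop = FALSE]
  s <- record$residues
  for (i in seq_len(nrow(edits))) {
    pos <- edits$position[i]; kind <- edits$kind[i]
    ref <- edits$ref[i]; alt <- edits$alt[i]
    if (kind == "substitution" && nchar(ref) != nchar(alt))
      stop("substitution ref/alt length mismatch at position ", pos)
    if (kind == "deletion" && nzchar(alt))
      stop("deletion must have empty alt (position ", pos, ")")
    w <- nchar(ref)
    if (pos < 1 || pos + w - 1 > nchar(s))
      stop("edit at position ", pos, " outside sequence (length ", nchar(s), ")")
    found <- substr(s, pos, pos + w - 1)
    if (w > 0 && found != ref)
      stop(sprintf("edit conflict at position %d: expected '%s', found '%s'",
                   pos, ref, found))
    s <- switch(kind,
      substitution = paste0(substr(s, 1, pos - 1), alt,
                            substr(s, pos + w, nchar(s))),
      deletion = paste0(substr(s, 1, pos - 1), substr(s, pos + w, nchar(s))),
      insertion = paste0(substr(s, 1, pos + w - 1), alt,
                         substr(s, pos + w, nchar(s))))
  }
  out <- record
  out$residues <- s
  out$description <- trimws(paste(record$description,
                                  sprintf("[%d edit(s) applied]", nrow(edits))))
  out
}

#' Read sequence edits from a 4-column TSV
#'
#' Columns: `position` (1-based), `kind`, `ref`, `alt`.
#'
#' @param path Path to the TSV file.
#' @return A data frame suitable for [apply_sequence_edits()].
#' @export
read_edits_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("position", "kind", "ref", "alt")
  if (!all(req %in% names(df)))
    stop("edits TSV must have columns: ", paste(req, collapse = ", "))
  df$position <- as.integer(df$position)
  df
}
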