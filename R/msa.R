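#' K-mer distance matrix between sequences
#'
#' Fractional k-mer distance: `1 - shared / (min(len_a, len_b) - k + 1)`,
#' where `shared` sums the minimum of the two k-mer count vectors. Used to
#' build the progressive-alignment guide tree.
#'
#' @param seqs Named character vector of sequences.
#' @param k K-mer size (default 6).
#' @return A symmetric distance matrix.
#' @keywords internal
kmer_distance <- function(seqs, k = 6L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    common <- intersect(names(ci), names(cj))
    shared <- sum(pmin(ci[common], cj[common]))
    denom <- max(1, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1)
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

# profile: matrix (5 x L) of column frequencies over A,C,G,T plus other/N;
# gap fraction tracked implicitly by columns summing to < 1
PROFILE_ALPHA <- c("A", "C", "G", "T", "N")

profile_from_rows <- function(rows) {
  L <- nchar(rows[1])
  mat <- matrix(0, length(PROFILE_ALPHA), L,
                dimnames = list(PROFILE_ALPHA, NULL))
  for (r in rows) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    ch[!(ch %in% c("A", "C", "G", "T", "-"))] <- "N"
    for (a in PROFILE_ALPHA) mat[a, ] <- mat[a, ] + (ch == a)
  }
  mat / length(rows)
}

insert_gap_columns <- function(rows, gap_before) {
  # gap_before: ascending positions (1..L+1) where a gap column is inserted
  if (length(gap_before) == 0) return(rows)
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    out <- character(length(ch) + length(gap_before))
    idx <- setdiff(seq_along(out), gap_before + seq_along(gap_before) - 1L)
    out[idx] <- ch
    out[setdiff(seq_along(out), idx)] <- "-"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

merge_profiles <- function(rows_a, rows_b, params) {
  Sab <- score_matrix_profiles(profile_from_rows(rows_a),
                               profile_from_rows(rows_b), params)
  res <- affine_dp(Sab, params$gap_open, params$gap_extend, 0L)
  path <- res$path
  gaps_a <- which(path[, 1] == 0) # columns where A gets a gap
  gaps_b <- which(path[, 2] == 0)
  # positions (in original column coords) before which to insert gaps
  before_a <- path[, 1]; before_b <- path[, 2]
  # for each gap column, the gap is inserted before the next consumed column
  na_cols <- nchar(rows_a[1]); nb_cols <- nchar(rows_b[1])
  gap_before_a <- integer(0); gap_before_b <- integer(0)
  nexta <- 1L; nextb <- 1L
  for (r in seq_len(nrow(path))) {
    if (path[r, 1] == 0) gap_before_a <- c(gap_before_a, nexta)
    else nexta <- path[r, 1] + 1L
    if (path[r, 2] == 0) gap_before_b <- c(gap_before_b, nextb)
    else nextb <- path[r, 2] + 1L
  }
  c(insert_gap_columns(rows_a, gap_before_a),
    insert_gap_columns(rows_b, gap_before_b))
}

score_matrix_profiles <- function(P1, P2, params) {
  k <- length(PROFILE_ALPHA)
  S <- matrix(params$mismatch, k, k)
  diag(S) <- params$match
  # N columns score 0 against everything
  S[k, ] <- 0; S[, k] <- 0
  t(P1) %*% S %*% P2
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive aligner: a guide tree from k-mer distances
#' (k = 6) and UPGMA (average-linkage clustering), then profile–profile
#' alignment along the tree using the affine-gap engine of [align()].
#' There is no iterative refinement, so figure-level identities from
#' refinement-based tools are reproduced approximately, not bit-exactly.
#'
#' @param seqs List of [seq_record]s (or named character vector), at least
#'   two, over a common alphabet.
#' @param params [align_params()] (global mode is used for merges).
#' @param reference_id Optional row id used for percent-identity reporting.
#' @return An object of class `msa_result`: `rows` (named character vector
#'   of equal-length gapped sequences, input order), `reference_id`, and
#'   `identity_to_reference` (per-row percent, when a reference is set).
#' @export
progressive_msa <- function(seqs, params = align_params(),
                            reference_id = NULL) {
  if (inherits(seqs, "seq_record")) seqs <- list(seqs)
  if (is.list(seqs)) {
    v <- vapply(seqs, function(r)
      if (inherits(r, "seq_record")) r$residues else toupper(r), character(1))
    nm <- names(seqs)
    ids <- vapply(seqs, function(r)
      if (inherits(r, "seq_record")) r$id else NA_character_, character(1))
    if (is.null(nm) || any(!nzchar(nm))) nm <- ids
    names(v) <- nm
    seqs <- v
  } else seqs <- toupper(seqs)
  if (length(seqs) < 2) stop("progressive_msa needs at least 2 sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (params$mode != "global") params$mode <- "global"

  if (length(unique(nchar(seqs))) == 1 && length(unique(seqs)) == 1) {
    rows <- seqs # identical sequences: trivial alignment
  } else {
    D <- kmer_distance(seqs, k = 6L)
    tree <- hclust(as.dist(D), method = "average") # UPGMA guide tree
    clusters <- lapply(seq_along(seqs), function(i) setNames(seqs[i], names(seqs)[i]))
    for (s in seq_len(nrow(tree$merge))) {
      pick <- function(x) if (x < 0) clusters[[-x]] else merged[[x]]
      if (s == 1) merged <- list()
      a <- pick(tree$merge[s, 1]); b <- pick(tree$merge[s, 2])
      m <- merge_profiles(a, b, params)
      names(m) <- c(names(a), names(b))
      merged[[s]] <- m
    }
    rows <- merged[[nrow(tree$merge)]][names(seqs)]
  }
  out <- structure(list(rows = rows, reference_id = reference_id,
                        params = params), class = "msa_result")
  if (!is.null(reference_id))
    out$identity_to_reference <- percent_identity_to_reference(out, reference_id)
  out
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("msa_result: %d rows x %d columns\n", length(x$rows),
              nchar(x$rows[1])))
  for (i in seq_along(x$rows)) {
    r <- x$rows[i]
    show <- if (nchar(r) > 50) paste0(substr(r, 1, 47), "...") else r
    pid <- if (!is.null(x$identity_to_reference))
      sprintf(" %5.1f%%", x$identity_to_reference[i]) else ""
    cat(sprintf("  %-12s %s%s\n", names(x$rows)[i], show, pid))
  }
  invisible(x)
}

#' Percent identity to a reference row
#'
#' For each row: identical columns among the reference's non-gap columns,
#' divided by the reference's non-gap column count, as a percentage.
#'
#' @param msa An `msa_result`.
#' @param reference_id Row name of the reference.
#' @return Named numeric vector of percentages (reference = 100).
#' @export
percent_identity_to_reference <- function(msa, reference_id = msa$reference_id) {
  if (is.null(reference_id) || !reference_id %in% names(msa$rows))
    stop("reference id not present in the alignment")
  ref <- strsplit(msa$rows[[reference_id]], "", fixed = TRUE)[[1]]
  keep <- ref != "-"
  denom <- sum(keep)
  vapply(msa$rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    100 * sum(keep & ch == ref & ch != "-") / denom
  }, numeric(1))
}

degap_map <- function(row) {
  # alignment column of each degapped position
  ch <- strsplit(row, "", fixed = TRUE)[[1]]
  which(ch != "-")
}

#' Find conserved stop-codon or polyA-signal columns
#'
#' A feature is reported at an alignment column when at least `min_support`
#' of the rows carry it in register there: for `kind = "stop"`, an
#' in-frame stop codon (per-row frame offsets on the degapped sequences
#' are required) whose first base maps to that column; for
#' `kind = "polyA"`, a motif occurrence whose first base maps to that
#' column.
#'
#' @param msa An `msa_result` over nucleotide sequences.
#' @param kind `"stop"` or `"polyA"`.
#' @param min_support Minimum fraction of rows (default 0.5).
#' @param frame_offsets Named integer vector (0/1/2) per row, required for
#'   `kind = "stop"`: offset of the reading frame on the degapped row.
#' @param motifs Motif set for `kind = "polyA"` (default `AATAAA`).
#' @return Data frame with `column` (first-base alignment column),
#'   `kind`, `support`, `n_rows`.
#' @export
find_conserved_columns <- function(msa, kind = c("stop", "polyA"),
                                   min_support = 0.5, frame_offsets = NULL,
                                   motifs = "AATAAA") {
  kind <- match.arg(kind)
  rows <- msa$rows
  n <- length(rows)
  hits <- list()
  for (nm in names(rows)) {
    deg <- gsub("-", "", rows[[nm]], fixed = TRUE)
    cmap <- degap_map(rows[[nm]])
    pos <- if (kind == "stop") {
      off <- if (is.null(frame_offsets)) 0L else frame_offsets[[nm]]
      if (is.null(off)) stop("no frame offset for row '", nm, "'")
      scan_inframe_stops(deg, off)
    } else {
      find_polya_signals(deg, motifs)$position
    }
    if (length(pos)) hits[[nm]] <- cmap[pos]
  }
  if (length(hits) == 0)
    return(data.frame(column = integer(0), kind = character(0),
                      support = numeric(0), n_rows = integer(0)))
  tab <- table(unlist(lapply(hits, unique)))
  support <- as.numeric(tab) / n
  keep <- support >= min_support
  out <- data.frame(column = as.integer(names(tab))[keep],
                    kind = rep(kind, sum(keep)),
                    support = support[keep], n_rows = as.integer(tab)[keep])
  out[order(out$column), , drop = FALSE]
}

#' Cross-species truncation table
#'
#' Runs the intron-retention truncation prediction for each species locus
#' and assembles a comparative table: predicted novel peptide, stop
#' presence, boundary-phase conservation relative to the reference
#' species, and percent identity of the novel peptide to the reference
#' peptide (from a progressive MSA of the peptides). Rows are ordered by
#' descending identity to the reference, reference first.
#'
#' @param loci Named list (by species id); each element a list with
#'   `gene` ([gene_model]), `genome` ([seq_record]), `intron_index`, and
#'   optionally `frame_anchor`.
#' @param reference Species id used as reference (default: first).
#' @param params [align_params()] for the peptide MSA.
#' @return A data frame of class `species_truncation_table`.
#' @export
cross_species_truncation_table <- function(loci, reference = names(loci)[1],
                                           params = align_params()) {
  stopifnot(length(loci) >= 1, reference %in% names(loci))
  reports <- lapply(names(loci), function(sp) {
    l <- loci[[sp]]
    b <- build_intron_retained(l$gene, l$genome, l$intron_index)
    anchor <- if (!is.null(l$frame_anchor)) l$frame_anchor else b$frame_anchor
    list(species = sp, report = predict_truncation(b, anchor))
  })
  names(reports) <- names(loci)
  ref_phase <- phase_of(reports[[reference]]$report)
  peptides <- vapply(reports, function(x) x$report$novel_peptide, character(1))
  pid <- rep(NA_real_, length(reports))
  names(pid) <- names(loci)
  usable <- nzchar(peptides)
  if (sum(usable) >= 2 && nzchar(peptides[[reference]])) {
    recs <- lapply(names(peptides)[usable], function(sp)
      seq_record(sp, peptides[[sp]], type = "protein"))
    msa <- progressive_msa(recs, params, reference_id = reference)
    pid[names(msa$identity_to_reference)] <- msa$identity_to_reference
  } else if (nzchar(peptides[[reference]])) {
    pid[reference] <- 100
  }
  df <- do.call(rbind, lapply(names(loci), function(sp) {
    r <- reports[[sp]]$report
    data.frame(species = sp,
               novel_peptide = r$novel_peptide,
               novel_length = r$novel_length,
               stop_present = !r$no_stop,
               truncated_at_end = r$no_stop,
               frame_conserved = identical(phase_of(r), ref_phase),
               identity_to_reference = unname(pid[sp]))
  }))
  ord <- order(df$species != reference, -ifelse(is.na(df$identity_to_reference),
                                                -Inf, df$identity_to_reference))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("species_truncation_table", class(df))
  df
}

phase_of <- function(report) {
  if (is.null(report$boundary_codon)) 0L else
    as.integer(report$boundary_codon[["n_exonic_nt"]])
}

#' Write an MSA to aligned FASTA
#'
#' @param msa An `msa_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  recs <- lapply(names(msa$rows), function(nm)
    seq_record(nm, msa$rows[[nm]], type = NULL))
  write_fasta(recs, path)
}
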