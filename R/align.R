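#' Alignment parameters
#'
#' Scoring for the deterministic affine-gap aligner. The gap model charges
#' `gap_open` for the first position of a gap run and `gap_extend` for each
#' further position (`gap_open >= gap_extend >= 0`). Two modes are
#' available: `"global"` (global with free end gaps — terminal overhangs are
#' unpenalized, suitable for aligning a read against a longer predicted
#' sequence) and `"local"` (best-scoring subalignment, Smith–Waterman
#' style). Traceback ties are broken deterministically: diagonal, then up
#' (gap in the second sequence), then left.
#'
#' Defaults follow common nucleotide practice: match +5 / mismatch -4 with
#' gap open 12 / extend 3 for global mode (the gap penalties used for the
#' read-vs-prediction comparisons), and gap open 10 / extend 0.5 for local
#' mode. A full substitution matrix can be supplied to override
#' match/mismatch scoring.
#'
#' @param match,mismatch Scores for identical / differing residues.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param mode `"global"` (free end gaps) or `"local"`.
#' @param matrix Optional square numeric matrix with residue dimnames,
#'   overriding `match`/`mismatch`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4,
                         gap_open = if (mode == "local") 10 else 12,
                         gap_extend = if (mode == "local") 0.5 else 3,
                         mode = c("global", "local"), matrix = NULL) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode, matrix = matrix),
            class = "align_params")
}

score_lookup <- function(a_chars, b_chars, params) {
  if (!is.null(params$matrix)) {
    M <- params$matrix
    missing_a <- setdiff(unique(a_chars), rownames(M))
    missing_b <- setdiff(unique(b_chars), colnames(M))
    if (length(missing_a) || length(missing_b))
      stop("residues absent from scoring matrix: ",
           paste(unique(c(missing_a, missing_b)), collapse = ", "))
    return(M[a_chars, b_chars, drop = FALSE])
  }
  S <- outer(a_chars, b_chars, function(x, y)
    ifelse(x == y, params$match, params$mismatch))
  S
}

#' Pairwise alignment with affine gaps
#'
#' Optimal pairwise alignment under [align_params()]: global with free end
#' gaps, or local. Deterministic for fixed inputs.
#'
#' @param a,b Sequences: character strings or [seq_record]s over a common
#'   alphabet (both nucleotide or both protein).
#' @param params An [align_params()] object.
#' @return An object of class `pairwise_alignment`: `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `a_range`,
#'   `b_range` (1-based spans of the aligned cores), `mode`, and `stats`
#'   (see [alignment_stats()]).
#' @export
align <- function(a, b, params = align_params()) {
  ida <- "a"; idb <- "b"
  if (inherits(a, "seq_record")) { ida <- a$id; ta <- a$type; a <- a$residues } else ta <- NULL
  if (inherits(b, "seq_record")) { idb <- b$id; tb <- b$type; b <- b$residues } else tb <- NULL
  if (!is.null(ta) && !is.null(tb) && ta != tb)
    stop("alphabet mismatch: '", ida, "' is ", ta, ", '", idb, "' is ", tb)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  S <- score_lookup(ac, bc, params)
  res <- affine_dp(S, params$gap_open, params$gap_extend,
                   if (params$mode == "local") 1L else 0L)
  path <- res$path
  ga <- ifelse(path[, 1] == 0, "-", ac[pmax(path[, 1], 1)])
  gb <- ifelse(path[, 2] == 0, "-", bc[pmax(path[, 2], 1)])
  out <- structure(list(
    aligned_a = paste(ga, collapse = ""), aligned_b = paste(gb, collapse = ""),
    id_a = ida, id_b = idb, score = res$score, mode = params$mode,
    a_range = c(res$a_start, res$a_end), b_range = c(res$b_start, res$b_end),
    params = params), class = "pairwise_alignment")
  out$stats <- alignment_stats(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(format_alignment(x, width = width))
  invisible(x)
}

# IUPAC nucleotide compatibility: do the base sets of two symbols intersect?
iupac_compatible <- function(x, y) {
  map <- Biostrings::IUPAC_CODE_MAP
  sx <- ifelse(x %in% names(map), map[x], x)
  sy <- ifelse(y %in% names(map), map[y], y)
  mapply(function(p, q) {
    any(strsplit(p, "")[[1]] %in% strsplit(q, "")[[1]])
  }, sx, sy, USE.NAMES = FALSE)
}

#' Alignment statistics (identities / positives / gaps)
#'
#' Computed over the full alignment length: identities are exact-match
#' columns, positives add columns whose symbols are IUPAC-compatible (for
#' nucleotides, e.g. `R` vs `A`), gaps are columns with a gap in either row.
#'
#' @param aln A `pairwise_alignment`.
#' @param positive_rule `"iupac"` (default) or `"identity"`.
#' @return A list with `length` and per-statistic `n` and `pct`.
#' @export
alignment_stats <- function(aln, positive_rule = c("iupac", "identity")) {
  positive_rule <- match.arg(positive_rule)
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  L <- length(ga)
  if (L == 0)
    return(list(length = 0L,
                identities = list(n = 0L, pct = NaN),
                positives = list(n = 0L, pct = NaN),
                gaps = list(n = 0L, pct = NaN)))
  gap <- ga == "-" | gb == "-"
  ident <- !gap & ga == gb
  pos <- ident
  if (positive_rule == "iupac") {
    cand <- !gap & !ident
    if (any(cand)) pos[cand] <- iupac_compatible(ga[cand], gb[cand])
  }
  pct <- function(n) 100 * n / L
  list(length = L,
       identities = list(n = sum(ident), pct = pct(sum(ident))),
       positives = list(n = sum(pos), pct = pct(sum(pos))),
       gaps = list(n = sum(gap), pct = pct(sum(gap))))
}

#' Substitution spectrum of a nucleotide alignment
#'
#' Counts transitions (A<->G, C<->T), transversions (all other mismatches),
#' and gaps — both as maximal gap-run events and total gapped positions.
#' Optionally restricted to a column interval (e.g. the span covered by a
#' repeat consensus, excluding terminal overhangs).
#'
#' @param aln A `pairwise_alignment` of nucleotide sequences.
#' @param columns Optional `c(first, last)` alignment-column interval.
#' @return A list with `transitions`, `transversions`, `gap_events`,
#'   `gap_nt`.
#' @export
substitution_spectrum <- function(aln, columns = NULL) {
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  if (!is.null(columns)) {
    idx <- seq.int(columns[1], columns[2])
    ga <- ga[idx]; gb <- gb[idx]
  }
  gap <- ga == "-" | gb == "-"
  mm <- !gap & ga != gb
  purine <- function(x) x %in% c("A", "G")
  ts <- sum(mm & ((purine(ga) & purine(gb)) | (!purine(ga) & !purine(gb) &
              ga %in% c("C", "T") & gb %in% c("C", "T"))))
  tv <- sum(mm) - ts
  # gap runs are counted per row: adjacent indels in opposite rows are
  # separate events
  n_runs <- function(x) { r <- rle(x == "-"); sum(r$values) }
  ev <- n_runs(ga) + n_runs(gb)
  list(transitions = ts, transversions = tv,
       gap_events = as.integer(ev), gap_nt = as.integer(sum(gap)))
}

#' Format a pairwise alignment as an EMBOSS-style text block
#'
#' @param aln A `pairwise_alignment`.
#' @param width Residues per block line.
#' @return A single string (use `cat()` to display).
#' @export
format_alignment <- function(aln, width = 60) {
  st <- aln$stats
  hdr <- sprintf(
    paste0("# %s vs %s  (%s)\n# Score: %.1f  Length: %d\n",
           "# Identity: %d/%d (%.1f%%)  Similarity: %d/%d (%.1f%%)  Gaps: %d/%d (%.1f%%)\n"),
    aln$id_a, aln$id_b, aln$mode, aln$score, st$length,
    st$identities$n, st$length, st$identities$pct,
    st$positives$n, st$length, st$positives$pct,
    st$gaps$n, st$length, st$gaps$pct)
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  marks <- ifelse(ga == "-" | gb == "-", " ", ifelse(ga == gb, "|", "."))
  blocks <- character(0)
  for (s in seq(1, max(length(ga), 1), by = width)) {
    e <- min(s + width - 1, length(ga))
    if (s > length(ga)) break
    blocks <- c(blocks, sprintf("%-8s %s\n%-8s %s\n%-8s %s\n", aln$id_a,
                paste(ga[s:e], collapse = ""), "",
                paste(marks[s:e], collapse = ""), aln$id_b,
                paste(gb[s:e], collapse = "")))
  }
  paste0(hdr, paste(blocks, collapse = "\n"))
}

#' Batch pairwise alignment of two FASTA files
#'
#' Aligns records pairwise (first vs first, etc., recycling a single record
#' in either file) and returns alignments plus a Table-style stats frame.
#'
#' @param fasta_a,fasta_b Paths to FASTA files.
#' @param params [align_params()].
#' @return A list with `alignments` and `stats` (data frame with identities,
#'   positives and gaps per pair).
#' @export
align_fasta <- function(fasta_a, fasta_b, params = align_params()) {
  ra <- read_fasta(fasta_a); rb <- read_fasta(fasta_b)
  n <- max(length(ra), length(rb))
  if (!(length(ra) %in% c(1L, n)) || !(length(rb) %in% c(1L, n)))
    stop("record counts are incompatible: ", length(ra), " vs ", length(rb))
  alns <- lapply(seq_len(n), function(i) {
    align(ra[[min(i, length(ra))]], rb[[min(i, length(rb))]], params)
  })
  stats <- do.call(rbind, lapply(alns, function(al) {
    s <- al$stats
    data.frame(id_a = al$id_a, id_b = al$id_b, score = al$score,
               length = s$length,
               identities_n = s$identities$n, identities_pct = s$identities$pct,
               positives_n = s$positives$n, positives_pct = s$positives$pct,
               gaps_n = s$gaps$n, gaps_pct = s$gaps$pct)
  }))
  list(alignments = alns, stats = stats)
}
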