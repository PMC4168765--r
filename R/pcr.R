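#' Primer objects
#'
#' A primer is a short oligonucleotide written 5'-to-3'. Forward primers
#' are matched against the template as-is; reverse primers as their
#' reverse complement.
#'
#' @param name Primer name.
#' @param sequence DNA string, 5'-to-3' (length >= 10, unambiguous bases
#'   unless `allow_ambiguous`).
#' @param role `"forward"` or `"reverse"`.
#' @param allow_ambiguous Permit IUPAC ambiguity codes (default FALSE).
#' @return An object of class `primer`.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse"),
                   allow_ambiguous = FALSE) {
  role <- match.arg(role)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 10) stop("primer '", name, "' shorter than 10 nt")
  ok <- if (allow_ambiguous) "^[ACGTNRYSWKMBDHV]+$" else "^[ACGT]+$"
  if (!grepl(ok, sequence))
    stop("primer '", name, "' contains disallowed characters")
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' Read primers from a TSV file
#'
#' Columns: `name`, `role`, `sequence`.
#'
#' @param path Path to the TSV.
#' @return A named list of [primer] objects.
#' @export
read_primer_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "role", "sequence")
  if (!all(req %in% names(df)))
    stop("primer TSV must have columns: ", paste(req, collapse = ", "))
  out <- lapply(seq_len(nrow(df)),
                function(i) primer(df$name[i], df$sequence[i], df$role[i]))
  names(out) <- df$name
  out
}

#' Find primer binding sites on a template
#'
#' Forward primers are matched as-is, reverse primers as their reverse
#' complement. Sites with more than `max_mismatch` mismatches, or with any
#' mismatch at the primer's 3'-terminal base (which would abolish extension)
#' are excluded. Sites are returned in ascending template order; no hit is
#' an empty frame, not an error.
#'
#' @param template A [seq_record] or DNA string.
#' @param prm A [primer].
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @param require_3prime_match Enforce the 3'-terminal-match rule (default
#'   TRUE).
#' @return Data frame with columns `start`, `end` (1-based template
#'   interval), `orientation`, `mismatches`.
#' @export
find_binding_sites <- function(template, prm, max_mismatch = 0L,
                               require_3prime_match = TRUE) {
  stopifnot(inherits(prm, "primer"))
  tmpl <- if (inherits(template, "seq_record")) template$residues else
    toupper(template)
  pat <- if (prm$role == "forward") prm$sequence else revcomp(prm$sequence)
  mp <- Biostrings::matchPattern(pat, Biostrings::DNAString(tmpl),
                                 max.mismatch = as.integer(max_mismatch))
  if (length(mp) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), mismatches = integer(0)))
  starts <- Biostrings::start(mp); ends <- Biostrings::end(mp)
  pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
  keep <- logical(length(starts)); mism <- integer(length(starts))
  for (i in seq_along(starts)) {
    site <- strsplit(substr(tmpl, starts[i], ends[i]), "", fixed = TRUE)[[1]]
    mm <- site != pchars
    mism[i] <- sum(mm)
    # the primer 3' end is the last base of a forward match but the first
    # template base of a reverse-complemented match
    three_prime_ok <- if (prm$role == "forward") !mm[length(mm)] else !mm[1]
    keep[i] <- mism[i] <= max_mismatch &&
      (!require_3prime_match || three_prime_ok)
  }
  data.frame(start = starts, end = ends,
             orientation = rep(prm$role, length(starts)),
             mismatches = mism)[keep, , drop = FALSE]
}

#' Predict an amplicon from a primer-site pair
#'
#' Product length is `reverse_end - forward_start + 1`. When a segment map
#' (from a `transcript_build`) is supplied, the prediction also reports
#' whether the amplicon spans a retained-intron segment.
#'
#' @param template_id Template identifier for the report.
#' @param forward_site,reverse_site Sites as `c(start, end)` template
#'   intervals (e.g. rows of [find_binding_sites()] output).
#' @param segment_map Optional `segments` data frame of a
#'   `transcript_build`.
#' @return An object of class `amplicon_prediction` with `product_length`
#'   and `spans_retained_intron`.
#' @export
predict_amplicon <- function(template_id, forward_site, reverse_site,
                             segment_map = NULL) {
  fs <- as.numeric(forward_site); rs <- as.numeric(reverse_site)
  if (fs[1] > fs[2] || rs[1] > rs[2]) stop("malformed primer site interval")
  if (fs[2] >= rs[1])
    stop("forward site must end before the reverse site begins ",
         sprintf("(got forward %d-%d, reverse %d-%d)", fs[1], fs[2], rs[1], rs[2]))
  len <- rs[2] - fs[1] + 1
  spans <- FALSE
  if (!is.null(segment_map)) {
    intr <- segment_map[grepl("^intron_", segment_map$label), , drop = FALSE]
    if (nrow(intr) > 0)
      spans <- any(intr$t_start <= rs[2] & intr$t_end >= fs[1])
  }
  structure(list(template_id = template_id,
                 forward_site = c(fs[1], fs[2]),
                 reverse_site = c(rs[1], rs[2]),
                 product_length = len,
                 spans_retained_intron = spans),
            class = "amplicon_prediction")
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  cat(sprintf("amplicon on '%s': F %d-%d, R %d-%d, product %d bp%s\n",
              x$template_id, x$forward_site[1], x$forward_site[2],
              x$reverse_site[1], x$reverse_site[2], x$product_length,
              if (x$spans_retained_intron) " (spans retained intron)" else ""))
  invisible(x)
}

#' In-silico PCR of a primer pair on a template
#'
#' Finds all binding sites of the forward and reverse primer and predicts
#' every correctly oriented, non-overlapping amplicon, optionally capped by
#' a maximum product size.
#'
#' @param template A [seq_record] or string; if a `transcript_build` is
#'   given its sequence and segment map are used.
#' @param forward,reverse [primer] objects.
#' @param max_mismatch Passed to [find_binding_sites()].
#' @param max_product Maximum product length to report (default `Inf`).
#' @return A list of `amplicon_prediction`s (possibly empty).
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatch = 0L,
                         max_product = Inf) {
  segmap <- NULL
  tid <- "template"
  if (inherits(template, "transcript_build")) {
    segmap <- template$segments
    tid <- paste0(template$gene_id, "_", template$variant)
    template <- seq_record(tid, template$sequence, type = "dna")
  } else if (inherits(template, "seq_record")) tid <- template$id
  fsites <- find_binding_sites(template, forward, max_mismatch)
  rsites <- find_binding_sites(template, reverse, max_mismatch)
  out <- list()
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    if (fsites$end[i] < rsites$start[j]) {
      amp <- predict_amplicon(tid, c(fsites$start[i], fsites$end[i]),
                              c(rsites$start[j], rsites$end[j]), segmap)
      if (amp$product_length <= max_product) out[[length(out) + 1]] <- amp
    }
  }
  out
}

#' Amplicon table for primer pairs across templates
#'
#' Convenience wrapper mirroring a primer-details table: one row per
#' (template, primer pair) with binding ranges and expected product size.
#'
#' @param templates Named list of templates (`seq_record` or
#'   `transcript_build`).
#' @param pairs List of `list(forward = , reverse = )` primer pairs.
#' @param max_mismatch Passed through.
#' @return Data frame with template, primer names, binding coordinates and
#'   product sizes (`NA` where a pair yields no product).
#' @export
amplicon_table <- function(templates, pairs, max_mismatch = 0L) {
  rows <- list()
  for (tn in names(templates)) for (p in pairs) {
    amps <- insilico_pcr(templates[[tn]], p$forward, p$reverse, max_mismatch)
    if (length(amps) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        template = tn, forward = p$forward$name, reverse = p$reverse$name,
        f_start = NA, f_end = NA, r_start = NA, r_end = NA,
        product_bp = NA, spans_retained_intron = NA)
    } else for (a in amps) {
      rows[[length(rows) + 1]] <- data.frame(
        template = tn, forward = p$forward$name, reverse = p$reverse$name,
        f_start = a$forward_site[1], f_end = a$forward_site[2],
        r_start = a$reverse_site[1], r_end = a$reverse_site[2],
        product_bp = a$product_length,
        spans_retained_intron = a$spans_retained_intron)
    }
  }
  do.call(rbind, rows)
}

#' Adapt a primer to a homologous context in another species
#'
#' Globally aligns the source context (which must contain the primer's
#' binding-strand footprint exactly) against the homologous target context
#' with free end gaps, projects the primer footprint through the alignment,
#' and returns the target bases over the footprint as the adapted primer.
#' A gap inside the projected footprint sets `failed = TRUE`.
#'
#' @param prm A [primer].
#' @param source_context DNA string containing the primer footprint (for a
#'   reverse primer, the footprint is the reverse complement of the primer).
#' @param target_context Homologous DNA string from the target species.
#' @param params [align_params()] for the context alignment.
#' @return A list with `primer` (adapted [primer]), `n_substitutions`,
#'   and `failed`.
#' @export
adapt_primer <- function(prm, source_context, target_context,
                         params = align_params()) {
  stopifnot(inherits(prm, "primer"))
  source_context <- toupper(source_context)
  target_context <- toupper(target_context)
  foot <- if (prm$role == "forward") prm$sequence else revcomp(prm$sequence)
  at <- regexpr(foot, source_context, fixed = TRUE)
  if (at == -1)
    stop("primer '", prm$name, "' footprint not found in source context")
  fs <- as.integer(at); fe <- fs + nchar(foot) - 1L
  if (params$mode != "global") params$mode <- "global"
  aln <- align(seq_record("src", source_context, type = "dna"),
               seq_record("tgt", target_context, type = "dna"), params)
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  src_pos <- cumsum(ga != "-")
  cols <- which(src_pos >= fs & src_pos <= fe & ga != "-")
  tgt <- gb[cols]
  failed <- any(tgt == "-") || length(cols) < nchar(foot)
  tgt_foot <- paste(tgt[tgt != "-"], collapse = "")
  adapted_seq <- if (prm$role == "forward") tgt_foot else revcomp(tgt_foot)
  n_sub <- if (failed) NA_integer_ else
    sum(strsplit(foot, "")[[1]] != strsplit(tgt_foot, "")[[1]])
  adapted <- if (nchar(adapted_seq) >= 10 && grepl("^[ACGT]+$", adapted_seq))
    primer(paste0(prm$name, "_adapted"), adapted_seq, prm$role) else NULL
  list(primer = adapted, n_substitutions = n_sub, failed = failed)
}
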