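#' Synthetic locus generation
#'
#' Generates a multi-exon gene on a random background with a designated
#' retained intron carrying, in order: the reading-frame continuation
#' (novel codons to a planted premature stop), a polyadenylation signal, a
#' transcription termination site, and optionally an inserted element
#' flanked by a target-site duplication (TSD) with an oligo(dA) tail.
#' Primer pairs are placed in exons and in the retained intron. Everything
#' needed for parameter-recovery testing is recorded in a ground-truth
#' manifest, and every planted feature is re-detected with the pipeline's
#' own detectors before the locus is returned (bounded rejection sampling;
#' generation fails rather than emit an inconsistent locus).
#'
#' Deterministic for fixed `(params, seed)`; the global RNG state is not
#' disturbed.
#'
#' @param params Named list overriding defaults; see
#'   [synthetic_locus_params()].
#' @param seed Integer seed (recorded in the manifest).
#' @param dir Optional output directory; when given, writes `genome.fasta`,
#'   `gene.gff3`, `primers.tsv`, `est.fasta` and `truth.json`.
#' @return A list with `genome` ([seq_record]), `gene` ([gene_model]),
#'   `primers` (named list of [primer]s), `est` (a TTS-supporting EST
#'   [seq_record]), and `truth` (the manifest).
#' @export
generate_locus <- function(params = list(), seed = 1L, dir = NULL) {
  p <- utils::modifyList(synthetic_locus_params(), params)
  validate_locus_params(p)
  out <- withr::with_seed(as.integer(seed), generate_locus_impl(p, seed))
  if (!is.null(dir)) write_locus(out, dir)
  out
}

#' Default synthetic-locus parameters
#'
#' The defaults mirror the structure reported for the human locus: a
#' boundary codon with one exonic nucleotide, a 22-residue novel
#' C-terminal, a single `AATAAA` signal at intron position 290, and an
#' EST-supported termination site at intron position 357. Sizes are kept
#' small (hundreds of nt) so full parameter-recovery grids run quickly.
#'
#' @return Named list of parameters: `exon_lengths`, `intron_lengths`,
#'   `retained_intron`, `cds_start`, `boundary_phase` (exonic nt in the
#'   boundary codon: 0, 1 or 2), `novel_length` (codons before the stop),
#'   `stop_triplet`, `polya_position` / `tts_position` (intron-relative),
#'   `flank` (genomic padding), `insert` (NULL or a list with `consensus`,
#'   `transitions`, `transversions`, `gap_events` (vector of deletion
#'   lengths), `tsd_length`, `tail_length`, `signal_to_tsd`), and
#'   `primer_length`.
#' @export
synthetic_locus_params <- function() {
  list(exon_lengths = c(150L, 120L, 90L),
       intron_lengths = c(120L, 600L),
       retained_intron = 2L,
       cds_start = 31L,
       boundary_phase = 1L,
       novel_length = 22L,
       stop_triplet = "TAA",
       polya_position = 290L,
       tts_position = 357L,
       flank = 50L,
       insert = NULL,
       primer_length = 22L,
       max_retries = 25L)
}

validate_locus_params <- function(p) {
  stopifnot(length(p$exon_lengths) >= 2,
            length(p$intron_lengths) == length(p$exon_lengths) - 1,
            p$retained_intron >= 1,
            p$retained_intron <= length(p$exon_lengths) - 1,
            p$boundary_phase %in% 0:2,
            p$novel_length >= 0,
            p$stop_triplet %in% c("TAA", "TAG", "TGA"),
            p$cds_start >= 1,
            p$polya_position >= 1, p$tts_position >= p$polya_position + 6)
  k <- p$retained_intron
  novel_nt <- novel_intron_nt(p$boundary_phase, p$novel_length)
  if (p$polya_position <= novel_nt + 3)
    stop("generation error: polya_position must lie downstream of the planted stop")
  need <- p$tts_position
  if (!is.null(p$insert)) {
    ins <- p$insert
    cons_len <- if (inherits(ins$consensus, "seq_record"))
      nchar(ins$consensus$residues) else nchar(ins$consensus)
    need <- p$polya_position + 5 + ins$signal_to_tsd +
      2 * ins$tsd_length + cons_len + ins$tail_length + 20
  }
  if (p$intron_lengths[k] < need + 10)
    stop("generation error: retained intron (", p$intron_lengths[k],
         " nt) too short for planted features (need >= ", need + 10, " nt)")
  invisible(TRUE)
}

novel_intron_nt <- function(phase, novel_length) {
  # intronic nt consumed by novel codons before the stop
  if (phase > 0) {
    if (novel_length == 0) 0L else (3L - phase) + 3L * (novel_length - 1L)
  } else 3L * novel_length
}

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

rand_sense_codons <- function(n) {
  if (n <= 0) return("")
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

generate_locus_impl <- function(p, seed) {
  k <- p$retained_intron
  exon_lengths <- as.integer(p$exon_lengths)
  # adjust the pre-intron exon so the requested boundary phase holds
  cds_nt_before <- sum(exon_lengths[1:k]) - (p$cds_start - 1L)
  if (cds_nt_before < 3) stop("generation error: no coding sequence before the retained intron")
  shift <- (p$boundary_phase - (cds_nt_before %% 3L)) %% 3L
  exon_lengths[k] <- exon_lengths[k] + shift
  cds_nt_before <- cds_nt_before + shift

  # spliced coding sequence: all sense codons (no premature stop anywhere)
  total_exonic <- sum(exon_lengths)
  coding_len <- total_exonic - (p$cds_start - 1L)
  coding <- substr(rand_sense_codons(ceiling(coding_len / 3) + 1), 1, coding_len)
  exonic <- paste0(rand_dna(p$cds_start - 1L), coding)

  # novel_length 0 with a split boundary codon is only realizable when the
  # exonic prefix is compatible with the stop triplet: rewrite the spliced
  # codon straddling the boundary so exon k ends with that prefix
  if (p$novel_length == 0 && p$boundary_phase > 0) {
    E <- sum(exon_lengths[1:k])
    cstart <- E - p$boundary_phase + 1L # codon start (phase = exonic nt)
    prefix <- substr(p$stop_triplet, 1, p$boundary_phase)
    cands <- SENSE_CODONS[startsWith(SENSE_CODONS, prefix)]
    codon <- sample(cands, 1)
    exonic <- paste0(substr(exonic, 1, cstart - 1L), codon,
                     substr(exonic, cstart + 3L, nchar(exonic)))
  }

  # split the exonic sequence into exons
  stops_at <- cumsum(exon_lengths)
  exon_seqs <- substring(exonic, c(1L, head(stops_at, -1) + 1L), stops_at)

  intron_seqs <- vapply(p$intron_lengths, rand_dna, character(1))
  exon_k_end <- substr(exon_seqs[k], nchar(exon_seqs[k]) - 2L, nchar(exon_seqs[k]))

  # build the retained intron, rejecting accidental AATAAA occurrences in
  # the transcribed window; occurrences inside protected feature cores
  # cannot be scrubbed, so the whole intron is rebuilt in that case
  done <- FALSE
  for (try in seq_len(p$max_retries)) {
    ri <- build_retained_intron_seq(p, exonic_tail = exon_k_end,
                                    phase = p$boundary_phase)
    cand <- ri$sequence
    for (try2 in seq_len(p$max_retries)) {
      hits <- find_polya_signals(cand)$position
      bad <- setdiff(hits[hits <= p$tts_position], ri$truth$polya_position)
      if (length(bad) == 0) { done <- TRUE; break }
      if (all(vapply(bad, function(pp)
        length(setdiff(seq.int(pp, pp + 5L), ri$protect)) == 0, logical(1))))
        break # unscrubbable: rebuild
      cand <- scrub_motif(cand, bad, protect = ri$protect)
    }
    if (done) break
  }
  if (!done) stop("generation error: could not isolate polyA signal")
  intron_seqs[k] <- cand

  flank5 <- rand_dna(p$flank); flank3 <- rand_dna(p$flank)
  pieces <- character(0)
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i])
    if (i < length(exon_seqs)) pieces <- c(pieces, intron_seqs[i])
  }
  gseq <- paste0(flank5, paste(pieces, collapse = ""), flank3)
  genome <- seq_record("synth_chr", gseq, description = "synthetic locus")

  # exon genomic coordinates
  starts <- integer(length(exon_seqs)); ends <- integer(length(exon_seqs))
  pos <- p$flank
  for (i in seq_along(exon_seqs)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + exon_lengths[i]
    pos <- ends[i]
    if (i < length(exon_seqs)) pos <- pos + nchar(intron_seqs[i])
  }
  gene <- gene_model("synth_gene", "synth_chr", "+",
                     data.frame(start = starts, end = ends), p$cds_start)

  spliced <- build_spliced(gene, genome)
  retained <- build_intron_retained(gene, genome, k)

  primers <- design_locus_primers(p, spliced, retained, k)

  est <- seq_record("synth_est",
                    paste0(substr(intron_seqs[k], 1, p$tts_position),
                           strrep("A", 20)),
                    description = "synthetic EST covering the intron to the TTS")

  truth <- list(seed = as.integer(seed),
                exon_lengths = exon_lengths,
                intron_lengths = unname(nchar(intron_seqs)),
                retained_intron = k,
                cds_start = p$cds_start,
                boundary_phase = p$boundary_phase,
                novel_length = p$novel_length,
                stop_triplet = if (is.null(ri$truth$stop_position)) NULL else p$stop_triplet,
                stop_intron_position = ri$truth$stop_position,
                polya_position = ri$truth$polya_position,
                tts_position = p$tts_position,
                insert = ri$truth$insert,
                primers = primers$truth,
                spliced_length = nchar(spliced$sequence),
                retained_length = nchar(retained$sequence))

  out <- list(genome = genome, gene = gene, primers = primers$primers,
              est = est, truth = truth)
  validate_locus(out, spliced, retained)
  out
}

# assemble the retained intron: novel codons, stop, filler, AATAAA, TTS,
# optional TSD/insert/tail
build_retained_intron_seq <- function(p, exonic_tail, phase) {
  protect <- integer(0)
  mark <- function(from, to) protect <<- c(protect, seq.int(from, to))
  pieces <- character(0); at <- 0L
  push <- function(s, protect_it = FALSE) {
    if (nchar(s) == 0) return(invisible(NULL))
    pieces[length(pieces) + 1L] <<- s
    if (protect_it) mark(at + 1L, at + nchar(s))
    at <<- at + nchar(s)
    invisible(NULL)
  }
  N <- p$novel_length
  stop_position <- NULL
  if (phase > 0) {
    ex <- substr(exonic_tail, nchar(exonic_tail) - phase + 1L, nchar(exonic_tail))
    if (N == 0) {
      # boundary codon itself must not be a stop; the stop is fully intronic
      compl_ <- completion_avoiding_stop(ex, phase)
      # N == 0 with phase > 0: the boundary codon contains intronic nt, so by
      # the operational definition it would encode a novel residue; plant the
      # stop as the boundary codon completion instead when possible
      stop_compl <- stop_completion(ex, phase, p$stop_triplet)
      if (!is.null(stop_compl)) {
        push(stop_compl, TRUE)
        stop_position <- 1L - phase + 0L # codon start is exonic
      } else {
        push(compl_, TRUE)
        push(p$stop_triplet, TRUE)
        stop_position <- (3L - phase) + 1L
      }
    } else {
      push(completion_avoiding_stop(ex, phase), TRUE)
      push(rand_sense_codons(N - 1L), TRUE)
      push(p$stop_triplet, TRUE)
      stop_position <- (3L - phase) + 3L * (N - 1L) + 1L
    }
  } else {
    push(rand_sense_codons(N), TRUE)
    push(p$stop_triplet, TRUE)
    stop_position <- 3L * N + 1L
  }
  # filler to the polyA signal
  gap1 <- p$polya_position - at - 1L
  if (gap1 < 0) stop("generation error: polyA signal overlaps the novel region")
  push(rand_dna(gap1))
  polya_position <- at + 1L
  push("AATAAA", TRUE)
  insert_truth <- NULL
  if (!is.null(p$insert)) {
    ins <- p$insert
    push(rand_dna(ins$signal_to_tsd))
    tsd <- rand_dna(ins$tsd_length)
    push(tsd, TRUE)
    ins_start <- at + 1L
    body <- mutate_consensus(ins)
    # two non-A bases between element body and tail keep the measured
    # oligo(dA) length exact even for A-rich consensus ends
    spacer <- if (ins$tail_length > 0) paste(sample(c("C", "G"), 2,
                                                    replace = TRUE),
                                             collapse = "") else ""
    push(paste0(body, spacer, strrep("A", ins$tail_length)), TRUE)
    ins_end <- at
    push(tsd, TRUE)
    push(rand_dna(20L))
    insert_truth <- list(interval = c(ins_start, ins_end),
                         tsd_length = ins$tsd_length, tsd_sequence = tsd,
                         tail_length = ins$tail_length,
                         transitions = ins$transitions,
                         transversions = ins$transversions,
                         gap_events = length(ins$gap_events),
                         gap_nt = sum(ins$gap_events),
                         signal_to_tsd = ins$signal_to_tsd)
  }
  tail_fill <- p$intron_lengths[p$retained_intron] - at
  if (tail_fill > 0) push(rand_dna(tail_fill))
  seqstr <- paste(pieces, collapse = "")
  # make the TTS boundary unambiguous for oligo(dA) trimming: an EST ending
  # at the TTS with a polyA tail must trim to exactly the planted position,
  # so the two intron bases at the boundary are forced non-A
  for (pos in c(p$tts_position - 1L, p$tts_position)) {
    if (pos >= 1 && pos <= nchar(seqstr) && !(pos %in% protect) &&
        substr(seqstr, pos, pos) == "A")
      substr(seqstr, pos, pos) <- sample(c("C", "G", "T"), 1)
  }
  list(sequence = seqstr,
       protect = protect,
       truth = list(stop_position = stop_position,
                    polya_position = polya_position,
                    insert = insert_truth))
}

completion_avoiding_stop <- function(exonic_part, phase) {
  need <- 3L - phase
  for (i in 1:50) {
    cand <- rand_dna(need)
    if (!(paste0(exonic_part, cand) %in% c("TAA", "TAG", "TGA"))) return(cand)
  }
  stop("generation error: could not complete boundary codon")
}

stop_completion <- function(exonic_part, phase, stop_triplet) {
  # completion turning the boundary codon into the requested stop, if the
  # exonic prefix is compatible
  if (substr(stop_triplet, 1, phase) == exonic_part)
    substr(stop_triplet, phase + 1L, 3L) else NULL
}

mutate_consensus <- function(ins) {
  cons <- if (inherits(ins$consensus, "seq_record")) ins$consensus$residues
          else toupper(ins$consensus)
  ch <- strsplit(cons, "", fixed = TRUE)[[1]]
  n <- length(ch)
  need <- ins$transitions + ins$transversions + length(ins$gap_events)
  if (n < 4 * need) stop("generation error: consensus too short for requested divergence")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  # keep mutated sites apart so the free-end-gaps alignment recovers them
  sites <- sort(sample(seq(3, n - 3), need, replace = FALSE))
  while (any(diff(sites) < 4) && need > 1) {
    sites <- sort(sample(seq(3, n - 3), need, replace = FALSE))
  }
  types <- sample(c(rep("ts", ins$transitions), rep("tv", ins$transversions),
                    rep("del", length(ins$gap_events))))
  dels <- ins$gap_events
  del_at <- integer(0); del_len <- integer(0)
  for (i in seq_along(sites)) {
    pos <- sites[i]
    if (types[i] == "ts") ch[pos] <- transition[[ch[pos]]]
    else if (types[i] == "tv") ch[pos] <- sample(transversion[[ch[pos]]], 1)
    else { del_at <- c(del_at, pos); del_len <- c(del_len, dels[1]); dels <- dels[-1] }
  }
  if (length(del_at)) {
    drop <- unlist(mapply(function(a, l) seq.int(a, a + l - 1), del_at, del_len,
                          SIMPLIFY = FALSE))
    ch <- ch[-drop]
  }
  paste(ch, collapse = "")
}

scrub_motif <- function(seq, positions, protect) {
  # break accidental motif occurrences at unprotected positions
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (pp in positions) {
    cols <- setdiff(seq.int(pp, pp + 5L), protect)
    if (length(cols) == 0) next
    tgt <- cols[[ceiling(length(cols) / 2)]]
    ch[tgt] <- sample(setdiff(c("A", "C", "G", "T"), ch[tgt]), 1)
  }
  paste(ch, collapse = "")
}

design_locus_primers <- function(p, spliced, retained, k) {
  pl <- p$primer_length
  # forward primer inside exon 1, after a margin
  f_start <- 11L
  fseq <- substr(spliced$sequence, f_start, f_start + pl - 1L)
  fwd <- primer("synthF", fseq, "forward")
  # exonic reverse primer in the post-intron exon (discriminates nothing;
  # amplifies both templates, mirroring a reference-transcript pair)
  exon_next <- spliced$segments[spliced$segments$label == paste0("exon_", k + 1L), ]
  r_ex_end <- exon_next$t_start + 10L + pl - 1L
  rex_seq <- revcomp(substr(spliced$sequence, exon_next$t_start + 10L, r_ex_end))
  rev_exon <- primer("synthR_exon", rex_seq, "reverse")
  # intronic reverse primer: binds only the retained template
  seg <- retained_segment(retained)
  ri_start <- seg$t_start + 149L
  rint_seq <- revcomp(substr(retained$sequence, ri_start, ri_start + pl - 1L))
  rev_intron <- primer("synthR_intron", rint_seq, "reverse")
  expected_spliced <- r_ex_end - f_start + 1L
  seg_len <- seg$t_end - seg$t_start + 1L
  expected_retained_exonpair <- expected_spliced + seg_len
  expected_retained_intron <- (ri_start + pl - 1L) - f_start + 1L
  list(primers = list(forward = fwd, reverse_exon = rev_exon,
                      reverse_intron = rev_intron),
       truth = list(
         forward = list(name = "synthF", sequence = fseq,
                        spliced_site = c(f_start, f_start + pl - 1L)),
         reverse_exon = list(name = "synthR_exon", sequence = rex_seq,
                             expected_product_spliced = expected_spliced,
                             expected_product_retained = expected_retained_exonpair),
         reverse_intron = list(name = "synthR_intron", sequence = rint_seq,
                               intron_site_start = 150L,
                               expected_product_spliced = NA,
                               expected_product_retained = expected_retained_intron)))
}

# generation-time self-validation: planted features must be re-detected
validate_locus <- function(out, spliced, retained) {
  tr <- out$truth
  rep_ <- predict_truncation(retained)
  if (rep_$novel_length != tr$novel_length)
    stop("generation error: novel length not recovered (",
         rep_$novel_length, " != ", tr$novel_length, ")")
  seg <- retained_segment(retained)
  intron_seq <- substr(retained$sequence, seg$t_start, seg$t_end)
  sig <- find_polya_signals(intron_seq)
  sig <- sig$position[sig$position <= tr$tts_position]
  if (!identical(sig, tr$polya_position))
    stop("generation error: polyA signal not uniquely recovered")
  if (!is.null(tr$insert)) {
    tsd <- detect_tsd(intron_seq, tr$insert$interval,
                      max_mismatch = 0L)
    if (!tsd$found || tsd$tsd_length != tr$insert$tsd_length)
      stop("generation error: TSD not recovered")
    tail <- measure_polya_tail(substr(intron_seq, tr$insert$interval[1],
                                      tr$insert$interval[2]))
    if (tail != tr$insert$tail_length && tr$insert$tail_length >= 8)
      stop("generation error: oligo(dA) tail not recovered")
  }
  amps <- insilico_pcr(retained, out$primers$forward, out$primers$reverse_intron)
  if (length(amps) != 1 ||
      amps[[1]]$product_length != tr$primers$reverse_intron$expected_product_retained)
    stop("generation error: intron-primer amplicon not recovered")
  amps0 <- insilico_pcr(spliced, out$primers$forward, out$primers$reverse_intron)
  if (length(amps0) != 0)
    stop("generation error: intron primer amplifies the spliced template")
  invisible(TRUE)
}

write_locus <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(out$genome, file.path(dir, "genome.fasta"))
  write_gene_models_gff3(out$gene, file.path(dir, "gene.gff3"))
  pr <- do.call(rbind, lapply(out$primers, function(x)
    data.frame(name = x$name, role = x$role, sequence = x$sequence)))
  write.table(pr, file.path(dir, "primers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(out$est, file.path(dir, "est.fasta"))
  jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' Generate a panel of diverged species loci
#'
#' Derives `n_species` loci from a base locus by seeded uniform (JC-style)
#' substitutions. Planted feature cores (the boundary region and novel
#' codons, the stop codon, the polyA signal, TSD copies and insert) are
#' protected from mutation unless a species is listed in `knockout_stop`,
#' in which case its stop codon is mutated to a sense codon. Short indels
#' can additionally be placed in the intron tail downstream of all planted
#' features (`indel_rate`), shifting downstream exon coordinates.
#'
#' @param base Output of [generate_locus()].
#' @param n_species Number of derived species.
#' @param divergence Substitution rate(s) in `[0, 0.5]` (recycled).
#' @param seed Integer seed.
#' @param knockout_stop Character vector of species ids (e.g. `"sp03"`)
#'   whose planted stop codon is destroyed.
#' @param indel_rate Per-base indel rate in the intron tail (default 0).
#' @return A list with `loci` (named list of `list(gene, genome,
#'   intron_index, frame_anchor)` ready for
#'   [cross_species_truncation_table()]) and `truth` (per-species
#'   divergence, substitution count, stop retention).
#' @export
generate_species_panel <- function(base, n_species, divergence, seed = 1L,
                                   knockout_stop = character(0),
                                   indel_rate = 0) {
  stopifnot(all(divergence >= 0), all(divergence <= 0.5))
  divergence <- rep_len(divergence, n_species)
  withr::with_seed(as.integer(seed), {
    tr <- base$truth
    k <- tr$retained_intron
    gseq <- base$genome$residues
    seg <- retained_segment(build_intron_retained(base$gene, base$genome, k))
    protect <- protected_genomic_positions(base, seg)
    loci <- list(); truth <- list()
    for (i in seq_len(n_species)) {
      sp <- sprintf("sp%02d", i)
      ch <- strsplit(gseq, "", fixed = TRUE)[[1]]
      mutable <- setdiff(seq_along(ch), protect)
      nmut <- rbinom(1, length(mutable), divergence[i])
      sites <- if (nmut > 0) sample(mutable, nmut) else integer(0)
      for (s in sites) ch[s] <- sample(setdiff(c("A", "C", "G", "T"), ch[s]), 1)
      stop_kept <- TRUE
      if (sp %in% knockout_stop && !is.null(tr$stop_intron_position)) {
        gpos <- seg$g_start + tr$stop_intron_position - 1L
        # turn the stop into a sense codon by mutating its middle base
        old <- paste0(ch[gpos], ch[gpos + 1L], ch[gpos + 2L])
        for (cand in c("C", "G", "T", "A")) {
          ch[gpos + 1L] <- cand
          if (!(paste0(ch[gpos], cand, ch[gpos + 2L]) %in% c("TAA", "TAG", "TGA")) &&
              cand != substr(old, 2, 2)) break
        }
        stop_kept <- FALSE
      }
      gene_i <- base$gene
      delta <- 0L
      if (indel_rate > 0) {
        tail_start <- seg$g_start + max(tr$tts_position,
          if (!is.null(tr$insert)) tr$insert$interval[2] + tr$insert$tsd_length
          else 0L) + 5L
        tail_end <- seg$g_end - 5L
        if (tail_end > tail_start) {
          nind <- rbinom(1, tail_end - tail_start, indel_rate)
          for (j in seq_len(nind)) {
            at <- sample(seq(tail_start, tail_end - 3L), 1)
            len <- sample(1:3, 1)
            if (runif(1) < 0.5) { # deletion
              ch <- ch[-seq.int(at, at + len - 1L)]
              delta <- delta - len
            } else {
              ch <- append(ch, sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           after = at)
              delta <- delta + len
            }
            tail_end <- min(tail_end, length(ch) - 5L)
          }
          if (delta != 0L) {
            ex <- gene_i$exons
            after <- ex$start > seg$g_end
            ex$start[after] <- ex$start[after] + delta
            ex$end[after] <- ex$end[after] + delta
            gene_i <- gene_model(gene_i$gene_id, gene_i$chrom, gene_i$strand,
                                 ex, gene_i$cds_start_in_transcript)
          }
        }
      }
      genome_i <- seq_record(base$genome$id, paste(ch, collapse = ""),
                             description = sp)
      loci[[sp]] <- list(gene = gene_i, genome = genome_i, intron_index = k,
                         frame_anchor = tr$cds_start)
      truth[[sp]] <- list(divergence = divergence[i], n_substitutions = nmut,
                          stop_retained = stop_kept, indel_delta = delta)
    }
    list(loci = loci, truth = truth)
  })
}

protected_genomic_positions <- function(base, seg) {
  tr <- base$truth
  prot <- integer(0)
  add <- function(from, to) prot <<- c(prot, seq.int(from, to))
  # exons (coding structure and primer sites stay fixed)
  for (i in seq_len(nrow(base$gene$exons)))
    add(base$gene$exons$start[i], base$gene$exons$end[i])
  g0 <- seg$g_start - 1L
  novel_nt <- novel_intron_nt(tr$boundary_phase, tr$novel_length)
  if (!is.null(tr$stop_intron_position))
    add(g0 + 1L, g0 + max(1L, tr$stop_intron_position + 2L))
  else if (novel_nt > 0) add(g0 + 1L, g0 + novel_nt)
  add(g0 + tr$polya_position, g0 + tr$polya_position + 5L)
  if (!is.null(tr$insert)) {
    iv <- tr$insert$interval
    add(g0 + iv[1] - tr$insert$tsd_length, g0 + iv[2] + tr$insert$tsd_length)
  }
  unique(prot)
}

#' Generate noisy reads from a template
#'
#' Stand-ins for Sanger consensus reads: full-length copies of the
#' template with seeded substitutions at `error_rate`, plus optional
#' deterministic planted indels. The truth lists every injected change.
#'
#' @param template A [seq_record] or DNA string.
#' @param error_rate Substitution rate in `[0, 0.2]`.
#' @param n Number of reads.
#' @param seed Integer seed.
#' @param planted_indels Optional list of `list(position, length,
#'   kind = "deletion"|"insertion")` applied to every read (positions on
#'   the template, applied high-to-low).
#' @return A list with `reads` (list of [seq_record]) and `truth`
#'   (per-read substitution positions and the planted indels).
#' @export
generate_noisy_reads <- function(template, error_rate, n, seed = 1L,
                                 planted_indels = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.2, n >= 1)
  tmpl <- if (inherits(template, "seq_record")) template$residues else
    toupper(template)
  withr::with_seed(as.integer(seed), {
    reads <- list(); truth <- list()
    for (i in seq_len(n)) {
      ch <- strsplit(tmpl, "", fixed = TRUE)[[1]]
      nmut <- rbinom(1, length(ch), error_rate)
      sites <- if (nmut > 0) sort(sample(seq_along(ch), nmut)) else integer(0)
      for (s in sites) ch[s] <- sample(setdiff(c("A", "C", "G", "T"), ch[s]), 1)
      s2 <- paste(ch, collapse = "")
      if (!is.null(planted_indels)) {
        ord <- order(-vapply(planted_indels, function(x) x$position, numeric(1)))
        for (pi_ in planted_indels[ord]) {
          if (pi_$kind == "deletion") {
            s2 <- paste0(substr(s2, 1, pi_$position - 1),
                         substr(s2, pi_$position + pi_$length, nchar(s2)))
          } else {
            ins <- paste(sample(c("A", "C", "G", "T"), pi_$length,
                                replace = TRUE), collapse = "")
            s2 <- paste0(substr(s2, 1, pi_$position), ins,
                         substr(s2, pi_$position + 1, nchar(s2)))
          }
        }
      }
      reads[[i]] <- seq_record(sprintf("read%02d", i), s2)
      truth[[i]] <- list(substitution_positions = sites,
                         planted_indels = planted_indels)
    }
    list(reads = reads, truth = truth)
  })
}
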