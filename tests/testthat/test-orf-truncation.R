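test_that("translation follows the standard code with N -> X", {
  expect_equal(translate_dna("ATGTAA"), "M*")
  expect_equal(translate_dna(""), "")
  expect_equal(translate_dna("ATNTAA"), "X*")
  expect_equal(translate_dna("TANAAA"), "XK") # ambiguous codon is never a stop
  expect_equal(translate_dna("AATGTA", frame_offset = 1), "M")
})

test_that("translation matches the Biostrings oracle on random sequences", {
  withr::local_seed(21)
  for (i in 1:10) {
    s <- rand_seq(300)
    expect_equal(translate_dna(s),
                 as.character(Biostrings::translate(Biostrings::DNAString(s))))
  }
})

test_that("in-frame stop scanning matches hand enumeration", {
  expect_equal(scan_inframe_stops("TAA"), 1L)
  expect_equal(scan_inframe_stops("ATGTGATAA"), c(4L, 7L))
  expect_equal(scan_inframe_stops("TAA", frame_offset = 1), integer(0))
  # property: positions agree with codon-by-codon translation
  withr::local_seed(22)
  for (i in 1:5) {
    s <- rand_seq(90)
    off <- sample(0:2, 1)
    aa <- strsplit(translate_dna(s, off), "")[[1]]
    expect_equal(scan_inframe_stops(s, off),
                 as.integer(off + 3 * (which(aa == "*") - 1) + 1))
  }
})

test_that("planted novel lengths are recovered across phases", {
  for (ph in 0:2) for (nv in c(0L, 5L)) {
    loc <- generate_locus(params = list(boundary_phase = ph,
                                        novel_length = nv), seed = 31 + ph)
    b <- build_intron_retained(loc$gene, loc$genome, loc$truth$retained_intron)
    r <- predict_truncation(b)
    expect_equal(r$novel_length, nv)
    if (ph == 0) expect_null(r$boundary_codon)
    else expect_equal(unname(r$boundary_codon["n_exonic_nt"]), ph)
  }
})

test_that("an intron beginning with a stop yields novel length 0 at position 1", {
  # exon ends on a codon boundary; intron starts TAA
  g <- paste0(strrep("ATG", 10), "TAA", rand_seq(30), strrep("GGC", 5))
  genome <- toy_genome(g)
  gene <- gene_model("imm", "chrT", "+",
                     data.frame(start = c(1, 64), end = c(30, 78)),
                     cds_start_in_transcript = 1)
  r <- predict_truncation(build_intron_retained(gene, genome, 1))
  expect_equal(r$novel_length, 0)
  expect_equal(r$stop_codon$triplet, "TAA")
  expect_equal(r$stop_codon$intron_relative_position, 1)
  expect_null(r$boundary_codon)
  expect_equal(r$shared_prefix_length, 10)
})

test_that("truncation is consistent with the stop scan and flags no-stop", {
  loc <- generate_locus(seed = 41)
  b <- build_intron_retained(loc$gene, loc$genome, loc$truth$retained_intron)
  r <- predict_truncation(b)
  seg <- b$segments[grepl("^intron_", b$segments$label), ]
  intron <- substr(b$sequence, seg$t_start, seg$t_end)
  off <- (r$stop_codon$intron_relative_position - 1) %% 3
  expect_true(r$stop_codon$intron_relative_position %in%
                scan_inframe_stops(intron, off))

  # no-stop path: a retained intron of sense codons only
  g <- paste0(strrep("ATG", 10), strrep("GGC", 10), strrep("TTC", 5))
  genome <- toy_genome(g)
  gene <- gene_model("ns", "chrT", "+",
                     data.frame(start = c(1, 61), end = c(30, 75)),
                     cds_start_in_transcript = 1)
  rn <- predict_truncation(build_intron_retained(gene, genome, 1))
  expect_true(rn$no_stop)
  expect_null(rn$stop_codon)
  expect_gt(rn$novel_length, 0)
})

test_that("frame anchors inside the retained segment are rejected", {
  loc <- generate_locus(seed = 43)
  b <- build_intron_retained(loc$gene, loc$genome, loc$truth$retained_intron)
  seg <- b$segments[grepl("^intron_", b$segments$label), ]
  expect_error(predict_truncation(b, seg$t_start + 3), "upstream")
})

test_that("spliced translation has no premature stop on generated loci", {
  for (sd in 1:3) {
    loc <- generate_locus(seed = 50 + sd)
    sp <- build_spliced(loc$gene, loc$genome)
    aa <- translate_dna(substr(sp$sequence, loc$truth$cds_start,
                               nchar(sp$sequence)))
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("C-terminal motif comparison recovers planted motifs", {
  motif <- "FDAFVVYSRQ" # a Box-1-like segment
  self <- compare_cterminal(motif, motif)
  expect_equal(self$stats$identities$pct, 100)
  expect_equal(nchar(self$aligned_a), nchar(motif))

  none <- compare_cterminal(strrep("G", 30), motif)
  expect_lt(none$stats$identities$n, 4) # no meaningful hit on poly-G

  withr::local_seed(61)
  tail <- paste0(paste(sample(c("L", "K", "E", "P", "W"), 25, replace = TRUE),
                       collapse = ""), motif,
                 paste(sample(c("L", "K", "E", "P", "W"), 15, replace = TRUE),
                       collapse = ""))
  hit <- compare_cterminal(tail, motif)
  expect_equal(hit$b_range, c(1, nchar(motif)))
  expect_equal(hit$a_range, c(26, 25 + nchar(motif)))
  expect_equal(gsub("-", "", hit$aligned_a), motif)

  empty <- compare_cterminal("", motif)
  expect_equal(empty$score, 0)
})
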