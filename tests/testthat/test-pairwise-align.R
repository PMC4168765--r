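test_that("identical sequences align gaplessly at full identity", {
  s <- rand_seq(20)
  a <- align(s, s)
  expect_equal(a$stats$identities$n, 20)
  expect_equal(a$stats$identities$pct, 100)
  expect_equal(a$stats$gaps$n, 0)
  expect_equal(a$score, 20 * 5) # length x match for self-alignment
})

test_that("alignment statistics count identities, IUPAC positives and gaps", {
  mk <- function(a, b) {
    structure(list(aligned_a = a, aligned_b = b, id_a = "a", id_b = "b",
                   score = 0, mode = "global", a_range = c(1, 4),
                   b_range = c(1, 4), params = align_params()),
              class = "pairwise_alignment")
  }
  st <- alignment_stats(mk("ACGT", "ACGA"))
  expect_equal(st$identities$n, 3)
  expect_equal(st$identities$pct, 75)
  st2 <- alignment_stats(mk("ACGT", "RCGT"))
  expect_equal(st2$identities$n, 3)
  expect_equal(st2$positives$n, 4) # R is compatible with A
  st3 <- alignment_stats(mk("AC-T", "ACGT"))
  expect_equal(st3$gaps$n, 1)
})

test_that("substitution spectra classify transitions, transversions and gap runs", {
  mk <- function(a, b) {
    structure(list(aligned_a = a, aligned_b = b, id_a = "a", id_b = "b",
                   score = 0, mode = "global", params = align_params()),
              class = "pairwise_alignment")
  }
  sp0 <- substitution_spectrum(mk("ACGT", "ACGT"))
  expect_equal(unlist(sp0), c(transitions = 0, transversions = 0,
                              gap_events = 0, gap_nt = 0))
  sp1 <- substitution_spectrum(mk("ACGT", "GCGT"))
  expect_equal(sp1$transitions, 1)
  expect_equal(sp1$transversions, 0)
  sp2 <- substitution_spectrum(mk("ACGT", "TCGA")) # A<->T twice
  expect_equal(sp2$transversions, 2)
  sp3 <- substitution_spectrum(mk("AAAAAA", "AA--AA"))
  expect_equal(sp3$gap_events, 1)
  expect_equal(sp3$gap_nt, 2)
  sp4 <- substitution_spectrum(mk("AA--AATT--", "AACCAA--CC"))
  expect_equal(sp4$gap_events, 3)
  expect_equal(sp4$gap_nt, 6)
})

test_that("free-end-gaps scores match the exhaustive enumeration oracle", {
  withr::local_seed(71)
  for (i in 1:40) {
    a <- rand_seq(sample(1:4, 1)); b <- rand_seq(sample(1:4, 1))
    expect_equal(align(a, b)$score, oracle_score_enum(a, b),
                 info = paste(a, b))
    # the cubic direct-definition oracle agrees with the enumeration
    expect_equal(oracle_score_cubic(a, b, mode = "global"),
                 oracle_score_enum(a, b), info = paste(a, b))
  }
})

test_that("both modes match the direct-definition oracle on short pairs", {
  withr::local_seed(72)
  for (i in 1:300) {
    a <- rand_seq(sample(1:8, 1)); b <- rand_seq(sample(1:8, 1))
    expect_equal(align(a, b)$score,
                 oracle_score_cubic(a, b, mode = "global"),
                 info = paste("global", a, b))
    expect_equal(align(a, b, align_params(gap_open = 10, gap_extend = 0.5,
                                          mode = "local"))$score,
                 oracle_score_cubic(a, b, open = 10, extend = 0.5,
                                    mode = "local"),
                 info = paste("local", a, b))
  }
})

test_that("scores agree with the reference overlap/local aligner", {
  withr::local_seed(73)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    a <- rand_seq(sample(30:80, 1)); b <- rand_seq(sample(30:80, 1))
    # gap cost open+(k-1)*extend maps to Biostrings gapOpening = open - extend
    ref <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                         substitutionMatrix = mat,
                                         gapOpening = 9, gapExtension = 3,
                                         scoreOnly = TRUE)
    expect_equal(align(a, b)$score, ref)
    ref_l <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 9, gapExtension = 3,
                                           scoreOnly = TRUE)
    expect_equal(align(a, b, align_params(gap_open = 12, gap_extend = 3,
                                          mode = "local"))$score, ref_l)
  }
})

test_that("alignment score properties hold", {
  withr::local_seed(74)
  for (i in 1:20) {
    a <- rand_seq(sample(10:40, 1)); b <- rand_seq(sample(10:40, 1))
    expect_equal(align(a, b)$score, align(b, a)$score) # symmetry
    loc <- align(a, b, align_params(mode = "local"))
    expect_gte(loc$score, 0)
    # mismatches relative to an identical copy never increase the score
    s0 <- align(a, a)$score
    expect_equal(s0, 5 * nchar(a))
    b2 <- a
    for (pos in sample(nchar(a), 3)) {
      substr(b2, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(b2, pos, pos))[1]
      expect_lt(align(a, b2)$score, s0)
    }
  }
})

test_that("degapping aligned strings recovers the inputs", {
  withr::local_seed(75)
  for (i in 1:20) {
    a <- rand_seq(sample(5:60, 1)); b <- rand_seq(sample(5:60, 1))
    al <- align(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("alphabet mismatches and batch alignment are handled", {
  dna <- seq_record("d", "ACGTACGT", type = "dna")
  prot <- seq_record("p", "MKVLF", type = "protein")
  expect_error(align(dna, prot), "alphabet mismatch")

  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(seq_record("r1", "ACGTACGTGG")), fa)
  write_fasta(list(seq_record("t1", "ACGTACGTGGTT")), fb)
  res <- align_fasta(fa, fb)
  expect_equal(nrow(res$stats), 1)
  expect_equal(res$stats$identities_n, 10)
})
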