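test_that("identical sequences align without gaps at 100% identity", {
  withr::local_seed(181)
  s <- rand_seq(80)
  msa <- progressive_msa(setNames(rep(s, 5), paste0("s", 1:5)),
                         reference_id = "s1")
  expect_true(all(nchar(msa$rows) == 80))
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  expect_equal(unname(msa$identity_to_reference), rep(100, 5))
})

test_that("a planted 3-nt insertion produces one 3-column gap block", {
  withr::local_seed(182)
  base <- rand_seq(60)
  with_ins <- paste0(substr(base, 1, 30), "GGG", substr(base, 31, 60))
  msa <- progressive_msa(c(a = base, b = with_ins, c = base))
  expect_equal(unique(nchar(msa$rows)), 63)
  runs <- gregexpr("-+", msa$rows[["a"]])[[1]]
  expect_length(runs, 1) # exactly one gap block
  expect_equal(attr(runs, "match.length"), 3)
  expect_false(grepl("-", msa$rows[["b"]], fixed = TRUE))
  # degapped rows reconstruct the inputs
  expect_equal(gsub("-", "", msa$rows[["a"]]), base)
  expect_equal(gsub("-", "", msa$rows[["b"]]), with_ins)
})

test_that("percent identity counts reference non-gap columns", {
  s <- strrep("ACGTT", 4) # 20 nt
  s2 <- paste0("GG", substr(s, 3, 20)) # 2 of 20 substituted
  msa <- progressive_msa(c(ref = s, other = s2), reference_id = "ref")
  expect_equal(unname(msa$identity_to_reference["ref"]), 100)
  expect_equal(unname(msa$identity_to_reference["other"]), 90)

  two <- progressive_msa(c(ref = "ACGTACGTAC", other = "ACGTACGTAT"),
                         reference_id = "ref")
  expect_equal(unname(two$identity_to_reference["other"]), 90)

  # an all-gap row scores 0 (constructed alignment)
  fake <- structure(list(rows = c(ref = "ACGT", gappy = "----")),
                    class = "msa_result")
  expect_equal(unname(percent_identity_to_reference(fake, "ref")["gappy"]), 0)
})

test_that("identity to reference is unchanged by appending an unrelated row", {
  withr::local_seed(183)
  base <- rand_seq(50)
  near <- paste0("T", substr(base, 2, 50))
  msa1 <- progressive_msa(c(ref = base, near = near), reference_id = "ref")
  msa2 <- progressive_msa(c(ref = base, near = near, junk = rand_seq(55)),
                          reference_id = "ref")
  expect_equal(msa2$identity_to_reference[["near"]],
               msa1$identity_to_reference[["near"]])
})

test_that("MSA degapping reconstructs every input sequence", {
  withr::local_seed(184)
  seqs <- setNames(vapply(1:6, function(i) rand_seq(sample(40:70, 1)),
                          character(1)), paste0("sp", 1:6))
  msa <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(msa$rows))), 1)
  for (nm in names(seqs)) expect_equal(gsub("-", "", msa$rows[[nm]]),
                                       unname(seqs[nm]))
})

test_that("conserved stop and polyA columns honour support thresholds", {
  # constructed alignment: all rows share TAA at columns 4-6, in frame 0
  rows <- setNames(rep(paste0("ATG", "TAA", "GGC"), 10), paste0("r", 1:10))
  msa <- structure(list(rows = rows), class = "msa_result")
  offs <- setNames(rep(0L, 10), names(rows))
  st <- find_conserved_columns(msa, "stop", min_support = 0.9,
                               frame_offsets = offs)
  expect_equal(st$column, 4L)
  expect_equal(st$support, 1)

  # 7 of 10 rows carry AATAAA at the same columns
  with_sig <- paste0("GGGG", "AATAAA", "CC")
  without <- paste0("GGGG", "AATCCA", "CC")
  rows2 <- setNames(c(rep(with_sig, 7), rep(without, 3)), paste0("r", 1:10))
  msa2 <- structure(list(rows = rows2), class = "msa_result")
  pa <- find_conserved_columns(msa2, "polyA", min_support = 0.6)
  expect_equal(pa$column, 5L)
  expect_equal(pa$support, 0.7)
  expect_equal(nrow(find_conserved_columns(msa2, "polyA", min_support = 0.8)), 0)

  # support equals brute-force per-column counts even with gapped rows
  rows3 <- setNames(c("AATAAAGG", "--AATAAA", "AATAAA--"), paste0("g", 1:3))
  msa3 <- structure(list(rows = rows3), class = "msa_result")
  pa3 <- find_conserved_columns(msa3, "polyA", min_support = 0)
  counts <- setNames(pa3$n_rows, pa3$column)
  expect_equal(counts[["1"]], 2L) # rows g1 and g3 start at column 1
  expect_equal(counts[["3"]], 1L) # row g2's motif maps to column 3
})

test_that("cross-species tables recover planted novel lengths and order rows", {
  specs <- list(human1 = 22L, human2 = 22L, human3 = 22L,
                rodent1 = 5L, rodent2 = 5L)
  loci <- list()
  for (i in seq_along(specs)) {
    loc <- generate_locus(params = list(novel_length = specs[[i]]),
                          seed = 200 + i)
    loci[[names(specs)[i]]] <- list(gene = loc$gene, genome = loc$genome,
                                    intron_index = loc$truth$retained_intron,
                                    frame_anchor = loc$truth$cds_start)
  }
  tab <- cross_species_truncation_table(loci, reference = "human1")
  expect_equal(setNames(tab$novel_length, tab$species)[names(specs)],
               unlist(specs), ignore_attr = TRUE)
  expect_equal(tab$species[1], "human1") # reference sorts first
  expect_true(all(tab$stop_present))
  expect_true(all(tab$frame_conserved)) # same boundary phase everywhere
  ids <- tab$identity_to_reference[-1]
  expect_true(all(diff(ids[!is.na(ids)]) <= 1e-9))
})

test_that("species without an in-frame intron stop are flagged truncated-at-end", {
  # a retained intron of pure sense codons
  g <- paste0(strrep("ATG", 12), strrep("GGC", 12), strrep("TTC", 6))
  genome <- toy_genome(g)
  gene <- gene_model("nostop", "chrT", "+",
                     data.frame(start = c(1, 73), end = c(36, 90)),
                     cds_start_in_transcript = 1)
  tab <- cross_species_truncation_table(
    list(sp = list(gene = gene, genome = genome, intron_index = 1L)))
  expect_false(tab$stop_present[1])
  expect_true(tab$truncated_at_end[1])
})
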