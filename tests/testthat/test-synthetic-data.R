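test_that("generation is deterministic for fixed params and seed", {
  a <- generate_locus(seed = 301)
  b <- generate_locus(seed = 301)
  expect_identical(a$genome$residues, b$genome$residues)
  expect_identical(a$truth, b$truth)
  c_ <- generate_locus(seed = 302)
  expect_false(identical(a$genome$residues, c_$genome$residues))
})

test_that("generation does not disturb the global RNG state", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_locus(seed = 303)); after <- runif(1)
  expect_identical(before, after)
})

test_that("human-like and rodent-like parameterizations are recovered", {
  human <- generate_locus(params = list(boundary_phase = 1L,
                                        novel_length = 22L), seed = 304)
  b <- build_intron_retained(human$gene, human$genome,
                             human$truth$retained_intron)
  expect_equal(predict_truncation(b)$novel_length, 22)

  rodent <- generate_locus(params = list(boundary_phase = 1L,
                                         novel_length = 5L), seed = 305)
  b2 <- build_intron_retained(rodent$gene, rodent$genome,
                              rodent$truth$retained_intron)
  expect_equal(predict_truncation(b2)$novel_length, 5)
})

test_that("infeasible parameters raise generation errors", {
  expect_error(generate_locus(params = list(intron_lengths = c(120L, 100L)),
                              seed = 306), "too short")
  expect_error(generate_locus(params = list(polya_position = 10L), seed = 307),
               "downstream of the planted stop")
})

test_that("locus files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  loc <- generate_locus(seed = 308, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fasta", "gene.gff3",
                                               "primers.tsv", "est.fasta",
                                               "truth.json")))))
  genome <- read_fasta(file.path(dir, "genome.fasta"))[[1]]
  gene <- read_gene_models_gff3(file.path(dir, "gene.gff3"),
                                cds_start_in_transcript = loc$truth$cds_start)[[1]]
  primers <- read_primer_tsv(file.path(dir, "primers.tsv"))
  expect_equal(genome$residues, loc$genome$residues)
  expect_equal(gene$exons, loc$gene$exons)
  b <- build_intron_retained(gene, genome, loc$truth$retained_intron)
  expect_equal(predict_truncation(b, loc$truth$cds_start)$novel_length,
               loc$truth$novel_length)
  amp <- insilico_pcr(b, primers$synthF, primers$synthR_intron)
  expect_equal(amp[[1]]$product_length,
               loc$truth$primers$reverse_intron$expected_product_retained)
})

test_that("species panels at zero divergence are identical to the base", {
  base <- generate_locus(seed = 309)
  pan <- generate_species_panel(base, 3, divergence = 0, seed = 310)
  for (sp in names(pan$loci))
    expect_identical(pan$loci[[sp]]$genome$residues, base$genome$residues)
  tab <- cross_species_truncation_table(pan$loci)
  expect_true(all(tab$novel_length == base$truth$novel_length))
})

test_that("stop knockouts reduce conserved-stop support by 1/n", {
  base <- generate_locus(seed = 311)
  pan <- generate_species_panel(base, 5, divergence = 0.02, seed = 312,
                                knockout_stop = "sp02")
  expect_false(pan$truth$sp02$stop_retained)
  # conserved-stop support at the planted column across the panel introns
  k <- base$truth$retained_intron
  introns <- lapply(pan$loci, function(l) {
    b <- build_intron_retained(l$gene, l$genome, l$intron_index)
    seg <- b$segments[grepl("^intron_", b$segments$label), ]
    substr(b$sequence, seg$t_start, seg$t_end)
  })
  phase_off <- (base$truth$stop_intron_position - 1) %% 3
  msa <- structure(list(rows = setNames(unlist(introns), names(introns))),
                   class = "msa_result") # equal lengths: substitutions only
  offs <- setNames(rep(as.integer(phase_off), length(introns)), names(introns))
  cc <- find_conserved_columns(msa, "stop", min_support = 0.7,
                               frame_offsets = offs)
  hit <- cc[cc$column == base$truth$stop_intron_position, ]
  expect_equal(hit$n_rows, 4L) # (n - 1) of n retain the stop
  expect_equal(hit$support, 4 / 5)
})

test_that("divergence produces the expected identity band", {
  base <- generate_locus(seed = 313)
  pan <- generate_species_panel(base, 10, divergence = 0.05, seed = 314)
  sp <- build_spliced(base$gene, base$genome)
  ids <- vapply(pan$loci, function(l) {
    s2 <- build_spliced(l$gene, l$genome)
    ch1 <- strsplit(sp$sequence, "")[[1]]; ch2 <- strsplit(s2$sequence, "")[[1]]
    100 * mean(ch1 == ch2)
  }, numeric(1))
  # exons are protected feature cores here, so spliced identity stays high;
  # intron divergence is checked instead
  ri <- function(gene, genome) {
    b <- build_intron_retained(gene, genome, base$truth$retained_intron)
    seg <- b$segments[grepl("^intron_", b$segments$label), ]
    substr(b$sequence, seg$t_start, seg$t_end)
  }
  i0 <- strsplit(ri(base$gene, base$genome), "")[[1]]
  div <- vapply(pan$loci, function(l) {
    mean(strsplit(ri(l$gene, l$genome), "")[[1]] != i0)
  }, numeric(1))
  expect_true(all(ids == 100))
  expect_gt(mean(div), 0.02) # around 5% minus protected cores
  expect_lt(mean(div), 0.08)
})

test_that("noisy reads reproduce planted error structure", {
  tmpl <- seq_record("t", rand_seq(875))
  clean <- generate_noisy_reads(tmpl, 0, 1, seed = 315)
  expect_identical(clean$reads[[1]]$residues, tmpl$residues)
  al0 <- align(clean$reads[[1]], tmpl)
  expect_equal(al0$stats$identities$pct, 100)

  noisy <- generate_noisy_reads(tmpl, 0.03, 3, seed = 316)
  for (i in 1:3) {
    al <- align(noisy$reads[[i]], tmpl)
    expect_gt(al$stats$identities$pct, 93) # binomial band around 97%
    expect_lt(al$stats$identities$pct, 99.9)
  }

  deleted <- generate_noisy_reads(tmpl, 0, 1, seed = 317,
    planted_indels = list(list(position = 400, length = 3, kind = "deletion")))
  al3 <- align(deleted$reads[[1]], tmpl)
  sp <- substitution_spectrum(al3)
  expect_equal(sp$gap_events, 1)
  expect_equal(sp$gap_nt, 3)
})
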