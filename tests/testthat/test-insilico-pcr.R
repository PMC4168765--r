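test_that("binding sites respect orientation, mismatch and 3' rules", {
  withr::local_seed(121)
  tmpl <- seq_record("t", rand_seq(120))
  fwd <- primer("F", substr(tmpl$residues, 1, 20), "forward")
  sites <- find_binding_sites(tmpl, fwd)
  expect_equal(sites$start, 1)
  expect_equal(sites$end, 20)
  expect_equal(sites$orientation, "forward")

  rev <- primer("R", revcomp(substr(tmpl$residues, 10, 30)), "reverse")
  rsites <- find_binding_sites(tmpl, rev)
  expect_equal(rsites$start, 10)
  expect_equal(rsites$end, 30)

  # internal mismatch tolerated with max_mismatch 1, not 0
  s <- substr(tmpl$residues, 1, 20)
  mid <- substr(s, 10, 10)
  s1 <- paste0(substr(s, 1, 9), setdiff(c("A", "C", "G", "T"), mid)[1],
               substr(s, 11, 20))
  expect_equal(nrow(find_binding_sites(tmpl, primer("F1", s1, "forward"))), 0)
  expect_equal(nrow(find_binding_sites(tmpl, primer("F1", s1, "forward"),
                                       max_mismatch = 1)), 1)
  # a 3'-terminal mismatch is excluded even when mismatches are allowed
  last <- substr(s, 20, 20)
  s2 <- paste0(substr(s, 1, 19), setdiff(c("A", "C", "G", "T"), last)[1])
  expect_equal(nrow(find_binding_sites(tmpl, primer("F2", s2, "forward"),
                                       max_mismatch = 1)), 0)
  expect_equal(nrow(find_binding_sites(tmpl, primer("F2", s2, "forward"),
                                       max_mismatch = 1,
                                       require_3prime_match = FALSE)), 1)
})

test_that("amplicon arithmetic and geometry checks follow the definition", {
  a <- predict_amplicon("t", c(545, 568), c(1209, 1231))
  expect_equal(a$product_length, 687)
  full <- predict_amplicon("t", c(1, 20), c(81, 100))
  expect_equal(full$product_length, 100)
  expect_error(predict_amplicon("t", c(50, 70), c(60, 80)), "forward site")
  segs <- data.frame(t_start = c(1, 101, 121), t_end = c(100, 120, 170),
                     chrom = "c", g_start = 0, g_end = 0,
                     label = c("exon_1", "intron_1", "exon_2"))
  expect_true(predict_amplicon("t", c(1, 20), c(130, 150), segs)$spans_retained_intron)
  expect_false(predict_amplicon("t", c(1, 20), c(60, 80), segs)$spans_retained_intron)
})

test_that("intron-placed reverse primers discriminate retained templates", {
  for (sd in 1:5) {
    loc <- generate_locus(seed = 130 + sd)
    sp <- build_spliced(loc$gene, loc$genome)
    rt <- build_intron_retained(loc$gene, loc$genome, loc$truth$retained_intron)
    on_rt <- insilico_pcr(rt, loc$primers$forward, loc$primers$reverse_intron)
    on_sp <- insilico_pcr(sp, loc$primers$forward, loc$primers$reverse_intron)
    expect_length(on_rt, 1)
    expect_length(on_sp, 0) # genomic-amplification exclusion logic
    expect_true(on_rt[[1]]$spans_retained_intron)
    expect_equal(on_rt[[1]]$product_length,
                 loc$truth$primers$reverse_intron$expected_product_retained)
    # exon-placed pair amplifies both, lengths differing by the intron
    both_sp <- insilico_pcr(sp, loc$primers$forward, loc$primers$reverse_exon)
    both_rt <- insilico_pcr(rt, loc$primers$forward, loc$primers$reverse_exon)
    k <- loc$truth$retained_intron
    expect_equal(both_rt[[1]]$product_length - both_sp[[1]]$product_length,
                 loc$truth$intron_lengths[k])
  }
})

test_that("amplicon prediction is invariant under template reverse-complement", {
  withr::local_seed(141)
  for (i in 1:5) {
    tmpl <- seq_record("t", rand_seq(200))
    f <- primer("F", substr(tmpl$residues, 21, 42), "forward")
    r <- primer("R", revcomp(substr(tmpl$residues, 150, 171)), "reverse")
    amp <- insilico_pcr(tmpl, f, r)
    # swap roles on the reverse-complemented template
    rc <- seq_record("rc", revcomp(tmpl$residues))
    f2 <- primer("F2", r$sequence, "forward")
    r2 <- primer("R2", f$sequence, "reverse")
    amp2 <- insilico_pcr(rc, f2, r2)
    expect_length(amp, 1)
    expect_length(amp2, 1)
    expect_equal(amp2[[1]]$product_length, amp[[1]]$product_length)
  }
})

test_that("segment-map product lengths equal direct string arithmetic", {
  loc <- generate_locus(seed = 151)
  rt <- build_intron_retained(loc$gene, loc$genome, loc$truth$retained_intron)
  amp <- insilico_pcr(rt, loc$primers$forward, loc$primers$reverse_intron)[[1]]
  # direct string positions of the primer and the reverse site
  fpos <- regexpr(loc$primers$forward$sequence, rt$sequence, fixed = TRUE)
  rpos <- regexpr(revcomp(loc$primers$reverse_intron$sequence), rt$sequence,
                  fixed = TRUE)
  expect_equal(amp$product_length,
               as.integer(rpos) + nchar(loc$primers$reverse_intron$sequence) -
                 as.integer(fpos))
})

test_that("primer adaptation projects footprints through context alignment", {
  withr::local_seed(161)
  src <- rand_seq(120)
  prm <- primer("P", substr(src, 41, 62), "forward")
  same <- adapt_primer(prm, src, src)
  expect_equal(same$n_substitutions, 0)
  expect_equal(same$primer$sequence, prm$sequence)

  # three substitutions inside the footprint (mirroring a rodent adaptation)
  tgt <- src
  for (pos in c(45, 52, 59)) {
    ch <- substr(tgt, pos, pos)
    substr(tgt, pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  three <- adapt_primer(prm, src, tgt)
  expect_equal(three$n_substitutions, 3)
  expect_false(three$failed)
  expect_equal(three$primer$sequence, substr(tgt, 41, 62))

  # a substitution outside the footprint leaves the primer unchanged
  tgt2 <- src
  substr(tgt2, 80, 80) <- setdiff(c("A", "C", "G", "T"),
                                  substr(src, 80, 80))[1]
  outside <- adapt_primer(prm, src, tgt2)
  expect_equal(outside$n_substitutions, 0)

  expect_error(adapt_primer(prm, rand_seq(50), src), "not found")
})

test_that("primer TSV round trip and validation work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trole\tsequence", "F1\tforward\tACGTACGTACGT",
               "R1\treverse\tTTGGCCAATTGG"), f)
  ps <- read_primer_tsv(f)
  expect_length(ps, 2)
  expect_equal(ps$F1$role, "forward")
  expect_error(primer("short", "ACGTACG", "forward"), "shorter")
  expect_error(primer("amb", "ACGTACGTNN", "forward"), "disallowed")
})
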