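# deterministic toy loci used across test files

toy_genome <- function(seq, chrom = "chrT", offset = 0) {
  seq_record(chrom, seq, type = "dna", offset = offset)
}

# a 2-exon plus-strand gene: exon1 100 nt, intron 20 nt, exon2 50 nt
toy_two_exon <- function(seed = 1) {
  withr::with_seed(seed, {
    g <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    genome <- toy_genome(g)
    gene <- gene_model("toy", "chrT", "+",
                       data.frame(start = c(11, 131), end = c(110, 180)),
                       cds_start_in_transcript = 1)
    list(genome = genome, gene = gene)
  })
}

# mirror a plus-strand gene onto the minus strand of the reverse-complemented
# genome; transcripts must be identical (strand-symmetry oracle)
mirror_gene_minus <- function(gene, genome) {
  L <- nchar(genome$residues)
  flip <- function(s, e) c(L - e + 1, L - s + 1)
  ex <- t(mapply(flip, gene$exons$start, gene$exons$end))
  genome2 <- seq_record(gene$chrom, revcomp(genome$residues), type = "dna")
  gene2 <- gene_model(gene$gene_id, gene$chrom, "-",
                      data.frame(start = ex[, 1], end = ex[, 2]),
                      gene$cds_start_in_transcript)
  list(genome = genome2, gene = gene2)
}
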