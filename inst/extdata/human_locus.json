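{
  "description": "Published coordinates of the human IL18R1 type II locus (hg19) used to assemble the surrogate locus and to reproduce amplicon arithmetic.",
  "reference_transcript": "ENST00000233957/NM_003855.2",
  "exon8_end_transcript": 1135,
  "frame_anchor_transcript": 1132,
  "frame_anchor_residue": 370,
  "intron89_genomic_start": 103006678,
  "intron89_genomic_end": 103010928,
  "typeII_reverse_genomic_start": 103006939,
  "typeII_reverse_genomic_end": 103006960,
  "forward_transcript_start": 545,
  "forward_transcript_end": 568,
  "reference_reverse_transcript_start": 1209,
  "reference_reverse_transcript_end": 1231,
  "expected_product_reference_bp": 687,
  "expected_product_typeII_bp": 874,
  "reported_novel_peptide_length": 22,
  "reported_tts_intron_position": 357,
  "query_exonic_nt": 302,
  "query_intron_nt": 60
}
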