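# Shared in-code fixtures for the test suite.

tiny_genome <- function(seqs = c(chr1 = "ACGTACGTAC")) {
  structure(toupper(seqs), class = "reference_genome")
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_vcf <- function(body, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  lines <- if (header) c("##fileformat=VCFv4.2",
                         "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  else character(0)
  writeLines(c(lines, body), path)
  path
}

# single-exon plus-strand transcript whose mRNA is `mrna`, placed at the
# start of its own chromosome
mrna_transcript <- function(mrna, utr5_len, cds_len, id = "TX1",
                            protein_id = "P1", chrom = "chrT") {
  list(genome = tiny_genome(stats::setNames(mrna, chrom)),
       tx = transcript_model(id, chrom, "+", 1L, nchar(mrna), utr5_len,
                             cds_len, protein_id))
}

# transcript fixture with a 227-nt 5' UTR and prescribed codons at given
# mRNA positions (codon_at: named list mRNA-start -> codon); the CDS is
# padded with non-stop codons and closed with a stop
worked_example_transcript <- function(codon_at, utr5_len = 227L,
                                      n_codons = 400L) {
  codons <- rep("GCT", n_codons)  # alanine filler
  codons[1] <- "ATG"
  for (start in as.integer(names(codon_at))) {
    stopifnot((start - utr5_len - 1L) %% 3L == 0L)
    codons[(start - utr5_len - 1L) %/% 3L + 1L] <- codon_at[[as.character(start)]]
  }
  codons[n_codons] <- "TAA"
  mrna <- paste0(strrep("T", utr5_len), paste(codons, collapse = ""),
                 strrep("T", 20L))
  mrna_transcript(mrna, utr5_len, 3L * n_codons)
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

small_cohort_spec <- function(...) {
  cohort_spec(seed = 101L, n_patients = 4L, n_cases = 5L, n_controls = 5L,
              n_germline_per_patient = 20L, n_somatic_per_case = 4L,
              catalog_fraction = 0.9, genome_length = 30000L,
              n_transcripts = 8L, ...)
}
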