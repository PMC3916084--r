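# Codon-level consequence calling and canonical protein mapping.

test_that("translate_codon uses the standard genetic code", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("AAC"), "N")
  expect_error(translate_codon("ANC"), "codon")
  expect_error(translate_codon("AT"), "codon")
})

test_that("substitutions in prescribed codons give the expected residue changes", {
  fx <- worked_example_transcript(list(`1092` = "AAC", `1203` = "AGC"))
  mrna <- transcript_mrna(fx$genome, fx$tx)
  r1 <- annotate_mrna_variant(fx$tx, mrna, 1092L, "A", "C")
  expect_equal(r1$aa_pos, 289L)
  expect_equal(r1$ref_aa, "N")
  expect_equal(r1$alt_aa, "H")
  expect_equal(r1$consequence, "missense")
  r2 <- annotate_mrna_variant(fx$tx, mrna, 1205L, "C", "A")
  expect_equal(r2$aa_pos, 326L)
  expect_equal(r2$ref_aa, "S")
  expect_equal(r2$alt_aa, "R")
  expect_equal(r2$consequence, "missense")
})

test_that("stop-gain, stop-loss, synonymous and utr consequences are classified", {
  fx <- mrna_transcript(paste0("TT", "ATG", "CAA", "CTT", "TGA", "GG"),
                        2L, 12L)
  mrna <- transcript_mrna(fx$genome, fx$tx)
  sg <- annotate_mrna_variant(fx$tx, mrna, 6L, "C", "T")   # CAA -> TAA
  expect_equal(sg$consequence, "stop-gain")
  expect_equal(sg$alt_aa, "*")
  syn <- annotate_mrna_variant(fx$tx, mrna, 11L, "T", "C") # CTT -> CTC
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$ref_aa, syn$alt_aa)
  sl <- annotate_mrna_variant(fx$tx, mrna, 12L, "T", "C")  # TGA -> CGA
  expect_equal(sl$consequence, "stop-loss")
  utr <- annotate_mrna_variant(fx$tx, mrna, 1L, "T", "A")
  expect_equal(utr$consequence, "utr")
  expect_true(is.na(utr$aa_pos))
  expect_error(annotate_mrna_variant(fx$tx, mrna, 6L, "G", "T"),
               "reference mismatch")
})

test_that("single-codon annotation equals the whole-CDS translation oracle", {
  spec <- small_cohort_spec()
  ref <- make_reference(spec)
  set.seed(99)
  n_checked <- 0L
  while (n_checked < 1000L) {
    tx <- ref$transcripts[[sample(length(ref$transcripts), 1)]]
    mrna <- transcript_mrna(ref$genome, tx)
    mpos <- sample((tx$utr5_len + 1L):(tx$utr5_len + tx$cds_len), 1L)
    ref_m <- substring(mrna, mpos, mpos)
    alt_m <- sample(setdiff(c("A", "C", "G", "T"), ref_m), 1)
    gpos <- mrna_to_genomic(tx, mpos)
    ref_g <- if (tx$strand == "-") chartr("ACGT", "TGCA", ref_m) else ref_m
    alt_g <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt_m) else alt_m
    ann <- annotate_snv(ref$genome, tx, tx$chrom, gpos, ref_g, alt_g)

    # oracle: mutate the whole mRNA, translate the full CDS, diff proteins
    mut <- mrna
    substr(mut, mpos, mpos) <- alt_m
    cds_ref <- substring(mrna, tx$utr5_len + 1L, tx$utr5_len + tx$cds_len)
    cds_mut <- substring(mut, tx$utr5_len + 1L, tx$utr5_len + tx$cds_len)
    aa_ref <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(cds_ref))), "")[[1]]
    aa_mut <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds_mut), no.init.codon = TRUE)), "")[[1]]
    diff_at <- which(aa_ref != aa_mut)
    codon_pos <- (mpos - tx$utr5_len - 1L) %/% 3L + 1L
    if (length(diff_at) == 0L) {
      expect_equal(ann$consequence, "synonymous")
      expect_equal(ann$aa_pos, codon_pos)
    } else {
      expect_equal(diff_at, ann$aa_pos)
      expect_equal(aa_ref[diff_at], ann$ref_aa)
      expect_equal(aa_mut[diff_at], ann$alt_aa)
      expected_cons <- if (aa_mut[diff_at] == "*") "stop-gain"
      else if (aa_ref[diff_at] == "*") "stop-loss" else "missense"
      expect_equal(ann$consequence, expected_cons)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})

test_that("minus-strand transcripts give the same protein annotation as their plus-strand mirror", {
  mrna <- paste0("TTTT", "ATGAACAGCCTTTGGTGA", "GG")
  fx_plus <- mrna_transcript(mrna, 4L, 18L)
  # mirror: genome carries the reverse complement, transcript on minus strand
  g_minus <- tiny_genome(c(chrT = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mrna)))))
  tx_minus <- transcript_model("TX1", "chrT", "-", 1L, nchar(mrna), 4L, 18L, "P1")
  L <- nchar(mrna)
  for (mpos in c(5L, 7L, 12L, 20L)) {
    ref_m <- substring(mrna, mpos, mpos)
    alt_m <- setdiff(c("A", "C", "G", "T"), ref_m)[1]
    a_plus <- annotate_snv(fx_plus$genome, fx_plus$tx, "chrT", mpos, ref_m, alt_m)
    gpos_minus <- L - mpos + 1L
    a_minus <- annotate_snv(g_minus, tx_minus, "chrT", gpos_minus,
                            chartr("ACGT", "TGCA", ref_m),
                            chartr("ACGT", "TGCA", alt_m))
    expect_equal(a_minus[, c("aa_pos", "ref_aa", "alt_aa", "consequence")],
                 a_plus[, c("aa_pos", "ref_aa", "alt_aa", "consequence")])
  }
})

test_that("splice classification is restricted to the intronic window", {
  tx <- transcript_model("t", "chr1", "+", c(101L, 120L), c(105L, 140L),
                         0L, 24L, "p")
  expect_true(classify_splice(tx, 106L))
  expect_true(classify_splice(tx, 107L))
  expect_false(classify_splice(tx, 108L))
  expect_true(classify_splice(tx, 119L))
  expect_false(classify_splice(tx, 110L))
  expect_false(classify_splice(tx, 106L, splice_window = 0L))
  expect_error(classify_splice(tx, 103L), "exonic")
})

test_that("each (variant, transcript) pair receives exactly one consequence", {
  spec <- small_cohort_spec()
  ref <- make_reference(spec)
  ch <- make_cohort(spec, ref)
  one <- ch$snvs_by_sample[[1]]
  one$sample_id <- "s1"
  ann <- annotate_snvs(ref$genome, ref$transcripts, one)
  expect_true(all(ann$consequence %in%
                    c("missense", "synonymous", "stop-gain", "stop-loss",
                      "splice", "utr", "intron", "intergenic")))
  pair <- paste(ann$pos, ann$ref, ann$alt, ann$transcript_id)
  expect_false(any(duplicated(pair)))
})

test_that("canonical mapping applies offsets and counts unmapped proteins", {
  idmap <- data.frame(protein_id = c("P1", "P2"),
                      canonical_protein_id = c("UP1", "UP2"),
                      offset = c(0L, 5L), stringsAsFactors = FALSE)
  annots <- data.frame(protein_id = c("P1", "P2", "P3"),
                       aa_pos = c(289L, 10L, 4L), stringsAsFactors = FALSE)
  out <- map_to_canonical(annots, idmap)
  expect_equal(out$canonical_pos, c(289L, 15L, NA_integer_))
  expect_equal(out$canonical_protein_id, c("UP1", "UP2", NA_character_))
  expect_equal(attr(out, "n_unmapped"), 1L)
})
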