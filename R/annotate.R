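# Codon-level consequence calling: from filtered SNVs to protein
# coordinates. One annotation row per (variant, transcript); no collapsing
# to a "most severe" consequence.

CONSEQUENCES <- c("missense", "synonymous", "stop-gain", "stop-loss",
                  "splice", "utr", "intron", "intergenic")

#' Translate a codon with the standard genetic code
#'
#' @param codon Three-letter A/C/G/T string (vectorized).
#' @return Single-letter amino acid, `"*"` for stop codons.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) stop("not an unambiguous codon: ", paste(codon[bad], collapse = ", "))
  unname(Biostrings::GENETIC_CODE[codon])
}

consequence_of <- function(ref_aa, alt_aa) {
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stop-gain")
  if (ref_aa == "*") return("stop-loss")
  "missense"
}

#' Annotate a substitution given in mRNA coordinates
#'
#' Locates the codon containing `mrna_pos`, substitutes the alternate base
#' at its offset, translates both codons and classifies the consequence.
#' `ref` and `alt` must be on the mRNA (sense) strand.
#'
#' @param tx A `transcript_model`.
#' @param mrna_seq The transcript's spliced mRNA sequence (see
#'   [transcript_mrna()]).
#' @param mrna_pos 1-based mRNA position of the substitution.
#' @param ref,alt Reference and alternate base (mRNA strand).
#' @return One-row data frame: transcript_id, mrna_pos, mrna_ref, mrna_alt,
#'   aa_pos, ref_aa, alt_aa, consequence, protein_id.
#' @export
annotate_mrna_variant <- function(tx, mrna_seq, mrna_pos, ref, alt) {
  if (ref == alt) stop("ref and alt must differ")
  seen <- substring(mrna_seq, mrna_pos, mrna_pos)
  if (seen != ref) {
    stop(sprintf("reference mismatch at %s mRNA position %d: expected %s, mRNA has %s",
                 tx$transcript_id, mrna_pos, ref, seen))
  }
  row <- data.frame(transcript_id = tx$transcript_id, mrna_pos = mrna_pos,
                    mrna_ref = ref, mrna_alt = alt, aa_pos = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    consequence = NA_character_, protein_id = tx$protein_id,
                    stringsAsFactors = FALSE)
  mp <- mrna_to_protein(tx, mrna_pos)
  if (is.na(mp$aa_pos)) {
    row$consequence <- "utr"
    return(row)
  }
  codon_start <- tx$utr5_len + (mp$aa_pos - 1L) * 3L + 1L
  ref_codon <- substring(mrna_seq, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, mp$codon_offset, mp$codon_offset) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  row$aa_pos <- mp$aa_pos
  row$ref_aa <- ref_aa
  row$alt_aa <- alt_aa
  row$consequence <- consequence_of(ref_aa, alt_aa)
  row
}

#' Is an intronic position within the splice window of an exon boundary?
#'
#' @param tx A `transcript_model`.
#' @param pos Genomic position, intronic for `tx`.
#' @param splice_window Number of intronic nucleotides adjacent to an exon
#'   boundary that count as splice-affecting (default 2, the canonical
#'   GT/AG dinucleotides).
#' @return `TRUE` if within `splice_window` nt of an internal exon boundary
#'   on the intronic side.
#' @export
classify_splice <- function(tx, pos, splice_window = 2L) {
  pos <- as.integer(pos)
  if (!is.na(genomic_to_mrna(tx, tx$chrom, pos))) {
    stop("position ", pos, " is exonic for ", tx$transcript_id)
  }
  n <- length(tx$exon_starts)
  if (n < 2L || splice_window <= 0L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    donor_lo <- tx$exon_ends[i] + 1L
    acc_hi <- tx$exon_starts[i + 1L] - 1L
    if (pos >= donor_lo && pos <= acc_hi) {
      return(pos - tx$exon_ends[i] <= splice_window ||
               tx$exon_starts[i + 1L] - pos <= splice_window)
    }
  }
  FALSE
}

#' Annotate one genomic SNV against one transcript
#'
#' Maps the genomic position into the transcript, complementing ref/alt for
#' minus-strand transcripts, and classifies the consequence (missense,
#' synonymous, stop-gain, stop-loss, utr, splice, intron or intergenic).
#'
#' @param genome A `reference_genome`.
#' @param tx A `transcript_model` on the variant's chromosome.
#' @param chrom,pos,ref,alt The substitution in genomic coordinates.
#' @param splice_window Passed to [classify_splice()].
#' @return One-row data frame as in [annotate_mrna_variant()] plus chrom,
#'   pos, ref, alt columns.
#' @export
annotate_snv <- function(genome, tx, chrom, pos, ref, alt, splice_window = 2L) {
  if (chrom != tx$chrom) stop("variant on ", chrom, " but transcript on ", tx$chrom)
  gref <- substring(genome[[chrom]], pos, pos)
  if (gref != ref) {
    stop(sprintf("reference mismatch at %s:%d: expected %s, genome has %s",
                 chrom, pos, ref, gref))
  }
  base <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
  mrna_pos <- genomic_to_mrna(tx, chrom, pos)
  if (is.na(mrna_pos)) {
    span_lo <- min(tx$exon_starts); span_hi <- max(tx$exon_ends)
    cons <- if (pos >= span_lo && pos <= span_hi) {
      if (classify_splice(tx, pos, splice_window)) "splice" else "intron"
    } else "intergenic"
    row <- data.frame(transcript_id = tx$transcript_id,
                      mrna_pos = NA_integer_, mrna_ref = NA_character_,
                      mrna_alt = NA_character_, aa_pos = NA_integer_,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      consequence = cons, protein_id = tx$protein_id,
                      stringsAsFactors = FALSE)
    return(cbind(base, row))
  }
  if (tx$strand == "-") {
    ref_t <- comp_base(ref); alt_t <- comp_base(alt)
  } else {
    ref_t <- ref; alt_t <- alt
  }
  mrna_seq <- transcript_mrna(genome, tx)
  cbind(base, annotate_mrna_variant(tx, mrna_seq, mrna_pos, ref_t, alt_t))
}

#' Annotate a table of SNVs against a set of transcripts
#'
#' Every (variant, transcript) pair on the same chromosome with a
#' non-intergenic consequence yields one row; variants touching no
#' transcript yield a single intergenic row with transcript fields `NA`.
#'
#' @param genome A `reference_genome`.
#' @param transcripts List of `transcript_model` objects.
#' @param snvs Data frame with columns sample_id, chrom, pos, ref, alt.
#' @param splice_window Passed to [classify_splice()].
#' @return Data frame of annotations.
#' @export
annotate_snvs <- function(genome, transcripts, snvs, splice_window = 2L) {
  # cache per-transcript geometry so cohort-scale annotation stays linear
  cache <- lapply(transcripts, function(tx) {
    list(tx = tx, mrna = transcript_mrna(genome, tx),
         epos = exonic_positions(tx),
         span_lo = min(tx$exon_starts), span_hi = max(tx$exon_ends))
  })
  out <- vector("list", nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    hits <- list()
    for (cx in cache) {
      tx <- cx$tx
      if (tx$chrom != snvs$chrom[i]) next
      pos <- as.integer(snvs$pos[i])
      if (pos < cx$span_lo - 1L || pos > cx$span_hi + 1L) next
      mrna_pos <- match(pos, cx$epos)
      if (is.na(mrna_pos)) {
        cons <- if (pos >= cx$span_lo && pos <= cx$span_hi) {
          if (classify_splice(tx, pos, splice_window)) "splice" else "intron"
        } else "intergenic"
        if (cons == "intergenic") next
        row <- data.frame(
          chrom = snvs$chrom[i], pos = pos, ref = snvs$ref[i],
          alt = snvs$alt[i], transcript_id = tx$transcript_id,
          mrna_pos = NA_integer_, mrna_ref = NA_character_,
          mrna_alt = NA_character_, aa_pos = NA_integer_,
          ref_aa = NA_character_, alt_aa = NA_character_,
          consequence = cons, protein_id = tx$protein_id,
          stringsAsFactors = FALSE)
      } else {
        if (tx$strand == "-") {
          ref_t <- comp_base(snvs$ref[i]); alt_t <- comp_base(snvs$alt[i])
        } else {
          ref_t <- snvs$ref[i]; alt_t <- snvs$alt[i]
        }
        row <- cbind(
          data.frame(chrom = snvs$chrom[i], pos = pos, ref = snvs$ref[i],
                     alt = snvs$alt[i], stringsAsFactors = FALSE),
          annotate_mrna_variant(tx, cx$mrna, mrna_pos, ref_t, alt_t))
      }
      hits[[length(hits) + 1L]] <- row
    }
    if (length(hits) == 0L) {
      hits[[1L]] <- data.frame(
        chrom = snvs$chrom[i], pos = as.integer(snvs$pos[i]),
        ref = snvs$ref[i], alt = snvs$alt[i], transcript_id = NA_character_,
        mrna_pos = NA_integer_, mrna_ref = NA_character_,
        mrna_alt = NA_character_, aa_pos = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        consequence = "intergenic", protein_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    chunk <- do.call(rbind, hits)
    chunk <- cbind(sample_id = snvs$sample_id[i], chunk,
                   stringsAsFactors = FALSE)
    out[[i]] <- chunk
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a protein id map (transcript protein -> canonical protein)
#'
#' Tab-delimited with header columns protein_id, canonical_protein_id,
#' offset (integer added to the protein position).
#'
#' @param path Input path.
#' @return Data frame id map, one row per protein_id.
#' @export
read_idmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "canonical_protein_id", "offset")
  if (!all(need %in% names(df))) {
    stop("idmap must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$protein_id)) stop("idmap has duplicate protein_id rows")
  df
}

#' Map annotated variants onto canonical protein coordinates
#'
#' Adds `canonical_protein_id` and `canonical_pos = aa_pos + offset`
#' columns. Protein ids absent from the map get `NA` canonical fields; the
#' number of such rows (among coding annotations) is recorded in the
#' `n_unmapped` attribute — mapping to canonical entries typically shrinks
#' the protein set since several transcript isoforms share one canonical
#' record.
#'
#' @param annots Annotation data frame from [annotate_snvs()].
#' @param idmap Data frame from [read_idmap()].
#' @return `annots` with canonical columns; attribute `n_unmapped`.
#' @export
map_to_canonical <- function(annots, idmap) {
  i <- match(annots$protein_id, idmap$protein_id)
  annots$canonical_protein_id <- idmap$canonical_protein_id[i]
  annots$canonical_pos <- ifelse(is.na(annots$aa_pos), NA_integer_,
                                 annots$aa_pos + idmap$offset[i])
  coding <- !is.na(annots$aa_pos)
  attr(annots, "n_unmapped") <- sum(coding & is.na(i))
  annots
}

#' Write an annotation table in curated-archive search-result layout
#'
#' Column order: transcript accession, mRNA position, base change `R|A`,
#' protein accession, amino-acid position, residue change, canonical
#' accession, canonical position, sample, type, library.
#'
#' @param annots Annotated (and canonically mapped) variant table.
#' @param path Output path.
#' @param type,library_strategy Free-text columns (recycled).
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annots, path, type = "", library_strategy = "WXS") {
  cod <- annots[!is.na(annots$aa_pos), , drop = FALSE]
  out <- data.frame(
    transcript_id = cod$transcript_id, pos = cod$mrna_pos,
    chg = paste0(cod$mrna_ref, "|", cod$mrna_alt),
    protein_id = cod$protein_id, aa_pos = cod$aa_pos,
    aa_chg = paste0(cod$ref_aa, "|", cod$alt_aa),
    canonical_id = if ("canonical_protein_id" %in% names(cod))
      cod$canonical_protein_id else NA_character_,
    canonical_pos = if ("canonical_pos" %in% names(cod))
      cod$canonical_pos else NA_integer_,
    sample = cod$sample_id, type = type, library = library_strategy,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
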