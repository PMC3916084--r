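# Reference genome and transcript coordinate model.
#
# All coordinates are 1-based inclusive (VCF convention). BED inputs are
# converted on read. Transcript exons are stored as ascending genomic
# intervals; 5'->3' transcript order is derived from the strand.

#' Load a reference genome from FASTA
#'
#' Reads a (small) FASTA file into a named character vector of uppercase
#' chromosome sequences. Lowercase input is accepted and normalized.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `reference_genome`; names are
#'   chromosome names, values are uppercase A/C/G/T/N strings.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("FASTA format error: duplicate record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA alphabet error: non-ACGTN characters in record(s): ",
         paste(nm[bad], collapse = ", "))
  }
  structure(seqs, class = "reference_genome")
}

#' Write a genome to FASTA (60-column wrapped)
#'
#' @param genome A `reference_genome` (named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  nchar(genome[[chrom]])
}

#' Construct a transcript model
#'
#' A transcript is a set of non-overlapping exons on one chromosome plus the
#' mRNA partition into 5' UTR, CDS (length divisible by 3, stop codon
#' included) and 3' UTR. Exon intervals are given in ascending genomic
#' order regardless of strand; on the minus strand the transcript's 5' end
#' is the highest genomic coordinate of the last interval.
#'
#' @param transcript_id Transcript accession.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 1-based inclusive exon
#'   bounds, ascending, non-overlapping.
#' @param utr5_len Number of mRNA nucleotides before the CDS.
#' @param cds_len Number of CDS nucleotides (divisible by 3).
#' @param protein_id Linked protein accession.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exon_starts,
                             exon_ends, utr5_len, cds_len, protein_id) {
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  utr5_len <- as.integer(utr5_len)
  cds_len <- as.integer(cds_len)
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exon_ends < exon_starts)) stop("exon end before start")
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(utils::head(exon_ends, -1L) >= utils::tail(exon_starts, -1L))) {
    stop("exons must be ascending and non-overlapping")
  }
  if (cds_len %% 3L != 0L) stop("cds_len must be divisible by 3")
  exonic_len <- sum(exon_ends - exon_starts + 1L)
  if (utr5_len + cds_len > exonic_len) {
    stop("utr5_len + cds_len exceeds total exonic length")
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exon_starts = exon_starts, exon_ends = exon_ends,
         utr5_len = utr5_len, cds_len = cds_len, protein_id = protein_id),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s%s) %d exon(s), utr5=%d cds=%d -> %s\n",
              x$transcript_id, x$chrom, x$strand, length(x$exon_starts),
              x$utr5_len, x$cds_len, x$protein_id))
  invisible(x)
}

#' Exonic genomic positions in transcript (5'->3') order
#'
#' @param tx A `transcript_model`.
#' @return Integer vector of genomic positions; element `i` is the genomic
#'   coordinate of mRNA position `i`.
#' @export
exonic_positions <- function(tx) {
  pos <- unlist(Map(seq.int, tx$exon_starts, tx$exon_ends), use.names = FALSE)
  if (tx$strand == "-") rev(pos) else pos
}

#' Map a genomic position to an mRNA position
#'
#' @param tx A `transcript_model`.
#' @param chrom,pos Genomic position (1-based).
#' @return 1-based mRNA position, or `NA_integer_` if `pos` is not exonic.
#' @export
genomic_to_mrna <- function(tx, chrom, pos) {
  if (chrom != tx$chrom) stop("position on ", chrom, " but transcript on ", tx$chrom)
  idx <- match(as.integer(pos), exonic_positions(tx))
  if (is.na(idx)) NA_integer_ else idx
}

#' Map an mRNA position back to its genomic coordinate
#'
#' Inverse of [genomic_to_mrna()].
#'
#' @param tx A `transcript_model`.
#' @param mrna_pos 1-based mRNA position.
#' @return Genomic position (integer).
#' @export
mrna_to_genomic <- function(tx, mrna_pos) {
  ep <- exonic_positions(tx)
  mrna_pos <- as.integer(mrna_pos)
  if (any(mrna_pos < 1L | mrna_pos > length(ep))) {
    stop("mRNA position out of range 1..", length(ep))
  }
  ep[mrna_pos]
}

#' Map an mRNA position to protein position and codon offset
#'
#' CDS positions map to `aa_pos = floor((mrna_pos - utr5_len - 1)/3) + 1`
#' with codon offset `((mrna_pos - utr5_len - 1) mod 3) + 1`. Positions in
#' the 5' or 3' UTR return `NA`.
#'
#' @param tx A `transcript_model`.
#' @param mrna_pos 1-based mRNA position.
#' @return List with `aa_pos` and `codon_offset`, both `NA_integer_` for
#'   untranslated positions.
#' @export
mrna_to_protein <- function(tx, mrna_pos) {
  mrna_pos <- as.integer(mrna_pos)
  exonic_len <- sum(tx$exon_ends - tx$exon_starts + 1L)
  if (mrna_pos < 1L || mrna_pos > exonic_len) {
    stop("mRNA position ", mrna_pos, " out of range 1..", exonic_len)
  }
  if (mrna_pos <= tx$utr5_len || mrna_pos > tx$utr5_len + tx$cds_len) {
    return(list(aa_pos = NA_integer_, codon_offset = NA_integer_))
  }
  off0 <- mrna_pos - tx$utr5_len - 1L
  list(aa_pos = off0 %/% 3L + 1L, codon_offset = off0 %% 3L + 1L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates exon sequences; on the minus strand the concatenation is
#' reverse-complemented so the result reads 5'->3' of the transcript.
#'
#' @param genome A `reference_genome`.
#' @param tx A `transcript_model`.
#' @return mRNA sequence as a single string.
#' @export
transcript_mrna <- function(genome, tx) {
  chrseq <- genome[[tx$chrom]]
  pieces <- substring(chrseq, tx$exon_starts, tx$exon_ends)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Extract a reference window around a genomic position
#'
#' Returns the `2*delta + 1` reference bases centered on `pos`; positions
#' overhanging the chromosome ends are padded with `N` so all windows have
#' equal length.
#'
#' @param genome A `reference_genome`.
#' @param chrom,pos Center position.
#' @param delta Non-negative flank width.
#' @return Character string of length `2*delta + 1`.
#' @export
extract_window <- function(genome, chrom, pos, delta) {
  delta <- as.integer(delta)
  if (delta < 0L) stop("delta must be >= 0")
  len <- chrom_length(genome, chrom)
  if (pos < 1L || pos > len) stop("position ", pos, " outside ", chrom)
  lo <- pos - delta
  hi <- pos + delta
  core <- substring(genome[[chrom]], max(lo, 1L), min(hi, len))
  paste0(strrep("N", max(0L, 1L - lo)), core, strrep("N", max(0L, hi - len)))
}

#' Read transcript models from a tab-delimited file
#'
#' Expected header: `transcript_id, chrom, strand, exon_starts, exon_ends,
#' utr5_len, cds_len, protein_id`, with exon bounds comma-joined.
#'
#' @param path Input path.
#' @return List of `transcript_model` objects, named by transcript id.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_starts", "exon_ends",
            "utr5_len", "cds_len", "protein_id")
  if (!all(need %in% names(df))) {
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(
      df$transcript_id[i], df$chrom[i], df$strand[i],
      as.integer(strsplit(df$exon_starts[i], ",")[[1]]),
      as.integer(strsplit(df$exon_ends[i], ",")[[1]]),
      df$utr5_len[i], df$cds_len[i], df$protein_id[i])
  })
  names(out) <- df$transcript_id
  out
}

#' Write transcript models to a tab-delimited file
#'
#' @param txs List of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(txs, path) {
  df <- do.call(rbind, lapply(txs, function(tx) {
    data.frame(transcript_id = tx$transcript_id, chrom = tx$chrom,
               strand = tx$strand,
               exon_starts = paste(tx$exon_starts, collapse = ","),
               exon_ends = paste(tx$exon_ends, collapse = ","),
               utr5_len = tx$utr5_len, cds_len = tx$cds_len,
               protein_id = tx$protein_id, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
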