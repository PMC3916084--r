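# Per-sample SNV parsing and depth/quality/region filtering.

#' Parse single-sample SNV calls from a VCF file
#'
#' Reads a VCF 4.x file (via vcfR), splits multi-allelic lines into one
#' record per alternate allele, and separates single-base substitutions
#' from everything else (indels, MNVs, symbolic alleles), which are
#' reported as `non_snv`. Depth is taken from INFO `DP`, falling back to
#' the first sample's FORMAT `DP`; records without any `DP` carry depth 0
#' (and so will fail the depth filter).
#'
#' @param path VCF file path.
#' @param sample_id Sample identifier attached to every record.
#' @return List of class `vcf_parse` with elements `snvs` (data frame:
#'   sample_id, chrom, pos, ref, alt, qual, depth) and `non_snv` (same
#'   shape, the excluded records).
#' @export
parse_vcf <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      qual = numeric(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(structure(list(snvs = empty, non_snv = empty), class = "vcf_parse"))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  depth <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  if (is.null(depth)) depth <- rep(NA_real_, nrow(fix))
  if (anyNA(depth) && ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) >= 2L) {
    gt_dp <- suppressWarnings(
      vcfR::extract.gt(v, "DP", as.numeric = TRUE))
    if (!is.null(gt_dp)) {
      miss <- is.na(depth)
      depth[miss] <- gt_dp[miss, 1L]
    }
  }
  depth[is.na(depth)] <- 0
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(sample_id = sample_id, chrom = fix$CHROM[i],
               pos = as.integer(fix$POS[i]), ref = toupper(fix$REF[i]),
               alt = toupper(alts), qual = qual[i],
               depth = as.integer(depth[i]), stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, rows)
  is_snv <- nchar(all_rows$ref) == 1L & nchar(all_rows$alt) == 1L &
    all_rows$ref %in% c("A", "C", "G", "T") &
    all_rows$alt %in% c("A", "C", "G", "T") &
    all_rows$ref != all_rows$alt
  structure(list(snvs = all_rows[is_snv, , drop = FALSE],
                 non_snv = all_rows[!is_snv, , drop = FALSE]),
            class = "vcf_parse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read target regions from a BED file
#'
#' BED's 0-based half-open intervals are converted to 1-based inclusive
#' genomic ranges on import.
#'
#' @param path BED file path.
#' @return A `GRanges` of target regions.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Filter configuration for SNV records
#'
#' Both thresholds are strict: a record is kept only when depth is greater
#' than `min_depth` *and* quality greater than `min_qual` (defaults: more
#' than 10 reads and quality above 20), and, when `regions` is supplied,
#' its position lies inside a target region.
#'
#' @param min_depth Exclusive read-depth threshold (default 10).
#' @param min_qual Exclusive quality threshold (default 20).
#' @param regions Optional `GRanges` of target (exome) regions, or `NULL`
#'   to skip the region test.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, min_qual = 20, regions = NULL) {
  if (min_depth < 0 || min_qual < 0) stop("thresholds must be non-negative")
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 regions = regions), class = "filter_config")
}

in_regions <- function(chrom, pos, regions) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, regions, ignore.strand = TRUE) > 0L
}

#' Apply depth/quality/region filters to SNV records
#'
#' Rejection reason is the first failing test in the fixed order depth,
#' quality, region, so reports are reproducible.
#'
#' @param records Data frame of SNV records as produced by [parse_vcf()].
#' @param cfg A [filter_config()].
#' @return List of class `filter_report` with `kept` and `rejected` data
#'   frames; `rejected` carries a `reason` column in
#'   `{depth, quality, region}`.
#' @export
filter_snvs <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(records)
  if (n == 0L) {
    rej <- cbind(records, reason = character(0))
    return(structure(list(kept = records, rejected = rej),
                     class = "filter_report"))
  }
  fail_depth <- !(records$depth > cfg$min_depth)
  fail_qual <- !(records$qual > cfg$min_qual)
  if (is.null(cfg$regions)) {
    fail_region <- rep(FALSE, n)
  } else {
    fail_region <- !in_regions(records$chrom, records$pos, cfg$regions)
  }
  reason <- rep(NA_character_, n)
  reason[fail_region] <- "region"
  reason[fail_qual] <- "quality"
  reason[fail_depth] <- "depth"
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  structure(list(kept = kept, rejected = rejected), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, rejected %d (%s)\n",
              nrow(x$kept), nrow(x$rejected),
              paste(sprintf("%s=%d", names(table(x$rejected$reason)),
                            as.integer(table(x$rejected$reason))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a filter report as a tab-delimited table
#'
#' Columns: sample_id, chrom, pos, ref, alt, qual, depth, status, reason.
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  kept <- report$kept
  if (nrow(kept)) { kept$status <- "kept"; kept$reason <- "" }
  else { kept$status <- character(0); kept$reason <- character(0) }
  rej <- report$rejected
  if (nrow(rej)) rej$status <- "rejected" else rej$status <- character(0)
  out <- rbind(kept[, c("sample_id", "chrom", "pos", "ref", "alt", "qual",
                        "depth", "status", "reason")],
               rej[, c("sample_id", "chrom", "pos", "ref", "alt", "qual",
                       "depth", "status", "reason")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
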