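# Metadata curation: TCGA-style barcode parsing, case/control typing,
# experiment accession assignment and GC-content QC.

#' Parse a TCGA-style sample barcode
#'
#' Barcodes are dash-delimited, e.g. `TCGA-CH-5739-01A-11D-1576-08`:
#' project, tissue source site, participant, sample type + vial, then
#' portion/analyte, plate and center as given. The sample type code is the
#' leading digits of the fourth field, the vial its trailing letters.
#'
#' @param s Barcode string.
#' @return List of class `barcode_fields`.
#' @export
parse_barcode <- function(s) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (length(parts) < 4L) stop("barcode has fewer than 4 fields: ", s)
  type_field <- parts[4]
  code <- sub("^([0-9]+).*$", "\\1", type_field)
  if (code == type_field && !grepl("^[0-9]+$", type_field)) {
    stop("non-numeric sample type code in barcode: ", s)
  }
  if (!grepl("^[0-9]+$", code)) stop("non-numeric sample type code in barcode: ", s)
  vial <- sub("^[0-9]+", "", type_field)
  structure(list(project = parts[1], tissue_source_site = parts[2],
                 participant = parts[3],
                 sample_type_code = as.integer(code), vial = vial,
                 trailing = if (length(parts) > 4L) parts[5:length(parts)]
                 else character(0)),
            class = "barcode_fields")
}

#' Re-assemble a parsed barcode
#'
#' Inverse of [parse_barcode()] for well-formed barcodes.
#'
#' @param bf A `barcode_fields` object.
#' @return Barcode string.
#' @export
format_barcode <- function(bf) {
  paste(c(bf$project, bf$tissue_source_site, bf$participant,
          paste0(sprintf("%02d", bf$sample_type_code), bf$vial),
          bf$trailing), collapse = "-")
}

#' Classify a sample type code into case or control
#'
#' Tumor sample types 01-09 are cases; matched normals 10-19 are controls.
#'
#' @param code Integer sample type code.
#' @return `"case"` or `"control"`.
#' @export
classify_arm <- function(code) {
  code <- as.integer(code)
  if (is.na(code) || code < 1L || code > 19L) {
    stop("sample type code ", code, " outside the classifiable range 1-19")
  }
  if (code <= 9L) "case" else "control"
}

#' Assign experiment accessions to curated samples
#'
#' Cases get prefix `CA`, controls `CO`, each with an arm-local serial
#' counter starting at 1 in input (curation) order, zero-padded to 5
#' digits, and a trailing cancer-type code (e.g. `CA00001BC`).
#'
#' @param arms Character vector of `"case"`/`"control"` in curation order.
#' @param cancer_code Two-letter cancer type suffix (default `"BC"`).
#' @return Character vector of accessions, same order as `arms`.
#' @export
assign_accessions <- function(arms, cancer_code = "BC") {
  if (!all(arms %in% c("case", "control"))) {
    stop("arms must be 'case' or 'control'")
  }
  serial <- integer(length(arms))
  serial[arms == "case"] <- seq_len(sum(arms == "case"))
  serial[arms == "control"] <- seq_len(sum(arms == "control"))
  prefix <- ifelse(arms == "case", "CA", "CO")
  sprintf("%s%05d%s", prefix, serial, cancer_code)
}

#' GC fraction of a set of sequences
#'
#' `N` bases are excluded from the denominator.
#'
#' @param seqs Character vector of nucleotide sequences (pooled).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seqs) {
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("empty sequence input")
  }
  s <- paste(toupper(seqs), collapse = "")
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(s) - nchar(gsub(b, "", s, fixed = TRUE))
  }, numeric(1))
  denom <- sum(counts)
  if (denom == 0) stop("no A/C/G/T bases in input")
  unname((counts["G"] + counts["C"]) / denom)
}

#' GC-content QC for a sample
#'
#' Samples outside the acceptable GC band (inclusive bounds, default
#' 38-48%) fail QC and would not be processed for curation.
#'
#' @param seqs Character vector of the sample's sequences.
#' @param lo,hi Inclusive GC-fraction bounds (defaults 0.38 and 0.48).
#' @return List with `status` (`"pass"`/`"fail"`) and `gc` fraction.
#' @export
gc_qc <- function(seqs, lo = 0.38, hi = 0.48) {
  gc <- gc_content(seqs)
  list(status = if (gc >= lo && gc <= hi) "pass" else "fail", gc = gc)
}

#' Curate a sample metadata table
#'
#' Parses barcodes, classifies arms, assigns experiment accessions in
#' curation order and (optionally) attaches GC QC status.
#'
#' @param barcodes Character vector of sample barcodes in curation order.
#' @param cancer_code Accession suffix (default `"BC"`).
#' @param library_strategy Free-text library column (recycled, default
#'   `"WXS"`).
#' @param sample_seqs Optional named list (by barcode) of sequences for GC
#'   QC; samples without sequences get status `"not_assessed"`.
#' @return Data frame: barcode, participant, sample_type_code, arm,
#'   accession, library, qc_status, gc.
#' @export
curate_metadata <- function(barcodes, cancer_code = "BC",
                            library_strategy = "WXS", sample_seqs = NULL) {
  parsed <- lapply(barcodes, parse_barcode)
  arms <- vapply(parsed, function(b) classify_arm(b$sample_type_code),
                 character(1))
  acc <- assign_accessions(arms, cancer_code)
  qc_status <- rep("not_assessed", length(barcodes))
  gc <- rep(NA_real_, length(barcodes))
  if (!is.null(sample_seqs)) {
    for (i in seq_along(barcodes)) {
      if (barcodes[i] %in% names(sample_seqs)) {
        q <- gc_qc(sample_seqs[[barcodes[i]]])
        qc_status[i] <- q$status
        gc[i] <- q$gc
      }
    }
  }
  data.frame(
    barcode = barcodes,
    participant = vapply(parsed, `[[`, character(1), "participant"),
    sample_type_code = vapply(parsed, `[[`, integer(1), "sample_type_code"),
    arm = arms, accession = acc, library = library_strategy,
    qc_status = qc_status, gc = gc, stringsAsFactors = FALSE)
}
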