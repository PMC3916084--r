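# Over/under-representation of nsSNVs in annotation sets (domains,
# pathways, keywords) under a uniform-placement null across the proteome.

#' Read annotation sets from a tab-delimited table
#'
#' Header: set_name, protein_id, start, end. Each row is a residue
#' interval belonging to the set; overlapping intervals of one protein
#' within a set are merged before footprint computation.
#'
#' @param path Input path.
#' @return Named list of sets; each set is a data frame of merged
#'   (protein_id, start, end) intervals with a `footprint` attribute.
#' @export
read_annotation_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("set_name", "protein_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation-set table must have columns: ", paste(need, collapse = ", "))
  }
  make_annotation_sets(df)
}

#' Build annotation sets from an interval data frame
#'
#' @param df Data frame with set_name, protein_id, start, end.
#' @return Named list of merged interval data frames (see
#'   [read_annotation_sets()]).
#' @export
make_annotation_sets <- function(df) {
  out <- lapply(split(df, df$set_name), function(d) {
    merged <- do.call(rbind, lapply(split(d, d$protein_id), function(p) {
      ir <- IRanges::reduce(IRanges::IRanges(p$start, p$end))
      data.frame(protein_id = p$protein_id[1],
                 start = IRanges::start(ir), end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    }))
    rownames(merged) <- NULL
    attr(merged, "footprint") <- sum(merged$end - merged$start + 1L)
    merged
  })
  out[order(names(out))]
}

#' Total residue footprint of an annotation set
#'
#' @param set One element of [read_annotation_sets()].
#' @return Integer footprint length (overlaps merged).
#' @export
footprint_length <- function(set) attr(set, "footprint")

#' Expected variant count in a set under uniform placement
#'
#' With `n_total` variants placed uniformly over a proteome of
#' `proteome_len` residues, a set covering `footprint_len` residues
#' expects `n_total * footprint_len / proteome_len` variants.
#'
#' @param n_total Total number of (unique) nsSNVs on the proteome.
#' @param footprint_len Residues covered by the set.
#' @param proteome_len Total proteome residues.
#' @return Expected count (double).
#' @export
expected_count <- function(n_total, footprint_len, proteome_len) {
  if (proteome_len <= 0) stop("proteome length must be positive")
  if (footprint_len > proteome_len) stop("footprint exceeds proteome length")
  n_total * footprint_len / proteome_len
}

#' Significance of observed vs expected counts
#'
#' Two-sided normal approximation to the Poisson:
#' `z = (observed - expected)/sqrt(expected)`, `p = 2 * pnorm(-|z|)`
#' floored at the smallest positive double. `method = "poisson"` instead
#' uses the exact two-sided Poisson tail (doubled smaller tail, capped at
#' 1).
#'
#' @param observed Observed count.
#' @param expected Expected count under the uniform null (> 0).
#' @param method `"normal"` (default) or `"poisson"`.
#' @return List with `z`, `p`, `direction` (`"over"`, `"under"` or
#'   `"none"` when observed equals expected).
#' @export
enrichment_test <- function(observed, expected, method = c("normal", "poisson")) {
  method <- match.arg(method)
  if (expected <= 0) stop("expected count must be positive")
  z <- (observed - expected) / sqrt(expected)
  p <- if (method == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    min(1, 2 * min(stats::ppois(observed, expected),
                   1 - stats::ppois(observed - 1, expected)))
  }
  p <- max(p, .Machine$double.xmin)
  p <- min(p, 1)
  direction <- if (observed > expected) "over"
  else if (observed < expected) "under" else "none"
  list(z = z, p = p, direction = direction)
}

variant_in_set <- function(variants, set) {
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(set))) {
    hit <- hit | (variants$protein_id == set$protein_id[i] &
                    variants$aa_pos >= set$start[i] &
                    variants$aa_pos <= set$end[i])
  }
  hit
}

#' Run the enrichment scan over all annotation sets
#'
#' Observed counts are unique nsSNV residue positions (protein, position)
#' falling inside each set's footprint; expected counts come from
#' [expected_count()] with either residue-footprint proportionality
#' (default) or protein-count proportionality.
#'
#' @param variants Data frame of nsSNVs with protein_id and aa_pos
#'   (deduplicated to unique positions internally).
#' @param sets Named list from [read_annotation_sets()].
#' @param proteins Named vector of protein sequences defining the proteome.
#' @param p_cutoff Report only sets with `p <= p_cutoff` (default 1,
#'   i.e. all).
#' @param method Passed to [enrichment_test()].
#' @param by `"footprint"` (residues, default) or `"protein_count"`.
#' @return Data frame sorted by ascending p then set name: set_name,
#'   observed, expected, z, p, direction, p_bonferroni, approx_ok (FALSE
#'   flags expected < 5 where the normal approximation is poor).
#' @export
run_enrichment <- function(variants, sets, proteins, p_cutoff = 1,
                           method = "normal", by = c("footprint", "protein_count")) {
  by <- match.arg(by)
  pos_key <- paste(variants$protein_id, variants$aa_pos, sep = ":")
  uvars <- variants[!duplicated(pos_key), c("protein_id", "aa_pos")]
  n_total <- nrow(uvars)
  proteome_len <- sum(nchar(proteins))
  n_proteins <- length(proteins)
  rows <- lapply(names(sets), function(nm) {
    set <- sets[[nm]]
    observed <- sum(variant_in_set(uvars, set))
    expected <- if (by == "footprint") {
      expected_count(n_total, footprint_length(set), proteome_len)
    } else {
      n_total * length(unique(set$protein_id)) / n_proteins
    }
    tst <- enrichment_test(observed, expected, method)
    data.frame(set_name = nm, observed = observed, expected = expected,
               z = tst$z, p = tst$p, direction = tst$direction,
               approx_ok = expected >= 5, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res <- res[res$p <= p_cutoff, , drop = FALSE]
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  res
}

#' Write an enrichment table
#'
#' Columns follow the Observed / Expected / +/- / P-value layout.
#'
#' @param res Result of [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(res, path) {
  out <- data.frame(set_name = res$set_name, observed = res$observed,
                    expected = res$expected,
                    direction = c(over = "+", under = "-", none = ".")[res$direction],
                    p_value = res$p, z = res$z,
                    p_bonferroni = res$p_bonferroni,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
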