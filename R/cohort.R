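# Cohort-level bookkeeping: presence matrix, novelty against a catalog,
# common/rare classes, case/control overlap, frequency spectrum.

#' Canonical variant keys
#'
#' Nucleotide-level keys are `chrom:pos:ref:alt`; amino-acid-level keys are
#' `protein:pos:refaa:altaa` (canonical protein coordinates when present,
#' else transcript protein coordinates).
#'
#' @param df Data frame of variants/annotations.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return Character vector of keys (may contain `NA` for non-coding rows
#'   at amino-acid level).
#' @export
variant_key <- function(df, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  if (level == "nucleotide") {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    pid <- if ("canonical_protein_id" %in% names(df)) {
      ifelse(is.na(df$canonical_protein_id), df$protein_id,
             df$canonical_protein_id)
    } else df$protein_id
    ppos <- if ("canonical_pos" %in% names(df)) {
      ifelse(is.na(df$canonical_pos), df$aa_pos, df$canonical_pos)
    } else df$aa_pos
    ifelse(is.na(df$aa_pos), NA_character_,
           paste(pid, ppos, df$ref_aa, df$alt_aa, sep = ":"))
  }
}

#' Build a binary variant-by-sample presence matrix
#'
#' @param variant_keys Named list: one character vector of variant keys per
#'   sample. Sample ids must be unique.
#' @param labels Named character vector mapping sample id to `"case"` or
#'   `"control"`.
#' @param patients Optional named character vector mapping sample id to a
#'   patient id.
#' @return Object of class `cohort_matrix`: list with binary matrix `M`
#'   (sorted keys x sorted samples), `labels`, `patients`.
#' @export
build_cohort_matrix <- function(variant_keys, labels, patients = NULL) {
  samples <- names(variant_keys)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("variant_keys must be a named list with unique sample ids")
  }
  if (!all(samples %in% names(labels))) {
    stop("every sample needs a case/control label")
  }
  if (!all(labels[samples] %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  empty <- vapply(variant_keys, length, integer(1)) == 0L
  if (any(empty)) {
    warning("sample(s) with no variants: ", paste(samples[empty], collapse = ", "))
  }
  keys <- sort(unique(unlist(variant_keys, use.names = FALSE)))
  samples <- sort(samples)
  M <- matrix(0L, nrow = length(keys), ncol = length(samples),
              dimnames = list(keys, samples))
  for (s in samples) M[unique(variant_keys[[s]]), s] <- 1L
  structure(list(M = M, labels = labels[samples],
                 patients = if (is.null(patients)) NULL else patients[samples]),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d variant keys x %d samples (%d case, %d control)\n",
              nrow(x$M), ncol(x$M), sum(x$labels == "case"),
              sum(x$labels == "control")))
  invisible(x)
}

arm_cols <- function(cm, arm) which(cm$labels == arm)

#' Known/novel classification against a variant catalog
#'
#' A key is *known* when present in the catalog (a dbSNP stand-in) and
#' *novel* otherwise. Summaries are given per sample, pooled per arm and
#' overall, and for the key subset present in both case and control arms
#' (pooling typically lowers the known fraction because catalog-known keys
#' recur across samples while novel keys stay private).
#'
#' @param cm A `cohort_matrix`.
#' @param catalog Character vector of known variant keys.
#' @return List with `per_key` (key, known flag), `per_sample`
#'   (sample, n, n_known, fraction_known) and `pooled`
#'   (scope in all/case/control/case_control_shared with counts and
#'   fraction_known).
#' @export
novelty <- function(cm, catalog) {
  keys <- rownames(cm$M)
  known <- keys %in% catalog
  per_key <- data.frame(key = keys, known = known, stringsAsFactors = FALSE)
  per_sample <- do.call(rbind, lapply(colnames(cm$M), function(s) {
    present <- cm$M[, s] == 1L
    data.frame(sample = s, n = sum(present), n_known = sum(known & present),
               fraction_known = if (sum(present)) sum(known & present) / sum(present) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pooled_scope <- function(scope, sel) {
    data.frame(scope = scope, n = sum(sel), n_known = sum(known & sel),
               fraction_known = if (sum(sel)) sum(known & sel) / sum(sel) else NA_real_,
               stringsAsFactors = FALSE)
  }
  in_case <- rowSums(cm$M[, arm_cols(cm, "case"), drop = FALSE]) > 0
  in_control <- rowSums(cm$M[, arm_cols(cm, "control"), drop = FALSE]) > 0
  pooled <- rbind(
    pooled_scope("all", rep(TRUE, length(keys))),
    pooled_scope("case", in_case),
    pooled_scope("control", in_control),
    pooled_scope("case_control_shared", in_case & in_control))
  list(per_key = per_key, per_sample = per_sample, pooled = pooled)
}

#' Common/rare classification by cohort frequency
#'
#' Frequency is the fraction of samples carrying the key; a key is
#' *common* when its frequency is strictly greater than the threshold
#' (default 0.10) and *rare* otherwise.
#'
#' @param cm A `cohort_matrix`.
#' @param common_threshold Fraction in (0, 1); strict "greater than".
#' @return Data frame: key, n_samples, frequency, class.
#' @export
frequency_classes <- function(cm, common_threshold = 0.10) {
  if (common_threshold <= 0 || common_threshold >= 1) {
    stop("common_threshold must be in (0, 1)")
  }
  n <- ncol(cm$M)
  if (n < 1L) stop("cohort has no samples")
  cnt <- rowSums(cm$M)
  data.frame(key = rownames(cm$M), n_samples = as.integer(cnt),
             frequency = cnt / n,
             class = ifelse(cnt / n > common_threshold, "common", "rare"),
             stringsAsFactors = FALSE)
}

#' Case/control overlap of variant keys
#'
#' Partitions keys into those present in both arms, case-only and
#' control-only, and emits a ternary heatmap matrix over keys x samples
#' (2 = sample carries a key shared by both arms, 1 = sample carries an
#' arm-unique key, 0 = absent).
#'
#' @param cm A `cohort_matrix` with both labels present.
#' @return List with `counts`, `fractions` (named both/case_only/
#'   control_only), `per_key` data frame and `heatmap` matrix.
#' @export
case_control_overlap <- function(cm) {
  if (length(unique(cm$labels)) < 2L) {
    stop("both case and control samples are required")
  }
  in_case <- rowSums(cm$M[, arm_cols(cm, "case"), drop = FALSE]) > 0
  in_control <- rowSums(cm$M[, arm_cols(cm, "control"), drop = FALSE]) > 0
  status <- ifelse(in_case & in_control, "both",
                   ifelse(in_case, "case_only", "control_only"))
  counts <- c(both = sum(status == "both"),
              case_only = sum(status == "case_only"),
              control_only = sum(status == "control_only"))
  heat <- cm$M * ifelse(status == "both", 2L, 1L)
  list(counts = counts, fractions = counts / nrow(cm$M),
       per_key = data.frame(key = rownames(cm$M), status = status,
                            stringsAsFactors = FALSE),
       heatmap = heat)
}

#' Sample-frequency spectrum of variant keys
#'
#' For each k in 1..n_samples, counts keys present in exactly k samples.
#' Also reports the fraction of keys at or below 10% cohort frequency.
#'
#' @param cm A `cohort_matrix`.
#' @param low_freq Frequency bound for the cumulative low-frequency
#'   fraction (default 0.10, inclusive).
#' @return List with `spectrum` (k, count, pct, cum_pct) and
#'   `low_freq_fraction`.
#' @export
frequency_spectrum <- function(cm, low_freq = 0.10) {
  n <- ncol(cm$M)
  cnt <- rowSums(cm$M)
  k <- seq_len(n)
  count <- vapply(k, function(x) sum(cnt == x), integer(1))
  pct <- 100 * count / nrow(cm$M)
  spectrum <- data.frame(k = k, count = count, pct = pct,
                         cum_pct = cumsum(pct))
  list(spectrum = spectrum,
       low_freq_fraction = sum(cnt / n <= low_freq) / nrow(cm$M))
}

#' Write the heatmap matrix with a numeric-id legend
#'
#' Rows get numeric ids; a companion legend file maps each id back to its
#' variant key, keeping the matrix axis compact.
#'
#' @param heatmap Matrix from [case_control_overlap()].
#' @param path Output path for the matrix; the legend is written next to it
#'   with suffix `.legend.tsv`.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(heatmap, path) {
  ids <- seq_len(nrow(heatmap))
  legend <- data.frame(row_id = ids, key = rownames(heatmap),
                       stringsAsFactors = FALSE)
  out <- as.data.frame(heatmap)
  out <- cbind(row_id = ids, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(legend, paste0(path, ".legend.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
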