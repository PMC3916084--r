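# End-to-end workflow: filter -> annotate -> cohort statistics -> site
# impact -> enrichment -> phylogeny, driven by a plain-text config.

#' Read a pipeline configuration
#'
#' YAML key/value file with input paths (`genome`, `transcripts`,
#' `proteins`, `sites`, `sets`, `catalog`, `idmap`, `bed`, `vcf_dir`,
#' `metadata`), parameters (`min_depth`, `min_qual`, `common_threshold`,
#' `delta`, `n_bootstrap`, `enrichment_cutoff`, `seed`) and `out_dir`.
#' Missing parameters take the package defaults.
#'
#' @param path YAML config path, or a named list (returned normalized).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(min_depth = 10, min_qual = 20, common_threshold = 0.10,
                   delta = 0L, n_bootstrap = 100L, enrichment_cutoff = 1,
                   seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "pipeline_config")
}

#' Run the full post-variant-calling workflow
#'
#' Stages: per-sample VCF parsing and filtering; codon-level annotation
#' with canonical protein mapping; cohort presence matrix with novelty,
#' frequency-class, case/control-overlap and spectrum summaries;
#' functional-site impact; annotation-set enrichment; SNV-shrunk-genome
#' alignment with a bootstrapped NJ tree. All inputs are validated before
#' any stage runs; every artifact is listed in `manifest.tsv`.
#'
#' @param config A [pipeline_config()] (or path/list coercible to one).
#' @return Invisibly, a named list of output paths plus the in-memory
#'   stage results.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  required <- c("genome", "transcripts", "proteins", "sites", "sets",
                "catalog", "idmap", "bed", "vcf_dir", "metadata", "out_dir")
  missing_keys <- required[!vapply(required, function(k)
    !is.null(cfg[[k]]), logical(1))]
  if (length(missing_keys)) {
    stop("config is missing: ", paste(missing_keys, collapse = ", "))
  }
  inputs <- c("genome", "transcripts", "proteins", "sites", "sets",
              "catalog", "idmap", "bed", "vcf_dir", "metadata")
  absent <- inputs[!file.exists(unlist(cfg[inputs]))]
  if (length(absent)) {
    stop("missing input(s): ",
         paste(sprintf("%s (%s)", absent, unlist(cfg[absent])), collapse = ", "))
  }
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  artifacts <- character(0)
  emit <- function(p) { artifacts <<- c(artifacts, p); p }

  genome <- load_fasta(cfg$genome)
  txs <- read_transcripts(cfg$transcripts)
  proteins <- read_protein_fasta(cfg$proteins)
  sites <- read_functional_sites(cfg$sites)
  sets <- read_annotation_sets(cfg$sets)
  idmap <- read_idmap(cfg$idmap)
  regions <- read_bed_regions(cfg$bed)
  catalog_df <- utils::read.delim(cfg$catalog, stringsAsFactors = FALSE)
  catalog_keys <- paste(catalog_df$chrom, catalog_df$pos, catalog_df$ref,
                        catalog_df$alt, sep = ":")
  meta <- utils::read.delim(cfg$metadata, stringsAsFactors = FALSE)
  if (!"arm" %in% names(meta)) {
    meta$arm <- vapply(meta$barcode, function(b)
      classify_arm(parse_barcode(b)$sample_type_code), character(1))
  }
  meta$accession <- assign_accessions(meta$arm)

  # --- filter ---------------------------------------------------------
  fcfg <- filter_config(cfg$min_depth, cfg$min_qual, regions)
  kept <- list()
  reports <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    vcf_path <- file.path(cfg$vcf_dir, paste0(sid, ".vcf"))
    if (!file.exists(vcf_path)) stop("no VCF for sample ", sid)
    parsed <- parse_vcf(vcf_path, sid)
    rep <- filter_snvs(parsed$snvs, fcfg)
    kept[[sid]] <- rep$kept
    reports[[sid]] <- rep
  }
  logf("filter: %d samples, %d kept / %d parsed SNVs",
       nrow(meta), sum(vapply(kept, nrow, integer(1))),
       sum(vapply(reports, function(r) nrow(r$kept) + nrow(r$rejected),
                  integer(1))))
  all_kept <- do.call(rbind, kept)
  comb <- do.call(rbind, lapply(reports, function(r) {
    k <- r$kept; j <- r$rejected
    if (nrow(k)) { k$status <- "kept"; k$reason <- "" }
    if (nrow(j)) j$status <- "rejected"
    rbind(k[, c(names(all_kept), "status", "reason"), drop = FALSE],
          j[, c(names(all_kept), "status", "reason"), drop = FALSE])
  }))
  utils::write.table(comb, emit(file.path(out, "filter_report.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- annotate -------------------------------------------------------
  annots <- annotate_snvs(genome, txs, all_kept)
  annots <- map_to_canonical(annots, idmap)
  write_annotation_table(annots, emit(file.path(out, "annotations.tsv")))
  logf("annotate: %d rows (%d missense)", nrow(annots),
       sum(annots$consequence == "missense"))

  # --- cohort ---------------------------------------------------------
  keys_by_sample <- lapply(split(all_kept, all_kept$sample_id),
                           variant_key, level = "nucleotide")
  labels <- stats::setNames(meta$arm, meta$sample_id)
  patients <- if ("patient" %in% names(meta))
    stats::setNames(meta$patient, meta$sample_id) else NULL
  cm <- build_cohort_matrix(keys_by_sample, labels, patients)
  nov <- novelty(cm, catalog_keys)
  fc <- frequency_classes(cm, cfg$common_threshold)
  spec_tab <- frequency_spectrum(cm)
  ov <- case_control_overlap(cm)
  per_key <- merge(fc, nov$per_key, by = "key")
  per_key <- merge(per_key, ov$per_key, by = "key")
  utils::write.table(per_key, emit(file.path(out, "variant_classes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(spec_tab$spectrum, emit(file.path(out, "spectrum.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_heatmap_matrix(ov$heatmap, emit(file.path(out, "heatmap.tsv")))
  logf("cohort: %d keys; known fraction (pooled) %.3f; low-freq fraction %.3f",
       nrow(cm$M), nov$pooled$fraction_known[nov$pooled$scope == "all"],
       spec_tab$low_freq_fraction)

  # --- site impact ----------------------------------------------------
  ns <- annots[!is.na(annots$aa_pos) & annots$consequence == "missense", ]
  ns$arm <- labels[ns$sample_id]
  by_arm <- do.call(rbind, lapply(c("case", "control"), function(a) {
    u <- dedupe_nssnvs(ns[ns$arm == a, , drop = FALSE])
    if (nrow(u)) u$arm <- a
    u
  }))
  impact <- site_hits(by_arm, sites, proteins)
  write_site_report(impact, emit(file.path(out, "site_impact.tsv")))
  logf("sites: %d losses", sum(impact$hits$lost))

  # --- enrichment -----------------------------------------------------
  enr <- run_enrichment(dedupe_nssnvs(ns), sets, proteins,
                        p_cutoff = cfg$enrichment_cutoff)
  write_enrichment_table(enr, emit(file.path(out, "enrichment.tsv")))
  logf("enrichment: %d sets reported", nrow(enr))

  # --- phylogeny ------------------------------------------------------
  snv_lists <- lapply(split(all_kept, all_kept$sample_id), function(d)
    d[, c("chrom", "pos", "ref", "alt")])
  aln <- build_shrunk_alignment(genome, snv_lists, delta = cfg$delta)
  write_alignment_fasta(aln, emit(file.path(out, "shrunk_alignment.fasta")))
  D <- p_distance(aln)
  write_distance_matrix(D, emit(file.path(out, "distances.tsv")))
  tree <- bootstrap_support(aln, n_reps = cfg$n_bootstrap, seed = cfg$seed)
  write_newick(tree, emit(file.path(out, "tree.nwk")))
  logf("phylogeny: %d samples, %d windows, %d bootstrap replicates",
       length(aln$samples), nrow(aln$windows), cfg$n_bootstrap)

  utils::write.table(
    data.frame(artifact = basename(artifacts), path = artifacts),
    file.path(out, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(list(paths = artifacts, filter = reports, annotations = annots,
                 cohort = cm, novelty = nov, frequency = fc,
                 spectrum = spec_tab, overlap = ov, site_impact = impact,
                 enrichment = enr, alignment = aln, tree = tree,
                 metadata = meta))
}
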