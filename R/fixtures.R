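# Deterministic synthetic-data generator: reference genome + transcript
# models + proteins + functional sites + annotation sets, and a paired
# case/control cohort with planted germline/somatic structure. Everything
# downstream is testable against the planted quantities.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specification of a synthetic case/control cohort
#'
#' Defaults mirror a 20-patient breast-cancer-style study: 55 samples (22
#' tumor cases and 33 matched-normal controls). Germline variants are
#' shared by all of a patient's samples; somatic variants are private to
#' individual case samples; a fixed fraction of all variant keys is placed
#' in the known-variant catalog.
#'
#' @param seed Integer seed; the generators draw from an explicit stream.
#' @param n_patients Number of patients (each gets at least one case and
#'   one control sample).
#' @param n_cases,n_controls Total case/control samples across patients.
#' @param n_germline_per_patient Germline SNVs per patient.
#' @param n_somatic_per_case Somatic SNVs private to each case sample.
#' @param catalog_fraction Fraction of variant keys placed in the catalog.
#' @param genome_length Reference length (single chromosome).
#' @param n_transcripts Number of transcript loci tiled onto the genome.
#' @param ptm_site_density Per-residue probability of annotating an
#'   eligible residue as a (non-sequon) PTM site.
#' @param include_failing Also emit records engineered to fail the depth,
#'   quality and region filters plus one indel per sample.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L, n_patients = 20L, n_cases = 22L,
                        n_controls = 33L, n_germline_per_patient = 50L,
                        n_somatic_per_case = 10L, catalog_fraction = 0.95,
                        genome_length = 100000L, n_transcripts = 20L,
                        ptm_site_density = 0.02, include_failing = TRUE) {
  stopifnot(n_patients >= 1L, n_cases >= n_patients, n_controls >= n_patients,
            n_germline_per_patient >= 0L, n_somatic_per_case >= 0L,
            catalog_fraction >= 0, catalog_fraction <= 1,
            ptm_site_density >= 0, ptm_site_density <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic reference: genome, transcripts, proteins, sites
#'
#' Transcript loci are tiled along one chromosome with known UTR/CDS
#' geometry (CDS starts with ATG, ends with a stop codon, no internal
#' stops), alternating strands and 1-3 exons. Protein sequences are the
#' exact CDS translations. N-linked glycosylation sites are annotated at
#' every sequon the proteins actually contain; phosphorylation,
#' acetylation, active and binding sites are placed at eligible residues.
#' Annotation sets comprise pathway-style sets that partition the proteome
#' (whole-protein footprints) plus domain-style sub-interval sets.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `reference_fixture` with `genome`, `transcripts`,
#'   `proteins`, `sites`, `sets` (data frame), `exome` (exon intervals data
#'   frame), `idmap`.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    chrom <- "chr1"
    cursor <- 1L
    segments <- character(0)
    txs <- list()
    proteins <- character(0)
    for (t in seq_len(spec$n_transcripts)) {
      spacer <- sample(50:150, 1)
      utr5 <- sample(10:60, 1)
      n_codons <- sample(30:100, 1)
      utr3 <- sample(10:40, 1)
      cds <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1))
      mrna <- paste0(rand_bases(utr5), cds, rand_bases(utr3))
      mlen <- nchar(mrna)
      n_exons <- sample(1:3, 1)
      brk <- sort(sample(seq_len(mlen - 1L), n_exons - 1L))
      exon_lens <- diff(c(0L, brk, mlen))
      intron_lens <- if (n_exons > 1L) sample(20:80, n_exons - 1L,
                                              replace = TRUE) else integer(0)
      strand <- if (t %% 2L == 0L) "-" else "+"
      # assemble the genomic (pre-mRNA) sequence in mRNA orientation
      pieces <- character(0)
      off <- 0L
      for (e in seq_len(n_exons)) {
        pieces <- c(pieces, substring(mrna, off + 1L, off + exon_lens[e]))
        off <- off + exon_lens[e]
        if (e < n_exons) pieces <- c(pieces, rand_bases(intron_lens[e]))
      }
      pre <- paste(pieces, collapse = "")
      locus_start <- cursor + spacer
      locus_end <- locus_start + nchar(pre) - 1L
      if (locus_end > spec$genome_length) {
        stop("transcripts exceed genome length; enlarge genome_length or ",
             "reduce n_transcripts")
      }
      # exon coordinates in mRNA orientation along the locus
      starts_m <- integer(n_exons); ends_m <- integer(n_exons)
      off <- locus_start
      for (e in seq_len(n_exons)) {
        starts_m[e] <- off
        ends_m[e] <- off + exon_lens[e] - 1L
        off <- ends_m[e] + 1L
        if (e < n_exons) off <- off + intron_lens[e]
      }
      if (strand == "-") {
        # genome carries the reverse complement; flip coordinates in-locus
        gseq <- revcomp(pre)
        flip <- function(x) locus_start + locus_end - x
        new_starts <- sort(flip(ends_m))
        new_ends <- sort(flip(starts_m))
        starts_g <- new_starts; ends_g <- new_ends
      } else {
        gseq <- pre
        starts_g <- starts_m; ends_g <- ends_m
      }
      segments <- c(segments, rand_bases(spacer), gseq)
      cursor <- locus_end + 1L
      tx_id <- sprintf("TX_%03d", t)
      prot_id <- sprintf("PROT_%03d", t)
      txs[[tx_id]] <- transcript_model(tx_id, chrom, strand, starts_g,
                                       ends_g, utr5, nchar(cds), prot_id)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
      proteins[[prot_id]] <- sub("\\*$", "", aa)
    }
    if (cursor <= spec$genome_length) {
      segments <- c(segments, rand_bases(spec$genome_length - cursor + 1L))
    }
    genome <- structure(stats::setNames(paste(segments, collapse = ""), chrom),
                        class = "reference_genome")

    # functional sites
    site_rows <- list()
    add_site <- function(pid, pos, type) {
      site_rows[[length(site_rows) + 1L]] <<- data.frame(
        protein_id = pid, start = pos, end = pos, site_type = type,
        evidence = "synthetic", stringsAsFactors = FALSE)
    }
    for (pid in names(proteins)) {
      pseq <- proteins[[pid]]
      ch <- strsplit(pseq, "", fixed = TRUE)[[1]]
      for (sq in find_sequons(pseq)) {
        if (sq + 2L <= nchar(pseq)) add_site(pid, sq, "N-linked-glycosylation")
      }
      elig <- which(ch %in% c("S", "T", "Y"))
      for (pos in elig[stats::runif(length(elig)) < spec$ptm_site_density]) {
        add_site(pid, pos, "phosphorylation")
      }
      ks <- which(ch == "K")
      for (pos in ks[stats::runif(length(ks)) < spec$ptm_site_density / 2]) {
        add_site(pid, pos, "acetylation")
      }
      if (stats::runif(1) < 0.3) add_site(pid, sample(nchar(pseq), 1), "active-site")
      if (stats::runif(1) < 0.3) add_site(pid, sample(nchar(pseq), 1), "binding-site")
    }
    sites <- do.call(rbind, site_rows)

    # annotation sets: pathways partition the proteome; domains are
    # sub-intervals of individual proteins
    pids <- names(proteins)
    n_pathways <- max(1L, ceiling(length(pids) / 5))
    assign_path <- rep(seq_len(n_pathways), length.out = length(pids))
    set_rows <- data.frame(
      set_name = sprintf("pathway_%02d", assign_path), protein_id = pids,
      start = 1L, end = nchar(proteins)[pids], stringsAsFactors = FALSE)
    dom_pids <- sample(pids, min(5L, length(pids)))
    dom_rows <- do.call(rbind, lapply(seq_along(dom_pids), function(i) {
      len <- nchar(proteins[[dom_pids[i]]])
      s <- sample(seq_len(max(1L, len - 10L)), 1)
      data.frame(set_name = sprintf("domain_%02d", i),
                 protein_id = dom_pids[i], start = s,
                 end = min(len, s + sample(8:20, 1)), stringsAsFactors = FALSE)
    }))
    sets <- rbind(set_rows, dom_rows)

    exome <- do.call(rbind, lapply(txs, function(tx) {
      data.frame(chrom = tx$chrom, start = tx$exon_starts,
                 end = tx$exon_ends, stringsAsFactors = FALSE)
    }))
    rownames(exome) <- NULL
    idmap <- data.frame(protein_id = pids,
                        canonical_protein_id = sprintf("UP%05d", seq_along(pids)),
                        offset = 0L, stringsAsFactors = FALSE)
    structure(list(genome = genome, transcripts = txs, proteins = proteins,
                   sites = sites, sets = sets, exome = exome, idmap = idmap),
              class = "reference_fixture")
  })
}

cds_genomic_positions <- function(tx) {
  ep <- exonic_positions(tx)
  ep[(tx$utr5_len + 1L):(tx$utr5_len + tx$cds_len)]
}

#' Generate a synthetic case/control cohort on a reference fixture
#'
#' Germline SNVs (shared by all of a patient's samples) and somatic SNVs
#' (private to individual case samples) are planted at distinct CDS
#' positions, so the case/control arm-unique fraction, catalog-known
#' fraction and frequency classes are known by construction. Depths and
#' qualities of planted records clear the default filters; when
#' `include_failing` is set, each sample also gets records sitting exactly
#' on the depth/quality boundaries, one off-target record and one indel,
#' all of which the default filters remove.
#'
#' @param spec A [cohort_spec()].
#' @param ref A `reference_fixture` from [make_reference()].
#' @return List of class `cohort_fixture`: `samples` (sample_id, barcode,
#'   patient, arm), `snvs_by_sample` (planted, filter-passing records),
#'   `raw_records` (everything written to the VCFs), `catalog` (data frame
#'   + `keys`), `planted` summary list.
#' @export
make_cohort <- function(spec, ref) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(ref, "reference_fixture"))
  with_seed(spec$seed + 1L, {
    genome <- ref$genome
    pool <- sort(unique(unlist(lapply(ref$transcripts, cds_genomic_positions))))
    exonic_all <- sort(unique(unlist(lapply(ref$transcripts, function(tx) {
      unlist(Map(seq.int, tx$exon_starts, tx$exon_ends), use.names = FALSE)
    }))))
    off_target <- setdiff(seq_len(nchar(genome[["chr1"]]) - 1L), exonic_all)
    extra_case <- spec$n_cases - spec$n_patients
    extra_control <- spec$n_controls - spec$n_patients
    cases_per_patient <- rep(1L, spec$n_patients) +
      tabulate(rep(seq_len(spec$n_patients), length.out = extra_case),
               nbins = spec$n_patients)
    controls_per_patient <- rep(1L, spec$n_patients) +
      tabulate(rep(seq_len(spec$n_patients), length.out = extra_control),
               nbins = spec$n_patients)
    need <- spec$n_patients * spec$n_germline_per_patient +
      spec$n_cases * spec$n_somatic_per_case
    if (need > length(pool)) {
      stop("not enough CDS positions (", length(pool), ") for ", need,
           " planted variants; enlarge the reference")
    }
    chosen <- sample(pool, need)
    ptr <- 0L
    take <- function(k) {
      out <- chosen[(ptr + 1L):(ptr + k)]
      ptr <<- ptr + k
      if (k == 0L) integer(0) else out
    }
    ref_base <- function(p) substring(genome[["chr1"]], p, p)
    alt_base <- function(rb) {
      vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
             character(1), USE.NAMES = FALSE)
    }
    mk_records <- function(pos) {
      if (length(pos) == 0L) {
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric(), depth = integer(),
                          stringsAsFactors = FALSE))
      }
      rb <- ref_base(pos)
      data.frame(chrom = "chr1", pos = pos, ref = rb, alt = alt_base(rb),
                 qual = round(stats::runif(length(pos), 25, 60), 1),
                 depth = sample(15:60, length(pos), replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    samples <- list()
    snvs_by_sample <- list()
    raw_records <- list()
    for (pt in seq_len(spec$n_patients)) {
      tss <- paste0(LETTERS[(pt - 1L) %/% 26L + 1L],
                    LETTERS[(pt - 1L) %% 26L + 1L])
      participant <- sprintf("%04d", 5000L + pt)
      germ <- mk_records(take(spec$n_germline_per_patient))
      n_case <- cases_per_patient[pt]
      n_control <- controls_per_patient[pt]
      for (k in seq_len(n_case + n_control)) {
        is_case <- k <= n_case
        code <- if (is_case) 1L else 11L
        vial <- LETTERS[if (is_case) k else k - n_case]
        barcode <- sprintf("TCGA-%s-%s-%02d%s-11D-%04d-01", tss, participant,
                           code, vial, pt)
        sample_id <- sprintf("%s-%s-%02d%s", tss, participant, code, vial)
        som <- if (is_case) mk_records(take(spec$n_somatic_per_case)) else
          mk_records(integer(0))
        planted <- rbind(germ, som)
        planted <- planted[order(planted$pos), , drop = FALSE]
        samples[[sample_id]] <- data.frame(
          sample_id = sample_id, barcode = barcode,
          patient = sprintf("P%02d", pt),
          arm = if (is_case) "case" else "control", stringsAsFactors = FALSE)
        snvs_by_sample[[sample_id]] <- planted
        raw <- planted
        if (spec$include_failing) {
          spare <- setdiff(pool, chosen)
          p_depth <- sample(spare, 1); p_qual <- sample(spare, 1)
          p_off <- sample(off_target, 1); p_ind <- sample(spare, 1)
          fail <- data.frame(
            chrom = "chr1",
            pos = c(p_depth, p_qual, p_off, p_ind),
            ref = c(ref_base(p_depth), ref_base(p_qual), ref_base(p_off),
                    substring(genome[["chr1"]], p_ind, p_ind + 1L)),
            alt = c(alt_base(ref_base(p_depth)), alt_base(ref_base(p_qual)),
                    alt_base(ref_base(p_off)), ref_base(p_ind)),
            qual = c(45, 20, 45, 45),
            depth = c(10L, 30L, 30L, 30L), stringsAsFactors = FALSE)
          raw <- rbind(raw, fail)
          raw <- raw[order(raw$pos), , drop = FALSE]
        }
        raw_records[[sample_id]] <- raw
      }
    }
    samples <- do.call(rbind, samples)
    rownames(samples) <- NULL
    keys <- sort(unique(unlist(lapply(snvs_by_sample, function(d) {
      paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    }))))
    n_known <- round(spec$catalog_fraction * length(keys))
    known <- sort(sample(keys, n_known))
    parts <- do.call(rbind, strsplit(known, ":", fixed = TRUE))
    catalog <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                          ref = parts[, 3], alt = parts[, 4],
                          stringsAsFactors = FALSE)
    planted <- list(
      n_keys = length(keys),
      n_germline = spec$n_patients * spec$n_germline_per_patient,
      n_somatic = spec$n_cases * spec$n_somatic_per_case,
      catalog_fraction = n_known / length(keys),
      arm_unique_fraction =
        spec$n_cases * spec$n_somatic_per_case / length(keys))
    structure(list(samples = samples, snvs_by_sample = snvs_by_sample,
                   raw_records = raw_records,
                   catalog = list(table = catalog, keys = known),
                   planted = planted),
              class = "cohort_fixture")
  })
}

#' Write one sample's records as a minimal VCF 4.2 file
#'
#' @param records Data frame with chrom, pos, ref, alt, qual, depth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d", records$chrom,
                       records$pos, records$ref, records$alt,
                       format(records$qual, trim = TRUE), records$depth), con)
  }
  invisible(path)
}

#' Write a reference + cohort fixture to a directory of standard files
#'
#' Emits genome.fasta, transcripts.tsv, proteins.fasta, sites.tsv,
#' sets.tsv, exome.bed, idmap.tsv, catalog.tsv, metadata.tsv and one VCF
#' per sample under `vcf/`.
#'
#' @param ref A `reference_fixture`.
#' @param cohort A `cohort_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(ref, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  write_fasta(ref$genome, file.path(dir, "genome.fasta"))
  write_transcripts(ref$transcripts, file.path(dir, "transcripts.tsv"))
  pset <- Biostrings::AAStringSet(ref$proteins)
  Biostrings::writeXStringSet(pset, file.path(dir, "proteins.fasta"), width = 60L)
  utils::write.table(ref$sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ref$sets, file.path(dir, "sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = ref$exome$chrom, start = ref$exome$start - 1L,
                    end = ref$exome$end)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, file.path(dir, "exome.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(ref$idmap, file.path(dir, "idmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$catalog$table, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(cohort$raw_records)) {
    write_sample_vcf(cohort$raw_records[[s]],
                     file.path(dir, "vcf", paste0(s, ".vcf")))
  }
  invisible(dir)
}
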