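# Functional-site impact: PTM/active/binding-site hits and N-linked
# glycosylation sequon (N-X-S/T, X != P) loss detection.

SITE_TYPES <- c("O-linked-glycosylation", "methylation", "acetylation",
                "N-linked-glycosylation", "phosphorylation", "ubiquitylation",
                "binding-site", "active-site", "other")

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences; nonstandard
#'   residues (U/X etc.) are tolerated with a warning.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no protein records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate protein record name(s) in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  odd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(odd)) {
    warning("nonstandard residues in: ", paste(nm[odd], collapse = ", "))
  }
  seqs
}

#' Read a functional-site table
#'
#' Tab-delimited with header protein_id, start, end, site_type, evidence.
#' Point sites have start == end.
#'
#' @param path Input path.
#' @return Data frame of sites.
#' @export
read_functional_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "site_type", "evidence")
  if (!all(need %in% names(df))) {
    stop("site table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Collapse nsSNVs to unique protein-level changes
#'
#' @param variants Data frame with protein_id, aa_pos, ref_aa, alt_aa (and
#'   optionally sample_id / arm columns).
#' @return Data frame of unique (protein_id, aa_pos, ref_aa, alt_aa) rows
#'   with a `multiplicity` column counting input occurrences.
#' @export
dedupe_nssnvs <- function(variants) {
  if (nrow(variants) == 0L) {
    return(data.frame(protein_id = character(), aa_pos = integer(),
                      ref_aa = character(), alt_aa = character(),
                      multiplicity = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(variants$protein_id, variants$aa_pos, variants$ref_aa,
               variants$alt_aa, sep = ":")
  tab <- table(key)
  first <- !duplicated(key)
  out <- variants[first, c("protein_id", "aa_pos", "ref_aa", "alt_aa"),
                  drop = FALSE]
  out$multiplicity <- as.integer(tab[key[first]])
  out <- out[order(out$protein_id, out$aa_pos, out$ref_aa, out$alt_aa), ]
  rownames(out) <- NULL
  out
}

#' Find N-linked glycosylation sequons in a protein
#'
#' Reports every start position i with residues N, X (any but proline),
#' then S or T; overlapping sequons are all reported.
#'
#' @param residues Amino-acid string.
#' @return Integer vector of sequon start positions (possibly empty).
#' @export
find_sequons <- function(residues) {
  n <- nchar(residues)
  if (n < 3L) return(integer(0))
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  i <- seq_len(n - 2L)
  i[ch[i] == "N" & ch[i + 1L] != "P" & (ch[i + 2L] %in% c("S", "T"))]
}

apply_substitution <- function(residues, pos, ref_aa, alt_aa) {
  seen <- substring(residues, pos, pos)
  if (seen != ref_aa) {
    stop(sprintf("reference mismatch at residue %d: expected %s, protein has %s",
                 pos, ref_aa, seen))
  }
  substr(residues, pos, pos) <- alt_aa
  residues
}

#' Does a substitution destroy an existing sequon?
#'
#' For each sequon whose 3-residue window covers the substituted position,
#' the motif is re-tested after the change; a sequon is lost when N-X-S/T
#' (X != P) no longer matches. A substitution up to two residues downstream
#' of the annotated N can therefore cause loss.
#'
#' @param residues Protein sequence.
#' @param pos,ref_aa,alt_aa The residue substitution.
#' @return Data frame: sequon_start, lost (logical); empty when no sequon
#'   covers `pos`.
#' @export
sequon_loss <- function(residues, pos, ref_aa, alt_aa) {
  mutated <- apply_substitution(residues, pos, ref_aa, alt_aa)
  starts <- find_sequons(residues)
  covering <- starts[starts <= pos & starts >= pos - 2L]
  if (length(covering) == 0L) {
    return(data.frame(sequon_start = integer(), lost = logical()))
  }
  still <- find_sequons(mutated)
  data.frame(sequon_start = covering, lost = !(covering %in% still))
}

#' Sequons created (not destroyed) by a substitution
#'
#' Reported separately from losses; gains never enter loss counts.
#'
#' @inheritParams sequon_loss
#' @return Integer vector of new sequon start positions.
#' @export
sequon_gain <- function(residues, pos, ref_aa, alt_aa) {
  mutated <- apply_substitution(residues, pos, ref_aa, alt_aa)
  setdiff(find_sequons(mutated), find_sequons(residues))
}

#' Map nsSNVs onto functional sites
#'
#' A variant hits a site when its residue position equals the site position
#' (or falls inside its interval). For non-motif site types any
#' substitution at the annotated residue counts as a loss. For
#' N-linked-glycosylation sites the full 3-residue sequon window starting
#' at the annotated N is evaluated with [sequon_loss()], so substitutions
#' up to two residues downstream of the N can cause loss.
#'
#' @param variants Unique protein-level changes with an `arm` column
#'   (`"case"`/`"control"`); see [dedupe_nssnvs()] — dedupe per arm before
#'   calling, or pass sample-level rows with arms attached.
#' @param sites Functional-site table ([read_functional_sites()]).
#' @param proteins Named vector of protein sequences.
#' @return List of class `site_impact_report`: `hits` data frame
#'   (protein_id, position, site_type, arm, variant fields, loss flag),
#'   `counts` (site_type x arm loss counts), `gains` data frame.
#' @export
site_hits <- function(variants, sites, proteins) {
  bad <- sites$protein_id %in% names(proteins) &
    sites$end > nchar(proteins[sites$protein_id])
  if (any(bad)) {
    stop("site position beyond protein length for rows: ",
         paste(which(bad), collapse = ", "))
  }
  if (!"arm" %in% names(variants)) {
    stop("variants need an 'arm' column (case/control)")
  }
  hit_rows <- list()
  gain_rows <- list()
  for (j in seq_len(nrow(sites))) {
    st <- sites[j, ]
    if (!st$protein_id %in% names(proteins)) next
    pseq <- proteins[[st$protein_id]]
    nlg <- st$site_type == "N-linked-glycosylation"
    win_lo <- st$start
    win_hi <- if (nlg) st$start + 2L else st$end
    if (nlg && st$start + 2L > nchar(pseq)) {
      warning("sequon window at ", st$protein_id, ":", st$start,
              " runs past the protein C-terminus; site skipped")
      next
    }
    cand <- variants[variants$protein_id == st$protein_id &
                       variants$aa_pos >= win_lo &
                       variants$aa_pos <= win_hi, , drop = FALSE]
    if (nrow(cand) == 0L) next
    for (i in seq_len(nrow(cand))) {
      v <- cand[i, ]
      lost <- if (nlg) {
        sl <- sequon_loss(pseq, v$aa_pos, v$ref_aa, v$alt_aa)
        any(sl$lost[sl$sequon_start == st$start])
      } else TRUE
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = st$protein_id, position = st$start,
        site_type = st$site_type, arm = v$arm, aa_pos = v$aa_pos,
        ref_aa = v$ref_aa, alt_aa = v$alt_aa, lost = lost,
        stringsAsFactors = FALSE)
    }
  }
  # sequon gains anywhere in annotated proteins, reported separately
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$protein_id %in% names(proteins)) next
    g <- sequon_gain(proteins[[v$protein_id]], v$aa_pos, v$ref_aa, v$alt_aa)
    if (length(g)) {
      gain_rows[[length(gain_rows) + 1L]] <- data.frame(
        protein_id = v$protein_id, sequon_start = g, arm = v$arm,
        aa_pos = v$aa_pos, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(protein_id = character(), position = integer(),
               site_type = character(), arm = character(), aa_pos = integer(),
               ref_aa = character(), alt_aa = character(), lost = logical(),
               stringsAsFactors = FALSE)
  losses <- hits[hits$lost, , drop = FALSE]
  counts <- table(factor(losses$site_type, levels = SITE_TYPES),
                  factor(losses$arm, levels = c("case", "control")))
  gains <- if (length(gain_rows)) do.call(rbind, gain_rows) else
    data.frame(protein_id = character(), sequon_start = integer(),
               arm = character(), aa_pos = integer(), stringsAsFactors = FALSE)
  structure(list(hits = hits, counts = counts, gains = gains),
            class = "site_impact_report")
}

#' @export
print.site_impact_report <- function(x, ...) {
  cat("<site_impact_report> losses by type and arm:\n")
  print(x$counts[rowSums(x$counts) > 0, , drop = FALSE])
  invisible(x)
}

#' Partition affected sites by arm
#'
#' @param report A `site_impact_report`.
#' @param site_type Optional site type to restrict to (e.g.
#'   `"N-linked-glycosylation"`).
#' @return List with `case_only`, `control_only`, `both`: data frames of
#'   (protein_id, position) pairs with site loss in only one or both arms.
#' @export
arm_unique_sites <- function(report, site_type = NULL) {
  losses <- report$hits[report$hits$lost, , drop = FALSE]
  if (!is.null(site_type)) {
    losses <- losses[losses$site_type == site_type, , drop = FALSE]
  }
  key <- paste(losses$protein_id, losses$position, sep = ":")
  in_case <- unique(key[losses$arm == "case"])
  in_control <- unique(key[losses$arm == "control"])
  pick <- function(keys) {
    i <- match(keys, key)
    data.frame(protein_id = losses$protein_id[i],
               position = losses$position[i], stringsAsFactors = FALSE)
  }
  list(case_only = pick(setdiff(in_case, in_control)),
       control_only = pick(setdiff(in_control, in_case)),
       both = pick(intersect(in_case, in_control)))
}

#' Write a site-impact report table
#'
#' Numeric row ids with protein accession, position, type and arm flags.
#'
#' @param report A `site_impact_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(report, path) {
  losses <- report$hits[report$hits$lost, , drop = FALSE]
  key <- paste(losses$protein_id, losses$position, losses$site_type, sep = ":")
  uniq <- !duplicated(key)
  out <- losses[uniq, c("protein_id", "position", "site_type"), drop = FALSE]
  ukey <- key[uniq]
  out$in_case <- as.integer(ukey %in% key[losses$arm == "case"])
  out$in_control <- as.integer(ukey %in% key[losses$arm == "control"])
  out <- cbind(row_id = seq_len(nrow(out)), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
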