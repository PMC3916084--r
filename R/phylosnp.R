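# SNV-shrunk genome phylogenetics: concatenated per-sample windows over
# the union of SNV positions, p-distances, neighbor joining, window-level
# bootstrap. Trees are ape "phylo" objects.

#' Union of SNV positions across samples
#'
#' If any sample has an SNV at a position, every sample contributes that
#' region to its shrunk genome; the union is sorted and deduplicated.
#'
#' @param snvs_by_sample Named list of data frames with chrom and pos.
#' @return Data frame (chrom, pos), sorted by chromosome then position.
#' @export
union_positions <- function(snvs_by_sample) {
  all_pos <- do.call(rbind, lapply(snvs_by_sample, function(d) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(chrom = d$chrom, pos = as.integer(d$pos),
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_pos) || nrow(all_pos) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  all_pos <- unique(all_pos)
  all_pos <- all_pos[order(all_pos$chrom, all_pos$pos), , drop = FALSE]
  rownames(all_pos) <- NULL
  all_pos
}

#' Build an SNV-shrunk genome alignment
#'
#' For each position in the union of all samples' SNV positions, each
#' sample contributes the reference window of width `2*delta + 1` centered
#' there, with that sample's own alternate alleles substituted at any of
#' its SNV positions falling inside the window. Samples with no SNV at the
#' center contribute the reference base, so the concatenated sequences
#' form an alignment of equal lengths. Windows overhanging chromosome ends
#' are N-padded.
#'
#' @param genome A `reference_genome`.
#' @param snvs_by_sample Named list of data frames with chrom, pos, ref,
#'   alt (one entry per sample).
#' @param delta Non-negative flank width (0, 1 or 2 are typical).
#' @return Object of class `shrunk_alignment`: `samples`, `seqs` (named
#'   character vector, equal lengths), `windows` (chrom, center, width).
#' @export
build_shrunk_alignment <- function(genome, snvs_by_sample, delta = 0L) {
  delta <- as.integer(delta)
  if (delta < 0L) stop("delta must be >= 0")
  samples <- names(snvs_by_sample)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("snvs_by_sample must be a named list with unique sample ids")
  }
  # validate and index each sample's alts
  alt_maps <- lapply(snvs_by_sample, function(d) {
    if (is.null(d) || nrow(d) == 0L) return(character(0))
    key <- paste(d$chrom, d$pos, sep = ":")
    dup <- duplicated(key)
    if (any(dup)) {
      clash <- key[dup][vapply(key[dup], function(k) {
        length(unique(d$alt[key == k])) > 1L
      }, logical(1))]
      if (length(clash)) {
        stop("conflicting alternate alleles for one sample at: ",
             paste(unique(clash), collapse = ", "))
      }
    }
    gref <- substring(genome[d$chrom], d$pos, d$pos)
    mism <- gref != d$ref
    if (any(mism)) {
      stop("reference mismatch at ",
           paste(key[mism], " (expected ", d$ref[mism], ", genome has ",
                 gref[mism], ")", sep = "", collapse = "; "))
    }
    stats::setNames(d$alt, key)[!dup]
  })
  centers <- union_positions(snvs_by_sample)
  width <- 2L * delta + 1L
  windows <- data.frame(chrom = centers$chrom, center = centers$pos,
                        width = rep(width, nrow(centers)),
                        stringsAsFactors = FALSE)
  seqs <- stats::setNames(rep("", length(samples)), samples)
  if (nrow(centers) > 0L) {
    ref_windows <- vapply(seq_len(nrow(centers)), function(i) {
      extract_window(genome, centers$chrom[i], centers$pos[i], delta)
    }, character(1))
    offs <- seq.int(-delta, delta)
    for (s in samples) {
      am <- alt_maps[[s]]
      sw <- ref_windows
      if (length(am)) {
        for (i in seq_len(nrow(centers))) {
          keys <- paste(centers$chrom[i], centers$pos[i] + offs, sep = ":")
          sub <- which(keys %in% names(am))
          for (k in sub) substr(sw[i], k, k) <- unname(am[keys[k]])
        }
      }
      seqs[s] <- paste(sw, collapse = "")
    }
  }
  structure(list(samples = samples, seqs = seqs, windows = windows),
            class = "shrunk_alignment")
}

#' @export
print.shrunk_alignment <- function(x, ...) {
  ncol_aln <- if (length(x$seqs)) nchar(x$seqs[[1]]) else 0L
  cat(sprintf("<shrunk_alignment> %d samples x %d columns (%d windows of width %d)\n",
              length(x$samples), ncol_aln, nrow(x$windows),
              if (nrow(x$windows)) x$windows$width[1] else 0L))
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

#' Pairwise p-distances of an alignment
#'
#' `d(i, j)` is the fraction of mismatching columns among columns where
#' neither sequence has `N`. A Jukes-Cantor correction is available via
#' `correction = "JC69"`.
#'
#' @param aln A `shrunk_alignment`, or a character matrix/named character
#'   vector of equal-length sequences.
#' @param correction `"none"` (default) or `"JC69"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(aln, correction = c("none", "JC69")) {
  correction <- match.arg(correction)
  if (inherits(aln, "shrunk_alignment")) {
    m <- alignment_matrix(aln)
    rownames(m) <- aln$samples
  } else if (is.matrix(aln)) {
    m <- aln
  } else {
    m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
  }
  n <- nrow(m)
  if (n < 2L) stop("at least 2 samples are required")
  if (ncol(m) < 1L) stop("alignment has no columns")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      if (!any(ok)) stop("no comparable columns between samples ", i, " and ", j)
      d <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (correction == "JC69") {
        if (d >= 0.75) stop("p-distance >= 0.75; JC69 correction undefined")
        d <- -0.75 * log(1 - 4 * d / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: iteratively join the pair
#' minimizing the Q-criterion, assign branch lengths by the standard
#' formulas, and reduce the matrix. Ties on Q are broken by the lowest
#' index pair; negative branch lengths are clamped to 0 with the length
#' transferred to the sister edge. Returns an unrooted tree with a basal
#' trifurcation.
#'
#' @param D Symmetric numeric distance matrix with dimnames (n >= 3).
#' @return An ape `phylo` object.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  node <- labs  # newick fragment per active cluster
  d <- unname(D)
  m <- n
  while (m > 3L) {
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { li <- 0; lj <- d[i, j] }
    if (lj < 0) { lj <- 0; li <- d[i, j] }
    new_lab <- sprintf("(%s:%.12g,%s:%.12g)", node[i], li, node[j], lj)
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    node <- c(node[others], new_lab)
    m <- m - 1L
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", node[1], la, node[2], lb,
                 node[3], lc)
  ape::read.tree(text = txt)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the canonical form is the
#' side containing the alphabetically first leaf, serialized as sorted
#' labels joined by `|`. Trivial splits (single leaf / all leaves) are
#' dropped.
#'
#' @param phy An ape `phylo` object.
#' @return Character vector of canonical bipartition strings.
#' @export
tree_bipartitions <- function(phy) {
  labs <- phy$tip.label
  anchor <- min(labs)
  pp <- ape::prop.part(phy)
  out <- vapply(pp, function(idx) {
    s <- labs[idx]
    if (!(anchor %in% s)) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
  full <- paste(sort(labs), collapse = "|")
  sizes <- lengths(strsplit(out, "|", fixed = TRUE))
  unique(out[out != full & sizes < length(labs) - 1L & sizes > 1L])
}

window_column_index <- function(aln) {
  nw <- nrow(aln$windows)
  if (nw == 0L) return(list())
  w <- aln$windows$width[1]
  lapply(seq_len(nw), function(i) seq.int((i - 1L) * w + 1L, i * w))
}

#' Neighbor-joining tree with window-level bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples the
#' delta-windows with replacement `n_reps` times; the support of an
#' internal branch is the percentage of replicate trees containing its
#' bipartition. Resampling whole windows keeps each SNV's flanking context
#' intact (with delta 0 this equals column resampling). Reproducible for a
#' given seed.
#'
#' @param aln A `shrunk_alignment` with at least 3 samples.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling stream.
#' @return An ape `phylo` with `node.label` holding supports (0-100);
#'   the basal node's label is empty.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- alignment_matrix(aln)
  rownames(m) <- aln$samples
  main <- neighbor_joining(p_distance(m))
  idx <- window_column_index(aln)
  nw <- length(idx)
  if (nw == 0L) stop("alignment has no windows")
  bips_main <- tree_bipartitions(main)
  counts <- stats::setNames(rep(0L, length(bips_main)), bips_main)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  for (rep in seq_len(n_reps)) {
    cols <- unlist(idx[sample.int(nw, nw, replace = TRUE)], use.names = FALSE)
    rep_tree <- neighbor_joining(p_distance(m[, cols, drop = FALSE]))
    hit <- bips_main %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  # attach supports to internal nodes by matching bipartitions
  labs <- main$tip.label
  anchor <- min(labs)
  pp <- ape::prop.part(main)
  node_bips <- vapply(pp, function(i2) {
    s <- labs[i2]
    if (!(anchor %in% s)) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
  main$node.label <- ifelse(node_bips %in% names(support),
                            as.character(support[node_bips]), "")
  attr(main, "bootstrap") <- data.frame(bipartition = names(support),
                                        support = unname(support),
                                        stringsAsFactors = FALSE)
  main
}

#' Bootstrap support of a given sample clade
#'
#' @param tree Result of [bootstrap_support()].
#' @param samples Character vector of sample ids forming the putative
#'   clade (bipartition side).
#' @return Support percentage, or `NA` if the bipartition is not in the
#'   tree.
#' @export
clade_support <- function(tree, samples) {
  bs <- attr(tree, "bootstrap")
  if (is.null(bs)) stop("tree has no bootstrap attribute")
  labs <- tree$tip.label
  anchor <- min(labs)
  s <- sort(samples)
  if (!(anchor %in% s)) s <- sort(setdiff(labs, s))
  key <- paste(s, collapse = "|")
  i <- match(key, bs$bipartition)
  if (is.na(i)) NA_real_ else bs$support[i]
}

#' Write a tree in Newick format
#'
#' Branch lengths are included; bootstrap supports (if computed) appear as
#' internal node labels.
#'
#' @param tree An ape `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a shrunk alignment as FASTA
#'
#' @param aln A `shrunk_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::DNAStringSet(aln$seqs)
  names(set) <- aln$samples
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a distance matrix as a tab-delimited table
#'
#' @param D Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  out <- cbind(sample = rownames(D), as.data.frame(D))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
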