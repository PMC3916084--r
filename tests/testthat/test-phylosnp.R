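# SNV-shrunk genome alignments, p-distances, NJ, bootstrap.

snv_df <- function(pos, ref, alt) {
  data.frame(chrom = rep("chr1", length(pos)), pos = as.integer(pos),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

test_that("union_positions merges, sorts and deduplicates", {
  s <- list(s1 = snv_df(3, "G", "A"), s2 = snv_df(7, "G", "T"))
  expect_equal(union_positions(s)$pos, c(3L, 7L))
  same <- list(s1 = snv_df(c(5, 2), c("A", "C"), c("T", "G")),
               s2 = snv_df(c(2, 5), c("C", "A"), c("G", "T")))
  expect_equal(union_positions(same)$pos, c(2L, 5L))
  expect_equal(nrow(union_positions(list(s1 = snv_df(integer(0),
                                                     character(0),
                                                     character(0))))), 0L)
})

test_that("shrunk alignment substitutes each sample's own alleles only", {
  g <- tiny_genome()  # chr1 = ACGTACGTAC
  s <- list(s1 = snv_df(3, "G", "A"), s2 = snv_df(7, "G", "T"),
            ref_only = snv_df(integer(0), character(0), character(0)))
  a0 <- build_shrunk_alignment(g, s, delta = 0)
  expect_equal(unname(a0$seqs[c("s1", "s2", "ref_only")]),
               c("AG", "GT", "GG"))
  a1 <- build_shrunk_alignment(g, s, delta = 1)
  expect_equal(unname(a1$seqs[c("s1", "s2")]), c("CATCGT", "CGTCTT"))
  expect_true(all(nchar(a1$seqs) == 6L))
  # ref mismatch and conflicting alts are errors
  expect_error(build_shrunk_alignment(g, list(s1 = snv_df(3, "T", "A"))),
               "reference mismatch")
  expect_error(build_shrunk_alignment(
    g, list(s1 = snv_df(c(3, 3), c("G", "G"), c("A", "T")))), "conflicting")
  # no SNVs anywhere -> empty alignment
  empty <- build_shrunk_alignment(
    g, list(s1 = snv_df(integer(0), character(0), character(0))))
  expect_equal(nrow(empty$windows), 0L)
})

test_that("alignment lengths scale exactly with delta for isolated SNVs", {
  set.seed(3)
  g <- tiny_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), 500,
                                         TRUE), collapse = "")))
  pos <- seq(20, 480, by = 20)  # pairwise separation > 2*delta
  samples <- lapply(1:4, function(i) {
    p <- sort(sample(pos, 10))
    rb <- substring(g[["chr1"]], p, p)
    snv_df(p, rb, vapply(rb, function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1)))
  })
  names(samples) <- paste0("s", 1:4)
  union_n <- nrow(union_positions(samples))
  for (delta in 0:2) {
    a <- build_shrunk_alignment(g, samples, delta)
    expect_true(all(nchar(a$seqs) == union_n * (2 * delta + 1)))
  }
})

test_that("p-distance counts mismatches and skips N columns", {
  expect_equal(p_distance(c(a = "AG", b = "GT"))["a", "b"], 1.0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0.0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # N in either sequence removes the column from the comparison
  expect_equal(p_distance(c(a = "NAAT", b = "AAAA"))["a", "b"], 1 / 3)
  expect_error(p_distance(c(a = "NN", b = "AA")), "comparable")
  D <- p_distance(c(a = "ACGT", b = "AGGT", c = "TCGA"))
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("NJ solves the three-point formulas exactly for 3 taxa", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  cd <- cophenetic(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(cd, D, tolerance = 1e-10)
})

test_that("NJ recovers the AB|CD split with exact branch lengths", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  expect_equal(cophenetic(tr)[labs, labs], D, tolerance = 1e-10)
  expect_true("A|B" %in% tree_bipartitions(tr))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
  asym <- D; asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("ultrametric pairs are joined first", {
  labs <- c("A", "B", "C", "D")
  # two clear cherries (A,B) and (C,D)
  D <- matrix(c(0, 1, 8, 8,
                1, 0, 8, 8,
                8, 8, 0, 1,
                8, 8, 1, 0), 4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  expect_true("A|B" %in% tree_bipartitions(tr))
})

test_that("NJ agrees with an independent implementation on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    g <- ape::rtree(n, rooted = FALSE, br = stats::runif, min = 0.1, max = 1)
    D <- cophenetic(g)
    mine <- neighbor_joining(D)
    apes <- ape::nj(D)
    expect_equal(phangorn::RF.dist(mine, apes), 0)
    expect_equal(phangorn::RF.dist(mine, g), 0)
  }
})

test_that("identical samples sit at distance zero as a cherry", {
  g <- tiny_genome(c(chr1 = "ACGTACGTACGTACGTACGT"))
  twin <- snv_df(c(3, 9, 15), c("G", "A", "G"), c("A", "T", "A"))
  other <- snv_df(c(5, 11), c("A", "G"), c("T", "C"))
  s <- list(t1 = twin, t2 = twin, o1 = other,
            o2 = snv_df(c(5), c("A"), c("T")))
  a <- build_shrunk_alignment(g, s, delta = 0)
  D <- p_distance(a)
  expect_equal(D["t1", "t2"], 0)
  tr <- neighbor_joining(D)
  # the t1/t2 cherry is the o1|o2 side in canonical (anchor-side) form
  expect_true("o1|o2" %in% tree_bipartitions(tr))
})

test_that("bootstrap supports are deterministic given a seed and order-invariant", {
  set.seed(44)
  g <- tiny_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                  collapse = "")))
  mk <- function(pos) {
    rb <- substring(g[["chr1"]], pos, pos)
    snv_df(pos, rb, vapply(rb, function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1)))
  }
  shared_ab <- seq(10, 200, by = 10)
  shared_cd <- seq(210, 390, by = 10)
  s <- list(a = mk(shared_ab), b = mk(c(shared_ab, 205)),
            c = mk(shared_cd), d = mk(c(shared_cd, 5)))
  a1 <- build_shrunk_alignment(g, s, delta = 0)
  t1 <- bootstrap_support(a1, n_reps = 50, seed = 9)
  t2 <- bootstrap_support(a1, n_reps = 50, seed = 9)
  expect_identical(attr(t1, "bootstrap"), attr(t2, "bootstrap"))
  expect_equal(clade_support(t1, c("a", "b")), 100)
  # reordering samples does not change supports of the same bipartition
  a2 <- build_shrunk_alignment(g, s[c("d", "b", "a", "c")], delta = 0)
  t3 <- bootstrap_support(a2, n_reps = 50, seed = 9)
  expect_equal(clade_support(t3, c("a", "b")), clade_support(t1, c("a", "b")))
})

test_that("newick and alignment files round-trip", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sum(back$edge.length), sum(tr$edge.length))

  g <- tiny_genome()
  a <- build_shrunk_alignment(g, list(s1 = snv_df(3, "G", "A"),
                                      s2 = snv_df(7, "G", "T")), delta = 1)
  fpath <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(a, fpath)
  back_aln <- Biostrings::readDNAStringSet(fpath)
  expect_equal(as.character(back_aln), a$seqs)
})
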