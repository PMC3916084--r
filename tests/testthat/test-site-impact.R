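# Functional-site mapping and sequon (N-X-S/T) loss rules.

test_that("dedupe collapses repeated protein-level changes with multiplicity", {
  v <- data.frame(protein_id = c("P1", "P1", "P1", "P1"),
                  aa_pos = c(10L, 10L, 10L, 10L),
                  ref_aa = c("N", "N", "N", "N"),
                  alt_aa = c("K", "K", "K", "S"), stringsAsFactors = FALSE)
  u <- dedupe_nssnvs(v)
  expect_equal(nrow(u), 2L)
  expect_equal(u$multiplicity[u$alt_aa == "K"], 3L)
  expect_equal(u$multiplicity[u$alt_aa == "S"], 1L)
  expect_equal(nrow(dedupe_nssnvs(v[0, ])), 0L)
})

test_that("find_sequons applies the N-X-S/T rule with X != P and overlaps", {
  expect_equal(find_sequons("MANGSK"), 3L)
  expect_equal(find_sequons("NPSA"), integer(0))
  expect_equal(find_sequons("NNSS"), c(1L, 2L))
  expect_equal(find_sequons("NN"), integer(0))
})

test_that("find_sequons matches a regular-expression oracle on random proteins", {
  set.seed(17)
  for (i in 1:500) {
    p <- random_aa_string(sample(3:60, 1))
    oracle <- as.integer(gregexpr("(?=N[^P][ST])", p, perl = TRUE)[[1]])
    oracle <- oracle[oracle > 0]
    expect_identical(find_sequons(p), oracle)
  }
})

test_that("sequon loss follows the motif: N->X and X->P lose, S->T retains", {
  p <- "MANGSK"
  expect_true(sequon_loss(p, 3L, "N", "K")$lost)
  expect_true(sequon_loss(p, 4L, "G", "P")$lost)
  expect_false(sequon_loss(p, 5L, "S", "T")$lost)
  expect_true(sequon_loss(p, 5L, "S", "A")$lost)
  # substitution outside any sequon window reports nothing
  expect_equal(nrow(sequon_loss(p, 1L, "M", "V")), 0L)
  expect_error(sequon_loss(p, 3L, "Q", "K"), "reference mismatch")
  # gains are reported separately
  expect_equal(sequon_gain("MAAGSK", 3L, "A", "N"), 3L)
  expect_equal(sequon_gain(p, 3L, "N", "K"), integer(0))
})

test_that("site hits use exact positions, and sequon windows for NLG sites", {
  proteins <- c(P1 = "MANGSKAAAA", P2 = "AAAAAAAAQA")
  sites <- data.frame(
    protein_id = c("P1", "P2"), start = c(3L, 9L), end = c(3L, 9L),
    site_type = c("N-linked-glycosylation", "active-site"),
    evidence = "syn", stringsAsFactors = FALSE)
  vars <- data.frame(
    protein_id = c("P1", "P2", "P2"), aa_pos = c(5L, 9L, 8L),
    ref_aa = c("S", "Q", "A"), alt_aa = c("A", "L", "G"),
    arm = c("case", "case", "control"), stringsAsFactors = FALSE)
  rep <- site_hits(vars, sites, proteins)
  # S->A two residues downstream of the annotated N destroys the sequon
  nlg <- rep$hits[rep$hits$site_type == "N-linked-glycosylation", ]
  expect_equal(nrow(nlg), 1L)
  expect_true(nlg$lost)
  expect_equal(nlg$position, 3L)
  # active-site hit only at the exact residue; neighbor at 8 is no hit
  act <- rep$hits[rep$hits$site_type == "active-site", ]
  expect_equal(nrow(act), 1L)
  expect_equal(act$aa_pos, 9L)
  expect_equal(unname(rep$counts["N-linked-glycosylation", "case"]), 1L)
  expect_equal(unname(rep$counts["active-site", "case"]), 1L)
  expect_equal(sum(rep$counts[, "control"]), 0L)
})

test_that("site positions beyond the protein are an annotation error", {
  proteins <- c(P1 = "MANGSK")
  sites <- data.frame(protein_id = "P1", start = 10L, end = 10L,
                      site_type = "phosphorylation", evidence = "syn",
                      stringsAsFactors = FALSE)
  vars <- data.frame(protein_id = "P1", aa_pos = 3L, ref_aa = "N",
                     alt_aa = "K", arm = "case", stringsAsFactors = FALSE)
  expect_error(site_hits(vars, sites, proteins), "beyond protein length")
})

test_that("arm partition recovers planted case-only loss sites", {
  # 60 case losses of which 5 are case-only, mirroring a small LOG census
  proteins <- stats::setNames(
    vapply(1:60, function(i) "AANGSAAAAA", character(1)),
    sprintf("P%02d", 1:60))
  sites <- data.frame(protein_id = names(proteins), start = 3L, end = 3L,
                      site_type = "N-linked-glycosylation", evidence = "syn",
                      stringsAsFactors = FALSE)
  case_vars <- data.frame(protein_id = names(proteins), aa_pos = 3L,
                          ref_aa = "N", alt_aa = "K", arm = "case",
                          stringsAsFactors = FALSE)
  control_vars <- case_vars[1:55, ]
  control_vars$arm <- "control"
  rep <- site_hits(rbind(case_vars, control_vars), sites, proteins)
  arm <- arm_unique_sites(rep, "N-linked-glycosylation")
  expect_equal(nrow(arm$case_only), 5L)
  expect_equal(nrow(arm$both), 55L)
  expect_equal(nrow(arm$control_only), 0L)
})

test_that("site-hit counts are invariant to variant input order", {
  set.seed(23)
  proteins <- c(P1 = random_aa_string(80), P2 = random_aa_string(80))
  sites <- data.frame(protein_id = c("P1", "P1", "P2"),
                      start = c(10L, 40L, 25L), end = c(10L, 40L, 25L),
                      site_type = c("phosphorylation", "acetylation",
                                    "active-site"),
                      evidence = "syn", stringsAsFactors = FALSE)
  vars <- data.frame(
    protein_id = sample(c("P1", "P2"), 30, TRUE),
    aa_pos = sample(80L, 30, TRUE), stringsAsFactors = FALSE)
  vars$ref_aa <- substring(proteins[vars$protein_id], vars$aa_pos, vars$aa_pos)
  vars$alt_aa <- "W"
  vars <- vars[vars$ref_aa != "W", ]
  vars$arm <- sample(c("case", "control"), nrow(vars), TRUE)
  r1 <- site_hits(vars, sites, proteins)
  r2 <- site_hits(vars[rev(seq_len(nrow(vars))), ], sites, proteins)
  expect_equal(r1$counts, r2$counts)
})
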