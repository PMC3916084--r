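# Cohort matrix, novelty, frequency classes, overlap and spectrum.

make_cm <- function(keysets, arms, patients = NULL) {
  labels <- stats::setNames(arms, names(keysets))
  build_cohort_matrix(keysets, labels, patients)
}

test_that("presence matrix has sorted keys and per-sample column sums", {
  cm <- make_cm(list(s1 = c("k1", "k2", "k3"), s2 = c("k2")),
                c("case", "control"))
  expect_equal(dim(cm$M), c(3L, 2L))
  expect_equal(rownames(cm$M), c("k1", "k2", "k3"))
  expect_equal(unname(colSums(cm$M)), c(3, 1))
  expect_equal(unname(cm$M["k2", ]), c(1L, 1L))
  expect_warning(make_cm(list(s1 = "k1", s2 = character(0)),
                         c("case", "control")), "no variants")
  expect_error(build_cohort_matrix(list(c("k1")), c(s1 = "case")),
               "named list")
})

test_that("novelty fractions dilute when private novel keys are pooled", {
  shared <- sprintf("g%03d", 1:90)
  keysets <- lapply(1:5, function(i) c(shared, sprintf("n%d_%02d", i, 1:10)))
  names(keysets) <- paste0("s", 1:5)
  cm <- make_cm(keysets, c("case", "case", "control", "control", "control"))
  nov <- novelty(cm, catalog = shared)
  expect_equal(nov$per_sample$fraction_known, rep(0.9, 5))
  pooled_all <- nov$pooled$fraction_known[nov$pooled$scope == "all"]
  expect_equal(pooled_all, 90 / 140)
  expect_lte(pooled_all, max(nov$per_sample$fraction_known))
  # keys present in both arms are exactly the shared catalog keys here
  shared_frac <- nov$pooled$fraction_known[nov$pooled$scope == "case_control_shared"]
  expect_equal(shared_frac, 1.0)
  # degenerate catalogs
  expect_true(all(novelty(cm, unlist(keysets))$per_sample$fraction_known == 1))
  expect_true(all(novelty(cm, character(0))$per_sample$fraction_known == 0))
})

test_that("common/rare split is strict at the 10% threshold", {
  keysets <- c(
    lapply(1:5, function(i) c("k_in5", "k_in6", "k_all")),
    lapply(6:6, function(i) c("k_in6", "k_all")),
    lapply(7:55, function(i) "k_all"))
  names(keysets) <- paste0("s", 1:55)
  cm <- make_cm(keysets, rep(c("case", "control"), length.out = 55))
  fc <- frequency_classes(cm)
  expect_equal(fc$class[fc$key == "k_in5"], "rare")     # 5/55 = 9.09%
  expect_equal(fc$class[fc$key == "k_in6"], "common")   # 6/55 = 10.9%
  expect_equal(fc$class[fc$key == "k_all"], "common")
  expect_equal(fc$frequency[fc$key == "k_in5"], 5 / 55)
  # the alternative 90% convention is reachable via the threshold argument
  fc90 <- frequency_classes(cm, common_threshold = 0.9)
  expect_equal(fc90$class[fc90$key == "k_in6"], "rare")
  expect_equal(fc90$class[fc90$key == "k_all"], "common")
})

test_that("case/control overlap recovers a planted 20% unique fraction", {
  germ <- sprintf("g%03d", 1:80)
  case_only <- sprintf("c%02d", 1:10)
  control_only <- sprintf("n%02d", 1:10)
  keysets <- list(ca1 = c(germ, case_only[1:5]), ca2 = c(germ, case_only[6:10]),
                  co1 = c(germ, control_only[1:5]),
                  co2 = c(germ, control_only[6:10]))
  cm <- make_cm(keysets, c("case", "case", "control", "control"))
  ov <- case_control_overlap(cm)
  expect_equal(sum(ov$counts), 100L)
  expect_equal(unname(ov$fractions["both"]), 0.8)
  expect_equal(unname(ov$fractions["case_only"] + ov$fractions["control_only"]),
               0.2)
  expect_equal(sum(ov$fractions), 1)
  # ternary heatmap: 2 on shared keys where present, 1 on unique, 0 absent
  expect_equal(unname(ov$heatmap["g001", "ca1"]), 2L)
  expect_equal(unname(ov$heatmap["c01", "ca1"]), 1L)
  expect_equal(unname(ov$heatmap["c01", "co1"]), 0L)
  single <- make_cm(list(s1 = "k1", s2 = "k2"), c("case", "case"))
  expect_error(case_control_overlap(single), "both case and control")
})

test_that("frequency spectrum counts keys by sample multiplicity", {
  keysets <- list(s1 = c("a", "b"), s2 = c("b", "c"), s3 = c("b"))
  cm <- make_cm(keysets, c("case", "control", "control"))
  fs <- frequency_spectrum(cm)
  expect_equal(fs$spectrum$count, c(2L, 0L, 1L))
  expect_equal(sum(fs$spectrum$count), nrow(cm$M))
  expect_equal(fs$spectrum$cum_pct[3], 100)
  # all keys private vs all universal
  priv <- make_cm(list(s1 = "a", s2 = "b"), c("case", "control"))
  expect_equal(frequency_spectrum(priv)$spectrum$count, c(2L, 0L))
  univ <- make_cm(list(s1 = "a", s2 = "a"), c("case", "control"))
  expect_equal(frequency_spectrum(univ)$spectrum$count, c(0L, 1L))
})

test_that("cohort summaries are invariant to sample order", {
  set.seed(31)
  keysets <- lapply(1:6, function(i) sample(sprintf("k%02d", 1:30),
                                            sample(5:20, 1)))
  names(keysets) <- paste0("s", 1:6)
  arms <- rep(c("case", "control"), 3)
  cm1 <- make_cm(keysets, arms)
  perm <- sample(6)
  cm2 <- make_cm(keysets[perm], arms[perm])
  catalog <- sprintf("k%02d", 1:15)
  expect_equal(novelty(cm1, catalog)$pooled, novelty(cm2, catalog)$pooled)
  expect_equal(frequency_classes(cm1), frequency_classes(cm2))
  expect_equal(case_control_overlap(cm1)$counts,
               case_control_overlap(cm2)$counts)
})
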