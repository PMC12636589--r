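test_that("hybrid calls resolve by read support with first-name tie-break", {
  call <- list(hybrid_families = "Tc1/DNA&hAT3/DNA")
  reads <- function(fams) data.frame(read_id = seq_along(fams), family = fams)
  expect_equal(
    resolve_hybrid_family(call, reads(rep(c("Tc1/DNA", "hAT3/DNA"), c(7, 3)))),
    "Tc1/DNA")
  # tie keeps the first family of the label
  expect_equal(
    resolve_hybrid_family(call, reads(rep(c("Tc1/DNA", "hAT3/DNA"), c(4, 4)))),
    "Tc1/DNA")
  # only one side supported
  expect_equal(
    resolve_hybrid_family(list(hybrid_families = "Gypsy/LTR&Copia/LTR"),
                          reads(rep("Copia/LTR", 2))),
    "Copia/LTR")
  # reads naming outside families are ignored
  expect_equal(
    resolve_hybrid_family(call, reads(c("Tc1/DNA", rep("Other/LTR", 10)))),
    "Tc1/DNA")
  expect_error(resolve_hybrid_family(list(hybrid_families = ""), reads("x")),
               "two family labels")
})

test_that("reference merging follows the 1 kb same-family chain rule", {
  # two same-family insertions 500 bp apart merge into one extent
  calls <- make_calls("chr1", c(1000, 2100), c(1600, 2900), "Gypsy27/LTR",
                      "S1", category = "reference", call_type = "presence")
  m <- merge_reference_calls(calls, max_gap = 1000)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1000L, 2900L))
  expect_equal(m$n_constituent_calls, 2L)

  # family mismatch blocks merging at any distance
  calls <- rbind(
    make_calls("chr1", 1000, 1600, "Gypsy27/LTR", "S1", "reference",
               "presence"),
    make_calls("chr1", 1700, 2000, "Copia-3/LTR", "S1", "reference",
               "presence"))
  expect_equal(nrow(merge_reference_calls(calls)), 2L)

  # chain with consecutive 950 bp gaps collapses transitively
  calls <- make_calls("chr1", c(0, 1050, 2100), c(100, 1150, 2200),
                      "Tc1-4/DNA", "S1", "reference", "presence")
  m <- merge_reference_calls(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 2200L))

  # mixed categories are an error
  bad <- rbind(make_calls("chr1", 0, 10, "a/DNA", "S1", "reference", "presence"),
               make_calls("chr1", 20, 30, "a/DNA", "S1"))
  expect_error(merge_reference_calls(bad), "reference-category")
})

test_that("non-reference clustering crosses genomes within 1 kb", {
  calls <- rbind(make_calls("chr1", 500, 510, "famA/DNA", "S1"),
                 make_calls("chr1", 1400, 1410, "famA/DNA", "S2"))
  cl <- cluster_nonreference_loci(calls)
  expect_equal(nrow(cl$loci), 1L)
  expect_equal(c(cl$loci$start, cl$loci$end), c(500L, 1410L))
  expect_equal(cl$presence[[cl$loci$locus_id]], c("S1", "S2"))

  calls$start[2] <- 1600L; calls$end[2] <- 1610L  # distance 1090 > 1000
  cl <- cluster_nonreference_loci(calls)
  expect_equal(nrow(cl$loci), 2L)
})

test_that("merging and clustering equal the transitive-closure oracle", {
  withr::local_seed(91)
  for (trial in 1:100) {
    df <- random_calls(sample(2:30, 1))
    got <- cluster_nonreference_loci(df, max_gap = 1000)$loci
    want <- oracle_cluster(df, max_gap = 1000)
    expect_equal(got[, c("chrom", "start", "end", "family",
                         "n_constituent_calls")],
                 want, ignore_attr = TRUE)
  }
})

test_that("cluster output is invariant to input row order", {
  withr::local_seed(17)
  df <- random_calls(25)
  a <- cluster_nonreference_loci(df)
  b <- cluster_nonreference_loci(df[sample.int(nrow(df)), ])
  expect_equal(a$loci, b$loci)
  expect_equal(a$presence, b$presence)
})

test_that("family classification maps classes and excludes non-TE repeats", {
  expect_equal(classify_family("AaegSat12/Satellite"), "EXCLUDED")
  expect_equal(classify_family("SimpleRep3/Simple_repeat"), "EXCLUDED")
  expect_equal(classify_family("buffer-1/buffer"), "EXCLUDED")
  expect_equal(classify_family("Tc1-4/DNA"), "DNA")
  expect_equal(classify_family("Helitron-2/RC"), "RC")
  expect_warning(cls <- classify_family("novel-rep-9/FooClass"),
                 "unrecognized")
  expect_equal(cls, "Unknown")
  # explicit map takes precedence over the suffix
  expect_equal(classify_family("mystery", class_map = c(mystery = "LINE")),
               "LINE")
  expect_error(classify_family(""), "empty family")
})

test_that("family-activity filter needs >= 2 non-ref loci with a non-singleton", {
  loci <- data.frame(
    locus_id = paste0("L", 1:6),
    family = c("one/DNA", "allsing/LTR", "allsing/LTR", "allsing/LTR",
               "good/DNA", "good/DNA"),
    category = "non_reference", stringsAsFactors = FALSE)
  k <- stats::setNames(c(5L, 1L, 1L, 1L, 2L, 1L), loci$locus_id)
  keep <- family_activity_filter(loci, k)
  # single-locus family removed even when common; all-singleton family
  # removed; family with two loci, one carried by 2 samples, kept
  expect_equal(unname(keep), c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))

  # reference loci of a failing family fall with it
  loci2 <- rbind(loci,
                 data.frame(locus_id = "L7", family = "one/DNA",
                            category = "reference"))
  k2 <- c(k, L7 = 10L)
  expect_false(family_activity_filter(loci2, k2)[7])
})

test_that("global frequency filters match the absent>=2 / carriers>=2 rules", {
  loci <- data.frame(
    locus_id = paste0("L", 1:4),
    category = c("reference", "reference", "non_reference", "non_reference"),
    stringsAsFactors = FALSE)
  k <- stats::setNames(c(121L, 120L, 1L, 2L), loci$locus_id)
  keep <- frequency_filters(loci, k, n_samples = 122)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(frequency_filters(loci, k, n_samples = 100), "exceeds")
})

test_that("length filter keeps >= 600 bp reference loci only", {
  loci <- data.frame(
    locus_id = paste0("L", 1:3),
    start = c(0L, 0L, 0L), end = c(599L, 600L, 80L),
    category = c("reference", "reference", "non_reference"),
    stringsAsFactors = FALSE)
  expect_equal(unname(length_filter(loci)), c(FALSE, TRUE, TRUE))
})

test_that("size-stratified SFS partitions reference loci at 200/600 bp", {
  loci <- data.frame(
    locus_id = paste0("L", 1:5),
    start = 0L, end = c(150L, 400L, 900L, 200L, 600L),
    category = "reference", stringsAsFactors = FALSE)
  k <- stats::setNames(c(1L, 2L, 3L, 4L, 5L), loci$locus_id)
  s <- size_stratified_sfs(loci, k, n_samples = 6)
  # [1,200), [200,600] inclusive, (600,inf)
  expect_equal(unname(s$stratum_sizes), c(1L, 3L, 1L))
  expect_equal(sum(s$stratum_sizes), nrow(loci))
  expect_equal(unname(s$lt200["1"]), 1L)
  expect_equal(unname(s$`200to600`[c("2", "4", "5")]), c(1L, 1L, 1L))
  expect_equal(unname(s$gt600["3"]), 1L)
})

test_that("curation on the planted fixture removes each locus at its stage", {
  sf <- small_fixture()
  truth <- sf$fx$truth$loci
  got <- sf$run$curation$all_loci
  expect_setequal(got$locus_id, truth$locus_id)
  m <- match(truth$locus_id, got$locus_id)
  expect_equal(got$fate[m], truth$fate)
  # every planted pathology dies at its designed stage
  expect_true(all(truth$fate[truth$planted == "non_te"] == "non_te"))
  expect_true(all(truth$fate[truth$planted == "fixed_ref"] ==
                    "reference_frequency"))
  expect_true(all(truth$fate[truth$planted == "all_but_one_ref"] ==
                    "reference_frequency"))
  expect_true(all(truth$fate[truth$planted == "singleton_nonref"] ==
                    "nonreference_singleton"))
  expect_true(all(truth$fate[truth$planted == "short_ref"] == "length"))
  expect_true(all(truth$fate[truth$planted == "merge_pair_ref"] == "survive"))
  # bookkeeping reconciles exactly
  rep <- sf$run$curation$report
  expect_equal(rep$input, rep$survivors + sum(rep$removed))
  expect_equal(rep$input, nrow(truth))
})
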