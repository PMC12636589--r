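make_freq <- function(pA, pB, countries = c("A", "B"), category = "non_reference") {
  nL <- length(pA)
  loci <- data.frame(
    locus_id = paste0("L", seq_len(nL)), chrom = "chr1",
    start = seq(1000L, by = 5000L, length.out = nL),
    end = seq(1000L, by = 5000L, length.out = nL) + 10L,
    family = "famA/DNA", te_class = "DNA", category = category,
    stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(loci, country = countries[1], k = NA_integer_, n = 10L, p = pA),
    data.frame(loci, country = countries[2], k = NA_integer_, n = 10L, p = pB),
    data.frame(loci, country = "global", k = NA_integer_, n = 20L,
               p = (pA + pB) / 2))
  class(out) <- c("frequency_table", "data.frame")
  out
}

test_that("top frequency differences rank by |dp| with positional tie-break", {
  freq <- make_freq(c(1.0, 0.2, 0.5), c(0.0, 0.2, 0.6))
  top <- top_frequency_differences(freq, c("A", "B"), n = 2)
  expect_equal(top$locus_id, c("L1", "L3"))
  expect_equal(top$abs_dp, c(1.0, 0.1))
  expect_equal(top$rank, 1:2)

  # ties resolve by (chrom, start) ascending
  freq2 <- make_freq(c(0.5, 0.5, 0.1), c(0.1, 0.1, 0.1))
  top2 <- top_frequency_differences(freq2, c("A", "B"), n = 2)
  expect_equal(top2$locus_id, c("L1", "L2"))

  expect_warning(all3 <- top_frequency_differences(freq, c("A", "B"), n = 9),
                 "exceeds")
  expect_equal(nrow(all3), 3L)
})

test_that("top-n equals a brute-force exhaustive sort on random tables", {
  withr::local_seed(71)
  for (trial in 1:20) {
    pA <- round(runif(50), 3); pB <- round(runif(50), 3)
    freq <- make_freq(pA, pB)
    top <- top_frequency_differences(freq, c("A", "B"), n = 10)
    want <- order(-abs(pA - pB), seq_along(pA))[1:10]
    expect_equal(top$locus_id, paste0("L", want))
    # permuting input rows leaves the result unchanged
    freq_perm <- freq[sample.int(nrow(freq)), ]
    class(freq_perm) <- class(freq)
    expect_equal(top_frequency_differences(freq_perm, c("A", "B"), n = 10),
                 top)
  }
})

test_that("cross-pair union deduplicates shared top loci", {
  # one locus is the top hit of both pairs
  freq3 <- make_freq(c(1.0, 0.3), c(0.0, 0.3))
  extra <- freq3[freq3$country == "B", ]
  extra$country <- "C"
  freq3 <- rbind(freq3, extra)
  class(freq3) <- c("frequency_table", "data.frame")
  scan <- differentiation_scan(freq3, n = 1,
                               categories = "non_reference")
  expect_equal(nrow(scan$pair_means), 3L)   # AB, AC, BC
  # L1 tops A-B and A-C; B-C has dp 0 everywhere so its top is L1 by
  # tie-break as well: the union has a single locus, not three
  expect_equal(nrow(scan$union_loci), 1L)
  expect_equal(scan$union_loci$locus_id, "L1")
  # grand mean = mean of per-pair top means
  expect_equal(unname(scan$grand_means["non_reference"]),
               mean(scan$pair_means$mean_abs_dp))
})

test_that("gene proximity uses the padded-span overlap rule with signed distance", {
  loci <- data.frame(locus_id = c("La", "Lb", "Lc"), chrom = "chr1",
                     start = c(5000L, 6000L, 17000L),
                     end = c(5100L, 6100L, 17050L), stringsAsFactors = FALSE)
  genes <- data.frame(id = "g1", chrom = "chr1", start = 16000L, end = 20000L,
                      stringsAsFactors = FALSE)
  hits <- gene_proximity(loci, genes, window = 10000)
  # [5000,5100) does not reach the padded span [6000,30000)
  expect_false("La" %in% hits$locus_id)
  # [6000,6100) does; gap to the gene span is 9900 (upstream)
  expect_equal(hits$signed_distance[hits$locus_id == "Lb"], -9900L)
  expect_equal(abs(hits$signed_distance[hits$locus_id == "Lb"]), 9900L)
  # overlapping the gene span itself gives distance 0
  expect_equal(hits$signed_distance[hits$locus_id == "Lc"], 0L)
})

test_that("gene proximity equals the quadratic all-pairs oracle", {
  withr::local_seed(73)
  for (trial in 1:10) {
    nl <- sample(5:40, 1); ng <- sample(2:10, 1)
    loci <- data.frame(locus_id = paste0("L", 1:nl), chrom = "chr1",
                       start = sample.int(50000L, nl), stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(10:500, nl, replace = TRUE)
    genes <- data.frame(id = paste0("g", 1:ng), chrom = "chr1",
                        start = sample.int(50000L, ng), stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(100:3000, ng, replace = TRUE)
    w <- 2000
    got <- gene_proximity(loci, genes, window = w)
    want <- expand.grid(li = 1:nl, gi = 1:ng)
    hit <- with(want, loci$end[li] > pmax(genes$start[gi] - w, 0) &
                  loci$start[li] < genes$end[gi] + w)
    want <- want[hit, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$locus_id, got$gene_id),
                    paste(loci$locus_id[want$li], genes$id[want$gi]))
  }
})

test_that("exon overlap stats classify loci and compare frequencies", {
  # loci 1-2 exonic at high frequency, 3-4 non-exonic low, 5 in a repeat
  freq <- make_freq(c(0.8, 0.7, 0.2, 0.1, 0.3), c(0.8, 0.7, 0.2, 0.1, 0.3))
  ann <- structure(list(
    genes = data.frame(id = "g1", chrom = "chr1", start = 0L, end = 50000L),
    exons = data.frame(id = c("e1", "e2"), chrom = "chr1",
                       start = c(1005L, 6009L), end = c(1020L, 6011L)),
    repeats = data.frame(chrom = "chr1", start = 21000L, end = 21011L)
  ), class = "annotation_set")
  rep_ <- exon_overlap_stats(freq, ann)
  lc <- rep_$locus_class
  expect_equal(lc$class[lc$locus_id %in% c("L1", "L2")], rep("exonic", 2))
  expect_equal(lc$class[lc$locus_id == "L5"], "nonexonic_repeat")
  expect_equal(lc$class[lc$locus_id %in% c("L3", "L4")],
               rep("nonexonic_nonrepeat", 2))
  expect_equal(unname(rep_$fractions["non_reference"]), 0.4)
  m <- rep_$means["non_reference", ]
  expect_equal(unname(m["exonic"]), 0.75)
  expect_equal(unname(m["nonexonic"]), mean(c(0.2, 0.1, 0.3)))
  expect_equal(unname(m["nonexonic_nonrepeat"]), mean(c(0.2, 0.1)))
  expect_gt(m["exonic"], m["nonexonic"])

  # 1 bp of overlap is enough to be exonic
  ann$exons <- data.frame(id = "e1", chrom = "chr1", start = 1009L,
                          end = 1010L)
  ann$repeats <- ann$repeats[0, ]
  rep2 <- exon_overlap_stats(freq, ann)
  expect_true(rep2$locus_class$exonic[rep2$locus_class$locus_id == "L1"])
})

test_that("high-frequency IR-gene scan applies containment and the 50% rule", {
  freq <- make_freq(c(12 / 24, 0.49, 0.9), c(0.2, 0.49, 0.9))
  freq$n <- 24L
  ir <- data.frame(gene_id = c("CYP1", "CYP2"), chrom = "chr1",
                   start = c(900L, 10990L), end = c(1200L, 11005L),
                   stringsAsFactors = FALSE)
  hits <- high_frequency_gene_scan(freq, ir, threshold = 0.5)
  # L1 (p = 0.5 in A) is inside CYP1: included at exactly 50%
  expect_true(all(c("L1") %in% hits$locus_id))
  expect_equal(hits$country[hits$locus_id == "L1"], "A")
  # L2 never reaches 0.5 anywhere
  expect_false("L2" %in% hits$locus_id)
  # L3 is high frequency but extends 1 bp beyond the CYP2 span
  expect_false("L3" %in% hits$locus_id)
})
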