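test_that("SNP encodings binarize genotypes and mask missing samples", {
  expect_equal(encode_snp(c(0L, 1L, 2L), "any_alt")$x, c(0L, 1L, 1L))
  expect_equal(encode_snp(c(0L, 1L, 2L), "hom_alt")$x, c(0L, 0L, 1L))
  e <- encode_snp(c(-1L, 1L), "any_alt")
  expect_equal(e$keep, c(FALSE, TRUE))
  expect_equal(e$x, 1L)
  expect_error(encode_snp(c(-1L, -1L), "any_alt"), "all samples missing")
  expect_error(encode_snp(c(0L, 3L), "any_alt"), "codes")
})

test_that("r2_binary matches hand-computed 2x2 table values", {
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  res <- r2_binary(x, y)
  expect_equal(res$r2, 0.6)
  expect_equal(res$r2, res$r^2, tolerance = 1e-12)

  expect_equal(r2_binary(x, x), list(r = 1, r2 = 1))
  expect_equal(r2_binary(x, 1 - x)$r, -1)
  expect_equal(r2_binary(x, 1 - x)$r2, 1)
  expect_true(is.na(r2_binary(x, rep(1, 8))$r))
  expect_error(r2_binary(x, y[1:4]), "length mismatch")
})

test_that("r2_binary equals the D^2/(pq(1-p)(1-q)) oracle on random pairs", {
  withr::local_seed(79)
  checked <- 0L
  while (checked < 1000L) {
    n <- sample(4:60, 1)
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (var(x) == 0 || var(y) == 0) next
    got <- r2_binary(x, y)
    expect_equal(got$r2, oracle_r2_table(x, y), tolerance = 1e-10)
    # symmetry and joint-complement invariance
    expect_equal(r2_binary(y, x)$r, got$r, tolerance = 1e-12)
    expect_equal(r2_binary(1 - x, 1 - y)$r, got$r, tolerance = 1e-12)
    checked <- checked + 1L
  }
})

ld_fixture <- function() {
  manifest <- toy_manifest(c(Colombia = 24L, USA = 8L))
  samples <- manifest$samples$sample_id
  withr::with_seed(83, {
    g <- matrix(rbinom(32 * 3, 1, 0.5), nrow = 32,
                dimnames = list(samples, NULL))
  })
  storage.mode(g) <- "integer"
  loci <- data.frame(
    locus_id = c("T1", "T2", "T3"), chrom = "chr9",
    start = c(95000L, 104000L, 500000L),
    end = c(95010L, 104010L, 500010L),
    family = "famA/DNA", te_class = "DNA", category = "non_reference",
    stringsAsFactors = FALSE)
  colnames(g) <- loci$locus_id
  gmat <- tepop:::new_genotype_matrix(g, loci)
  # SNP inside the gene; TE1/TE2 within 10 kb of the span, TE3 far away
  genes <- data.frame(gene_id = "VGSC", chrom = "chr9", start = 100000L,
                      end = 120000L, stringsAsFactors = FALSE)
  focal <- data.frame(snp_id = "V410L", chrom = "chr9", pos = 110001L,
                      gene_id = "VGSC", stringsAsFactors = FALSE)
  list(manifest = manifest, gmat = gmat, genes = genes, focal = focal,
       samples = samples)
}

test_that("LD scan takes the max over encodings and windows candidate TEs", {
  fx <- ld_fixture()
  colombia <- fx$samples[1:24]
  # SNP genotypes: hets where T1 is present, hom-alt for a subset, so the
  # two encodings disagree
  codes <- ifelse(fx$gmat$geno[colombia, "T1"] == 1L, 1L, 0L)
  # upgrade a few carriers to hom-alt so the encodings disagree while
  # any-alt still reproduces the TE vector exactly
  codes[which(codes == 1L)[1:4]] <- 2L
  all_codes <- c(codes, rep(0L, 8))
  names(all_codes) <- fx$samples
  snp_table <- structure(list(
    sites = data.frame(snp_id = "V410L", chrom = "chr9", pos = 110001L),
    geno = matrix(all_codes, nrow = 1,
                  dimnames = list("V410L", fx$samples))),
    class = "snp_genotype_table")
  pairs <- te_snp_ld_scan(fx$gmat, snp_table, fx$focal, fx$genes, fx$manifest,
                          population = "Colombia", threshold = 0.2)
  expect_true(all(pairs$locus_id %in% c("T1", "T2")))  # T3 outside window
  t1 <- pairs[pairs$locus_id == "T1", ]
  e1 <- encode_snp(codes, "any_alt"); e2 <- encode_snp(codes, "hom_alt")
  r1 <- r2_binary(fx$gmat$geno[colombia, "T1"], e1$x)
  r2 <- r2_binary(fx$gmat$geno[colombia, "T1"], e2$x)
  expect_equal(t1$r2_enc1, r1$r2)
  expect_equal(t1$r2_enc2, r2$r2)
  expect_equal(t1$r2_max, max(r1$r2, r2$r2))
  expect_equal(t1$distance_bp, 110000L - 95010L + 1L)
  expect_false(t1$negative_ld)

  # a TE identical to the any-alt vector scores r2_max = 1
  expect_equal(t1$r2_enc1, 1)

  # lowering the threshold never removes a reported pair
  lower <- te_snp_ld_scan(fx$gmat, snp_table, fx$focal, fx$genes, fx$manifest,
                          population = "Colombia", threshold = 0.05)
  expect_true(all(paste(pairs$locus_id, pairs$snp_id) %in%
                    paste(lower$locus_id, lower$snp_id)))

  # unknown focal SNP or gene warns and skips
  bad_focal <- fx$focal; bad_focal$snp_id <- "NOPE"
  expect_warning(
    none <- te_snp_ld_scan(fx$gmat, snp_table, bad_focal, fx$genes,
                           fx$manifest, population = "Colombia"),
    "absent from VCF")
  expect_equal(nrow(none), 0L)
})

test_that("missing genotypes are dropped pairwise", {
  fx <- ld_fixture()
  colombia <- fx$samples[1:24]
  codes <- fx$gmat$geno[colombia, "T1"] * 2L   # perfect hom-alt association
  codes[1:3] <- -1L
  all_codes <- c(codes, rep(0L, 8)); names(all_codes) <- fx$samples
  snp_table <- structure(list(
    sites = data.frame(snp_id = "V410L", chrom = "chr9", pos = 110001L),
    geno = matrix(all_codes, nrow = 1,
                  dimnames = list("V410L", fx$samples))),
    class = "snp_genotype_table")
  pairs <- te_snp_ld_scan(fx$gmat, snp_table, fx$focal, fx$genes, fx$manifest,
                          population = "Colombia")
  t1 <- pairs[pairs$locus_id == "T1", ]
  expect_equal(t1$n_used, 21L)
  expect_equal(t1$r2_enc2, 1)
})

test_that("negative association is flagged from the winning encoding's sign", {
  withr::local_seed(89)
  sim <- simulate_ir_scenario(150, h = 0.5, d = 0)
  manifest <- as_manifest(data.frame(sample_id = names(sim$te),
                                     country = "Colombia"))
  loci <- data.frame(locus_id = "TE1", chrom = "chr3", start = 1126910L,
                     end = 1126920L, family = "CMC-Chapev2/DNA",
                     te_class = "DNA", category = "non_reference",
                     stringsAsFactors = FALSE)
  g <- matrix(sim$te, ncol = 1, dimnames = list(names(sim$te), "TE1"))
  gmat <- tepop:::new_genotype_matrix(g, loci)
  snp_table <- structure(list(sites = sim$sites, geno = sim$geno),
                         class = "snp_genotype_table")
  genes <- data.frame(gene_id = c("VGSC", "RDL"), chrom = "chr3",
                      start = c(1000000L, 2000000L),
                      end = c(1400000L, 2100000L), stringsAsFactors = FALSE)
  focal <- data.frame(snp_id = c("V410L", "A301S"), chrom = "chr3",
                      pos = c(1050000L, 2050000L),
                      gene_id = c("VGSC", "RDL"), stringsAsFactors = FALSE)
  pairs <- te_snp_ld_scan(gmat, snp_table, focal, genes, manifest,
                          population = "Colombia")
  t1 <- pairs[pairs$snp_id == "V410L", ]
  # d = 0: TE presence is exactly the complement of hom-alt
  expect_equal(t1$r_enc2, -1)
  expect_equal(t1$r2_max, 1)
  expect_true(t1$negative_ld)
})
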