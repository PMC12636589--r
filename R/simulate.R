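#' Balding-Nichols per-country presence frequencies
#'
#' Each country's presence frequency is drawn from a Beta distribution with
#' mean `p_anc` and variance `F * p_anc * (1 - p_anc)` (shape parameters
#' `p_anc (1-F)/F` and `(1-p_anc)(1-F)/F`). `F = 0` returns `p_anc` for
#' every country; `p_anc` of 0 or 1 returns the constant with a warning.
#' Uses the current RNG state: call `set.seed()` first for reproducibility.
#'
#' @param p_anc Ancestral presence frequency in (0, 1).
#' @param F Differentiation parameter in `[0, 1)`.
#' @param n_countries Number of countries.
#' @return Numeric vector of length `n_countries`.
#' @export
sample_population_frequencies <- function(p_anc, F, n_countries) {
  stopifnot(F >= 0, F < 1, p_anc >= 0, p_anc <= 1)
  if (p_anc == 0 || p_anc == 1) {
    warning("p_anc is ", p_anc, "; returning the constant")
    return(rep(p_anc, n_countries))
  }
  if (F == 0) {
    return(rep(p_anc, n_countries))
  }
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  stats::rbeta(n_countries, a, b)
}

#' Simulate a true binary presence matrix
#'
#' Independent Bernoulli draws per sample and locus at that sample's
#' country-specific presence frequency.
#'
#' @param freqs Numeric matrix, loci x countries (colnames = country
#'   labels), of presence frequencies.
#' @param sample_sizes Named integer vector of samples per country; names
#'   must match `colnames(freqs)`.
#' @return Integer 0/1 matrix, samples x loci; rownames are
#'   `<country>_<i>`.
#' @export
simulate_presence_matrix <- function(freqs, sample_sizes) {
  stopifnot(all(names(sample_sizes) %in% colnames(freqs)))
  blocks <- lapply(names(sample_sizes), function(cc) {
    n <- sample_sizes[[cc]]
    m <- matrix(stats::rbinom(n * nrow(freqs), 1L,
                              rep(freqs[, cc], each = n)),
                nrow = n)
    rownames(m) <- sprintf("%s_%02d", cc, seq_len(n))
    m
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  out
}

#' Analytic dual-encoding r-squared for the IR haplotype scenario
#'
#' Exact enumeration of the joint distribution of one individual's two
#' independent haplotypes: a haplotype is the resistance type with
#' probability `h`; a tag SNP is alternate on resistance haplotypes and the
#' TE allele rides wild-type haplotypes, each with per-site discordance `d`.
#' Returns the population correlation between TE presence and the SNP under
#' both genotype encodings, and the max-rule summary.
#'
#' @param h Resistance haplotype frequency in `[0, 1]`.
#' @param d Per-site discordance probability in `[0, 0.5]`.
#' @return list with `r_enc1`, `r2_enc1` (any-alt), `r_enc2`, `r2_enc2`
#'   (hom-alt), `r2_max`, `winning_encoding`, `negative_ld`.
#' @export
ir_expected_r2 <- function(h, d) {
  stopifnot(h >= 0, h <= 1, d >= 0, d <= 1)
  # haplotype joint pmf over (state, snp allele a, te allele b)
  hap <- expand.grid(state = c("R", "W"), a = 0:1, b = 1:0)
  hap$p_state <- ifelse(hap$state == "R", h, 1 - h)
  p_a1 <- ifelse(hap$state == "R", 1 - d, d)
  p_b1 <- ifelse(hap$state == "R", d, 1 - d)
  hap$p <- hap$p_state * ifelse(hap$a == 1, p_a1, 1 - p_a1) *
    ifelse(hap$b == 1, p_b1, 1 - p_b1)
  # individual = two iid haplotypes
  idx <- expand.grid(i = seq_len(nrow(hap)), j = seq_len(nrow(hap)))
  p <- hap$p[idx$i] * hap$p[idx$j]
  G <- hap$a[idx$i] + hap$a[idx$j]
  T_ <- as.integer(hap$b[idx$i] | hap$b[idx$j])
  corr_bin <- function(s) {
    Es <- sum(p * s); Et <- sum(p * T_)
    vs <- Es * (1 - Es); vt <- Et * (1 - Et)
    if (vs <= 0 || vt <= 0) return(NA_real_)
    (sum(p * s * T_) - Es * Et) / sqrt(vs * vt)
  }
  r1 <- corr_bin(as.integer(G >= 1))
  r2 <- corr_bin(as.integer(G == 2))
  r2s <- c(r1^2, r2^2)
  win <- which.max(replace(r2s, is.na(r2s), -Inf))
  list(r_enc1 = r1, r2_enc1 = r1^2, r_enc2 = r2, r2_enc2 = r2^2,
       r2_max = max(r2s, na.rm = TRUE),
       winning_encoding = c("any_alt", "hom_alt")[win],
       negative_ld = c(r1, r2)[win] < 0)
}

#' Simulate the resistance-haplotype scenario
#'
#' Each individual draws two haplotypes, resistance-type with probability
#' `h`. Four linked SNPs are alternate on resistance haplotypes (each with
#' independent per-site discordance `d`), the TE allele rides wild-type
#' haplotypes (discordance `d`), and one unlinked SNP segregates at
#' frequency `q_unlinked` independently of haplotype state. Uses the
#' current RNG state.
#'
#' @param n Number of diploid individuals.
#' @param h Resistance haplotype frequency (default 0.5, an
#'   intermediate-frequency haplotype).
#' @param d Per-site discordance (default 0.02, a typical short-read
#'   genotyping error rate).
#' @param chrom Chromosome label for the emitted sites.
#' @param positions 1-based positions of the five SNPs (four linked + one
#'   unlinked).
#' @param snp_ids SNP identifiers.
#' @param sample_ids Sample identifiers (default `ind_001...`).
#' @param q_unlinked Allele frequency of the unlinked SNP.
#' @return list with `sites` (data.frame `snp_id`, `chrom`, `pos`), `geno`
#'   (integer code matrix, 5 x n, codes as in [read_snp_vcf()]), `te`
#'   (binary presence vector length n), and `expected`
#'   ([ir_expected_r2()] for the linked SNPs).
#' @export
simulate_ir_scenario <- function(n, h = 0.5, d = 0.02, chrom = "chr3",
                                 positions = c(1050000L, 1120000L, 1180000L,
                                               1230000L, 2050000L),
                                 snp_ids = c("V410L", "S723T", "I915K",
                                             "V1016I", "A301S"),
                                 sample_ids = NULL, q_unlinked = 0.3) {
  stopifnot(length(positions) == 5L, length(snp_ids) == 5L)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind_%03d", seq_len(n))
  stopifnot(length(sample_ids) == n)
  hap_state <- matrix(stats::rbinom(2L * n, 1L, h), nrow = 2L)  # 1 = resistance
  geno <- matrix(0L, nrow = 5L, ncol = n,
                 dimnames = list(snp_ids, sample_ids))
  for (s in 1:4) {
    p_alt <- ifelse(hap_state == 1L, 1 - d, d)
    alleles <- matrix(stats::rbinom(2L * n, 1L, p_alt), nrow = 2L)
    geno[s, ] <- colSums(alleles)
  }
  geno[5L, ] <- colSums(matrix(stats::rbinom(2L * n, 1L, q_unlinked),
                               nrow = 2L))
  p_te <- ifelse(hap_state == 1L, d, 1 - d)
  te_alleles <- matrix(stats::rbinom(2L * n, 1L, p_te), nrow = 2L)
  te <- as.integer(colSums(te_alleles) >= 1L)
  names(te) <- sample_ids
  list(
    sites = data.frame(snp_id = snp_ids, chrom = chrom,
                       pos = as.integer(positions), stringsAsFactors = FALSE),
    geno = geno,
    te = te,
    expected = ir_expected_r2(h, d)
  )
}

#' Write SNP genotype codes as a VCF
#'
#' Inverse of [read_snp_vcf()] for biallelic diploid sites; codes 0/1/2/-1
#' become GT `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param sites data.frame `snp_id`, `chrom`, `pos`.
#' @param geno Integer code matrix, sites x samples (colnames = sample ids).
#' @param path Output path.
#' @export
write_snp_vcf <- function(sites, geno, path) {
  stopifnot(nrow(sites) == nrow(geno))
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `-1` = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  ord <- order(sites$chrom, sites$pos)
  body <- vapply(ord, function(i) {
    paste(c(sites$chrom[i], sites$pos[i], sites$snp_id[i], "A", "T", ".",
            "PASS", ".", "GT", gt[as.character(geno[i, ])]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Default synthetic-fixture configuration
#'
#' The "paper-mini" study conditions: six countries at the real per-country
#' sample sizes (122 genomes total), ~2,000 loci, Balding-Nichols
#' differentiation F = 0.05, breakpoint jitter 400 bp (below the 1 kb merge
#' distance), 5% hybrid calls, and planted pathological loci exercising each
#' curation filter. The IR scenario plants a resistance haplotype at
#' frequency 0.5 in Colombia with the TE in negative association
#' (discordance 0.02).
#'
#' @param seed Integer seed.
#' @param ... Named overrides of any config field.
#' @return list of configuration values.
#' @export
fixture_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    countries = c(Brazil = 18L, Colombia = 24L, USA = 28L, Senegal = 20L,
                  Gabon = 13L, Kenya = 19L),
    n_ref = 420L,
    n_nonref = 1300L,
    n_fixed_ref = 30L,
    n_all_but_one_ref = 30L,
    n_short_ref = 40L,
    n_merge_pair_ref = 20L,
    n_singleton_nonref = 60L,
    n_non_te = 40L,
    F = 0.05,
    ref_anc_shape = c(2, 2),       # ancestral freq Beta for reference loci
    nonref_anc_shape = c(0.5, 2.5),  # non-reference loci are mostly rare
    jitter = 400L,
    call_len = 10L,
    hybrid_rate = 0.05,
    dup_call_rate = 0.1,
    ir = list(h = 0.5, d = 0.02, country = "Colombia", q_unlinked = 0.3)
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

te_family_pool <- function() {
  data.frame(
    family = c("Tc1-4/DNA", "hAT-7/DNA", "CMC-Chapev2/DNA", "TcMar-9/DNA",
               "Gypsy27/LTR", "Copia-3/LTR", "Pao-11/LTR",
               "R1-3/LINE", "Jockey-5/LINE", "RTE-2/LINE",
               "Feilai-1/SINE", "gecko-2/SINE",
               "Helitron-2/RC",
               "aae-rnd-1/Unknown", "aae-rnd-6/Unknown"),
    stringsAsFactors = FALSE
  )
}

non_te_family_pool <- function() {
  c("AaegSat1/Satellite", "AaegSat12/Satellite", "SimpleRep3/Simple_repeat",
    "buffer-1/buffer")
}

# first-failing-stage bookkeeping on the realized truth matrix; mirrors the
# published filtering rules directly on carrier counts.
truth_fates <- function(loci, k, n_samples, min_ref_len = 600) {
  fate <- rep("survive", nrow(loci))
  alive <- rep(TRUE, nrow(loci))
  drop <- alive & loci$te_class == "EXCLUDED"
  fate[drop] <- "non_te"; alive <- alive & !drop

  nr <- alive & loci$category == "non_reference"
  fam_n <- table(loci$family[nr])
  fam_ns <- tapply(k[nr] >= 2L, loci$family[nr], any)
  active <- names(fam_n)[as.integer(fam_n) >= 2L &
                           as.logical(fam_ns[names(fam_n)])]
  drop <- alive & !(loci$family %in% active)
  fate[drop] <- "family_activity"; alive <- alive & !drop

  drop <- alive & loci$category == "reference" & (n_samples - k) < 2L
  fate[drop] <- "reference_frequency"; alive <- alive & !drop
  drop <- alive & loci$category == "non_reference" & k < 2L
  fate[drop] <- "nonreference_singleton"; alive <- alive & !drop

  drop <- alive & loci$category == "reference" &
    (loci$end - loci$start) < min_ref_len
  fate[drop] <- "length"
  fate
}

#' Generate the full synthetic fixture
#'
#' Writes per-sample call tables, reference-TE annotation, manifest, SNP
#' VCF, GFF3 gene/exon annotation, repeat BED, IR gene/focal-SNP lists,
#' hybrid read-support table, a JSON copy of the configuration, and a
#' `truth/` directory with the ground-truth genotype matrix, per-locus
#' expected filter fate, per-country frequencies and analytic LD
#' expectations. Fully deterministic given `config$seed`.
#'
#' @param config list from [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return (invisibly) list with `dir`, `truth` (in-memory truth objects)
#'   and `paths`.
#' @export
make_fixture <- function(config = fixture_config(), out_dir) {
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "calls"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  countries <- config$countries
  manifest <- as_manifest(data.frame(
    sample_id = unlist(lapply(names(countries), function(cc)
      sprintf("%s_%02d", cc, seq_len(countries[[cc]])))),
    country = rep(names(countries), countries),
    stringsAsFactors = FALSE
  ))
  samples <- manifest$samples$sample_id
  n_samples <- length(samples)
  fams <- te_family_pool()$family

  # ---- locus design ------------------------------------------------------
  design <- rbind(
    data.frame(category = "reference", planted = "normal",
               n = config$n_ref, stringsAsFactors = FALSE),
    data.frame(category = "reference", planted = "fixed_ref",
               n = config$n_fixed_ref),
    data.frame(category = "reference", planted = "all_but_one_ref",
               n = config$n_all_but_one_ref),
    data.frame(category = "reference", planted = "short_ref",
               n = config$n_short_ref),
    data.frame(category = "reference", planted = "merge_pair_ref",
               n = config$n_merge_pair_ref),
    data.frame(category = "non_reference", planted = "normal",
               n = config$n_nonref),
    data.frame(category = "non_reference", planted = "singleton_nonref",
               n = config$n_singleton_nonref),
    data.frame(category = "non_reference", planted = "non_te",
               n = config$n_non_te)
  )
  loci <- data.frame(
    category = rep(design$category, design$n),
    planted = rep(design$planted, design$n),
    stringsAsFactors = FALSE
  )
  nL <- nrow(loci)
  loci$family <- ifelse(loci$planted == "non_te",
                        sample(non_te_family_pool(), nL, replace = TRUE),
                        sample(fams, nL, replace = TRUE))
  loci$ref_len <- ifelse(loci$planted == "short_ref",
                         sample(100:599, nL, replace = TRUE),
                         sample(600:3000, nL, replace = TRUE))
  # shuffle, then lay out on chr1/chr2 with 5 kb spacing (no accidental
  # merging: spacing minus twice the jitter stays far above the 1 kb gap)
  loci <- loci[sample.int(nL), , drop = FALSE]
  rownames(loci) <- NULL
  loci$chrom <- rep(c("chr1", "chr2"), length.out = nL)
  loci$start <- NA_integer_; loci$end <- NA_integer_
  cursor <- c(chr1 = 10000L, chr2 = 10000L)
  ann_rows <- list()
  for (i in seq_len(nL)) {
    ch <- loci$chrom[i]
    pos <- cursor[[ch]]
    if (loci$category[i] == "reference") {
      if (loci$planted[i] == "merge_pair_ref") {
        e1 <- c(pos, pos + 800L)
        e2 <- c(pos + 1100L, pos + 1800L)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          chrom = ch, start = c(e1[1L], e2[1L]), end = c(e1[2L], e2[2L]),
          family = loci$family[i], locus_idx = i, stringsAsFactors = FALSE)
        loci$start[i] <- e1[1L]; loci$end[i] <- e2[2L]
        cursor[[ch]] <- e2[2L] + 5000L
      } else {
        loci$start[i] <- pos; loci$end[i] <- pos + loci$ref_len[i]
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = loci$end[i],
          family = loci$family[i], locus_idx = i, stringsAsFactors = FALSE)
        cursor[[ch]] <- loci$end[i] + 5000L
      }
    } else {
      # template insertion point; realized extent set after jitter below
      loci$start[i] <- pos; loci$end[i] <- pos + config$call_len
      cursor[[ch]] <- pos + 5000L
    }
  }
  annotation <- do.call(rbind, ann_rows)
  annotation$te_class <- classify_family(annotation$family, warn = FALSE)
  loci$te_class <- classify_family(loci$family, warn = FALSE)

  # ---- IR scenario locus (non-reference TE inside the VGSC span) ---------
  ir <- config$ir
  ir_locus <- data.frame(
    category = "non_reference", planted = "ir_te", family = "CMC-Chapev2/DNA",
    ref_len = NA_integer_, chrom = "chr3", start = 1126910L,
    end = 1126910L + config$call_len,
    te_class = "DNA", stringsAsFactors = FALSE
  )
  loci <- rbind(loci[, names(ir_locus)], ir_locus)
  nL <- nrow(loci)

  # ---- true genotypes ----------------------------------------------------
  p_anc <- ifelse(loci$category == "reference",
                  stats::rbeta(nL, config$ref_anc_shape[1L],
                               config$ref_anc_shape[2L]),
                  stats::rbeta(nL, config$nonref_anc_shape[1L],
                               config$nonref_anc_shape[2L]))
  freqs <- t(vapply(p_anc, function(p) {
    sample_population_frequencies(p, config$F, length(countries))
  }, numeric(length(countries))))
  colnames(freqs) <- names(countries)
  geno <- simulate_presence_matrix(freqs, countries)
  geno <- geno[samples, , drop = FALSE]  # manifest order
  for (i in seq_len(nL)) {
    pl <- loci$planted[i]
    if (pl == "fixed_ref") geno[, i] <- 1L
    if (pl == "all_but_one_ref") { geno[, i] <- 1L; geno[sample.int(n_samples, 1L), i] <- 0L }
    if (pl == "singleton_nonref") { geno[, i] <- 0L; geno[sample.int(n_samples, 1L), i] <- 1L }
    if (pl == "short_ref" || pl == "merge_pair_ref" || pl == "non_te") {
      # guarantee these reach their own filter stage: polymorphic, non-rare
      k <- sample(5:(n_samples - 5L), 1L)
      geno[, i] <- 0L; geno[sample.int(n_samples, k), i] <- 1L
    }
  }

  # IR scenario genotypes: resistance haplotype only in the focal country
  ir_geno <- matrix(0L, nrow = 5L, ncol = n_samples)
  ir_te <- integer(n_samples)
  for (cc in names(countries)) {
    idx <- which(manifest$samples$country == cc)
    sim <- simulate_ir_scenario(length(idx),
                                h = if (cc == ir$country) ir$h else 0,
                                d = ir$d,
                                sample_ids = samples[idx],
                                q_unlinked = ir$q_unlinked)
    ir_geno[, idx] <- sim$geno
    ir_te[idx] <- sim$te
    ir_sites <- sim$sites  # constant site metadata, identical across calls
  }
  colnames(ir_geno) <- samples
  rownames(ir_geno) <- ir_sites$snp_id
  geno[, nL] <- ir_te

  # drop loci with zero carriers anywhere: they generate no calls and thus
  # no locus; they are not part of the fixture truth
  k_all <- colSums(geno)
  keep <- k_all > 0L | loci$category == "reference"
  # a reference locus absent from every genome also never forms
  keep <- keep & !(loci$category == "reference" & k_all == 0L)
  loci <- loci[keep, , drop = FALSE]
  geno <- geno[, keep, drop = FALSE]
  annotation <- annotation[annotation$locus_idx %in% which(keep), , drop = FALSE]
  annotation$locus_idx <- match(annotation$locus_idx, which(keep))
  rownames(loci) <- NULL
  nL <- nrow(loci)
  k_all <- colSums(geno)

  # ---- emit call tables (and realize non-reference locus extents) --------
  emitted <- emit_call_tables(geno, loci, annotation, manifest, config,
                              file.path(out_dir, "calls"))
  loci$start <- emitted$loci$start
  loci$end <- emitted$loci$end
  loci$locus_id <- make_locus_id(loci$category, loci$chrom, loci$start,
                                 loci$end, loci$family)
  colnames(geno) <- loci$locus_id

  # ---- annotations: genes/exons, repeats, IR genes, focal SNPs ----------
  nonref_idx <- which(loci$category == "non_reference" &
                        loci$planted == "normal")
  exonic_idx <- nonref_idx[seq(1L, length(nonref_idx), by = 10L)]
  genes <- data.frame(
    id = sprintf("GENE%04d", seq_along(exonic_idx)),
    chrom = loci$chrom[exonic_idx],
    start = pmax(loci$start[exonic_idx] - 500L, 0L),
    end = loci$start[exonic_idx] + 1500L,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    id = sprintf("GENE%04d.e1", seq_along(exonic_idx)),
    parent = genes$id,
    chrom = genes$chrom,
    start = pmax(loci$start[exonic_idx] - 50L, 0L),
    end = loci$start[exonic_idx] + 250L,
    stringsAsFactors = FALSE
  )
  vgsc <- data.frame(id = "VGSC", chrom = "chr3", start = 1000000L,
                     end = 1400000L, stringsAsFactors = FALSE)
  rdl <- data.frame(id = "RDL", chrom = "chr3", start = 2000000L,
                    end = 2100000L, stringsAsFactors = FALSE)
  # CYP genes spanning a few common non-reference loci, for the >=50% scan
  common <- which(loci$category == "non_reference" & k_all / n_samples >= 0.5 &
                    loci$te_class != "EXCLUDED")
  cyp_idx <- utils::head(common, 3L)
  cyps <- if (length(cyp_idx) > 0L) data.frame(
    id = sprintf("CYP9J%02d", seq_along(cyp_idx)),
    chrom = loci$chrom[cyp_idx],
    start = pmax(loci$start[cyp_idx] - 2000L, 0L),
    end = loci$end[cyp_idx] + 2000L,
    stringsAsFactors = FALSE
  ) else genes[0, ]
  all_genes <- rbind(genes, vgsc, rdl, cyps)
  write_gff3(all_genes, exons, file.path(out_dir, "annotation.gff3"))
  repeat_idx <- setdiff(nonref_idx[seq(2L, length(nonref_idx), by = 15L)],
                        exonic_idx)
  repeats <- data.frame(chrom = loci$chrom[repeat_idx],
                        start = pmax(loci$start[repeat_idx] - 100L, 0L),
                        end = loci$end[repeat_idx] + 100L,
                        stringsAsFactors = FALSE)
  write_bed3(repeats, file.path(out_dir, "repeats.bed"))
  ir_genes <- data.frame(
    gene_id = c("VGSC", "RDL", cyps$id),
    chrom = c("chr3", "chr3", cyps$chrom),
    start = c(vgsc$start, rdl$start, cyps$start),
    end = c(vgsc$end, rdl$end, cyps$end),
    label = c("voltage-gated sodium channel", "GABA receptor subunit",
              rep("cytochrome P450", nrow(cyps))),
    stringsAsFactors = FALSE
  )
  utils::write.table(ir_genes, file.path(out_dir, "ir_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  focal <- data.frame(
    snp_id = ir_sites$snp_id,
    chrom = ir_sites$chrom,
    pos = ir_sites$pos,
    gene_id = c(rep("VGSC", 4L), "RDL"),
    stringsAsFactors = FALSE
  )
  utils::write.table(focal, file.path(out_dir, "focal_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_snp_vcf(ir_sites, ir_geno, file.path(out_dir, "snps.vcf"))
  write_sample_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_reference_annotation(
    annotation[order(annotation$chrom, annotation$start), ],
    file.path(out_dir, "ref_annotation.tsv"))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- truth sidecars ----------------------------------------------------
  fate <- truth_fates(loci, k_all, n_samples)
  truth_loci <- data.frame(
    locus_id = loci$locus_id, chrom = loci$chrom, start = loci$start,
    end = loci$end, family = loci$family, te_class = loci$te_class,
    category = loci$category, planted = loci$planted,
    carrier_count = unname(k_all), fate = fate, stringsAsFactors = FALSE
  )
  utils::write.table(truth_loci, file.path(out_dir, "truth", "loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmat <- new_genotype_matrix(geno, loci[, c("locus_id", "chrom", "start",
                                             "end", "family", "te_class",
                                             "category")])
  write_genotype_matrix(gmat, file.path(out_dir, "truth", "matrix.tsv"))
  truth_freq <- locus_frequencies(gmat, manifest)
  write_frequency_table(truth_freq, file.path(out_dir, "truth",
                                              "frequencies.tsv"))
  expected_ld <- c(list(h = ir$h, d = ir$d, country = ir$country,
                        te_locus_id = loci$locus_id[loci$planted == "ir_te"],
                        tag_snp = "V410L"),
                   ir_expected_r2(ir$h, ir$d))
  jsonlite::write_json(expected_ld,
                       file.path(out_dir, "truth", "expected_ld.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    dir = out_dir,
    truth = list(loci = truth_loci, gmat = gmat, frequencies = truth_freq,
                 expected_ld = expected_ld),
    manifest = manifest
  ))
}

#' Emit per-sample call tables for a true genotype matrix
#'
#' For every carried non-reference locus, emits 1-2 presence calls with the
#' start jittered uniformly within the configured bound, injecting
#' hybrid-family names (with read-support sidecars that always resolve back
#' to the true family) at the configured rate; for every non-carried
#' reference locus, emits absence calls against its annotation entries.
#' Returns the realized locus extents (min jittered start to max jittered
#' end over each non-reference cluster), which become the ground-truth
#' coordinates.
#'
#' @param geno True 0/1 matrix, samples x loci.
#' @param loci Locus design data.frame (`category`, `chrom`, `start`, `end`,
#'   `family`).
#' @param annotation Reference annotation rows with `locus_idx` linking back
#'   to `loci`.
#' @param manifest `te_manifest`.
#' @param config list from [fixture_config()].
#' @param calls_dir Output directory for `<sample>.ref.bed` /
#'   `<sample>.nonref.bed` files; a `hybrid_support.tsv` is written next to
#'   it.
#' @return list with `loci` (realized extents) and `hybrid_support`.
#' @export
emit_call_tables <- function(geno, loci, annotation, manifest, config,
                             calls_dir) {
  dir.create(calls_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- manifest$samples$sample_id
  fams <- te_family_pool()$family
  jit <- config$jitter
  clen <- config$call_len
  nonref_rows <- list()
  support_rows <- list()
  realized <- loci
  for (i in which(loci$category == "non_reference")) {
    carriers <- samples[geno[, i] == 1L]
    if (length(carriers) == 0L) next
    n_calls <- 1L + stats::rbinom(length(carriers), 1L, config$dup_call_rate)
    cs <- rep(carriers, n_calls)
    starts <- loci$start[i] +
      as.integer(round(stats::runif(length(cs), -jit, jit)))
    hyb <- stats::runif(length(cs)) < config$hybrid_rate &
      loci$planted[i] != "non_te"
    name_fam <- rep(loci$family[i], length(cs))
    for (j in which(hyb)) {
      decoy <- sample(setdiff(fams, loci$family[i]), 1L)
      true_first <- stats::runif(1) < 0.5
      n_true <- sample(3:9, 1L)
      # decoy support: strictly fewer reads, or a tie only when the true
      # family is first in the label (ties resolve to the first name)
      n_decoy <- if (true_first) sample.int(n_true, 1L) else
        sample.int(n_true - 1L, 1L)
      name_fam[j] <- if (true_first)
        paste0(loci$family[i], "&", decoy) else
          paste0(decoy, "&", loci$family[i])
      support_rows[[length(support_rows) + 1L]] <- data.frame(
        chrom = loci$chrom[i], start = starts[j], end = starts[j] + clen,
        sample_id = cs[j],
        family = c(loci$family[i], decoy),
        n_reads = c(n_true, n_decoy), stringsAsFactors = FALSE)
    }
    nonref_rows[[length(nonref_rows) + 1L]] <- data.frame(
      chrom = loci$chrom[i], start = starts, end = starts + clen,
      name = paste(name_fam, "nonref", cs, sep = "|"),
      support = sample(4:30, length(cs), replace = TRUE),
      sample_id = cs, stringsAsFactors = FALSE)
    realized$start[i] <- min(starts)
    realized$end[i] <- max(starts) + clen
  }
  nonref <- if (length(nonref_rows) > 0L) do.call(rbind, nonref_rows) else NULL
  ref_rows <- list()
  for (i in which(loci$category == "reference")) {
    non_carriers <- samples[geno[, i] == 0L]
    if (length(non_carriers) == 0L) next
    ann <- annotation[annotation$locus_idx == i, , drop = FALSE]
    for (a in seq_len(nrow(ann))) {
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        chrom = ann$chrom[a], start = ann$start[a], end = ann$end[a],
        name = paste(ann$family[a], "refabs", non_carriers, sep = "|"),
        support = sample(4:30, length(non_carriers), replace = TRUE),
        sample_id = non_carriers, stringsAsFactors = FALSE)
    }
  }
  ref <- if (length(ref_rows) > 0L) do.call(rbind, ref_rows) else NULL
  for (s in samples) {
    write_call_rows(nonref[nonref$sample_id == s, , drop = FALSE],
                    file.path(calls_dir, paste0(s, ".nonref.bed")))
    write_call_rows(ref[ref$sample_id == s, , drop = FALSE],
                    file.path(calls_dir, paste0(s, ".ref.bed")))
  }
  support <- if (length(support_rows) > 0L) {
    do.call(rbind, support_rows)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               sample_id = character(), family = character(),
               n_reads = integer(), stringsAsFactors = FALSE)
  }
  utils::write.table(support,
                     file.path(dirname(calls_dir), "hybrid_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(loci = realized, hybrid_support = support)
}

write_call_rows <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- rows[order(rows$chrom, rows$start, rows$end, rows$name), ]
  writeLines(paste(rows$chrom, rows$start, rows$end, rows$name, 0L, "+",
                   rows$support, sep = "\t"), path)
  invisible(path)
}

write_gff3 <- function(genes, exons, path) {
  lines <- "##gff-version 3"
  g <- sprintf("%s\ttepop\tgene\t%d\t%d\t.\t+\t.\tID=%s",
               genes$chrom, genes$start + 1L, genes$end, genes$id)
  e <- sprintf("%s\ttepop\texon\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
               exons$chrom, exons$start + 1L, exons$end, exons$id,
               exons$parent)
  writeLines(c(lines, g, e), path)
  invisible(path)
}

write_bed3 <- function(df, path) {
  writeLines(paste(df$chrom, df$start, df$end, sep = "\t"), path)
  invisible(path)
}

#' Read a fixture's hybrid support table
#' @param path `hybrid_support.tsv` path.
#' @return data.frame.
#' @export
read_hybrid_support <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the curation pipeline on a fixture directory
#'
#' Convenience wrapper reading every input [make_fixture()] wrote and
#' running [curate_loci()] plus [build_genotype_matrix()].
#'
#' @param dir Fixture directory.
#' @param ... Passed to [curate_loci()].
#' @return list with `curation`, `gmat`, `manifest`, `frequencies`.
#' @export
run_fixture_pipeline <- function(dir, ...) {
  manifest <- read_sample_manifest(file.path(dir, "manifest.tsv"))
  annotation <- read_reference_annotation(file.path(dir, "ref_annotation.tsv"))
  ref_calls <- read_call_dir(file.path(dir, "calls"), "reference")
  nonref_calls <- read_call_dir(file.path(dir, "calls"), "non_reference")
  support <- read_hybrid_support(file.path(dir, "hybrid_support.tsv"))
  cur <- curate_loci(ref_calls, nonref_calls, annotation, manifest,
                     hybrid_support = support, ...)
  gmat <- build_genotype_matrix(cur, manifest)
  list(curation = cur, gmat = gmat, manifest = manifest,
       frequencies = locus_frequencies(gmat, manifest))
}
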