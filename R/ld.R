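#' Binarize diploid SNP genotype codes
#'
#' Two encodings make SNP genotypes comparable to binary TE presence calls:
#' `any_alt` treats heterozygous and homozygous-alternate genotypes as
#' "present" (codes 1 and 2 map to 1), while `hom_alt` treats only
#' homozygous-alternate genotypes as present (code 2 maps to 1, code 1 to
#' 0). Missing genotypes (code -1) are masked out for pairwise deletion.
#'
#' @param codes Integer genotype codes in `{0, 1, 2, -1}`.
#' @param mode `"any_alt"` or `"hom_alt"`.
#' @return list with `x` (binary vector over the kept samples) and `keep`
#'   (logical mask of non-missing samples).
#' @export
encode_snp <- function(codes, mode = c("any_alt", "hom_alt")) {
  mode <- match.arg(mode)
  if (!all(codes %in% c(0L, 1L, 2L, -1L))) {
    stop("genotype codes must be in {0, 1, 2, -1}")
  }
  keep <- codes != -1L
  if (!any(keep)) stop("all samples missing for SNP")
  x <- if (mode == "any_alt") as.integer(codes[keep] >= 1L)
       else as.integer(codes[keep] == 2L)
  list(x = x, keep = keep)
}

#' Signed correlation and r-squared between two binary vectors
#'
#' `r` is the Pearson correlation of the 0/1 vectors, equivalent to the
#' standard haplotype-count LD formula `D / sqrt(pq(1-p)(1-q))` on the 2x2
#' contingency table; `r2 = r^2`. Undefined (both `NA`) when either vector
#' is constant.
#'
#' @param x,y Binary vectors of equal length >= 2.
#' @return list with `r` and `r2`.
#' @export
r2_binary <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need >= 2 observations")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("vectors must be binary (0/1)")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r * r)
}

# distance from a 1-based SNP position to a 0-based half-open locus; 0 if
# the position falls inside the interval.
snp_locus_distance <- function(pos, start, end) {
  p0 <- pos - 1L
  ifelse(p0 >= start & p0 < end, 0L,
         ifelse(p0 < start, start - p0, p0 - (end - 1L)))
}

#' LD scan between TE loci and focal IR SNPs
#'
#' For each focal SNP and each TE locus within `window` bp of the SNP's gene
#' span, computes the signed correlation between the population's binary TE
#' genotypes and the SNP genotypes under both encodings ([encode_snp()]),
#' takes the larger r-squared of the two as the estimate, and reports pairs
#' exceeding `threshold`. A focal SNP may tag a multi-SNP resistance
#' haplotype; the scan needs only the tag. The sign flag marks negative
#' association (the signed r of the winning encoding is negative, i.e. the
#' TE rides the non-alternate haplotype).
#'
#' @param gmat A `te_genotype_matrix`.
#' @param snp_table A `snp_genotype_table` from [read_snp_vcf()].
#' @param focal_snps data.frame `snp_id`, `chrom`, `pos`, `gene_id`.
#' @param genes Gene data.frame (`gene_id` or `id`, `chrom`, `start`, `end`)
#'   resolving the focal SNPs' gene spans.
#' @param manifest `te_manifest`.
#' @param population Country label restricting the samples, or `NULL` for
#'   all.
#' @param window Padding around the gene span in bp (default 10000).
#' @param threshold Report pairs with `r2_max` strictly above this value
#'   (default 0.2); set to -Inf to keep everything.
#' @return data.frame of class `ld_pairs` with columns `locus_id`, `snp_id`,
#'   `population`, `distance_bp`, `r_enc1`, `r2_enc1`, `r_enc2`, `r2_enc2`,
#'   `r2_max`, `negative_ld`, `n_used`.
#' @export
te_snp_ld_scan <- function(gmat, snp_table, focal_snps, genes, manifest,
                           population = NULL, window = 10000,
                           threshold = 0.2) {
  gene_id <- if ("gene_id" %in% names(genes)) genes$gene_id else genes$id
  samples <- pop_samples(gmat, manifest, population)
  pop_label <- if (is.null(population)) "all" else population
  out <- list()
  for (i in seq_len(nrow(focal_snps))) {
    sid <- focal_snps$snp_id[i]
    srow <- match(sid, snp_table$sites$snp_id)
    if (is.na(srow)) {
      warning("focal SNP absent from VCF: ", sid)
      next
    }
    gi <- match(focal_snps$gene_id[i], gene_id)
    if (is.na(gi)) {
      warning("gene not found in annotation: ", focal_snps$gene_id[i])
      next
    }
    gs <- max(genes$start[gi] - window, 0)
    ge <- genes$end[gi] + window
    near <- which(gmat$loci$chrom == genes$chrom[gi] &
                    gmat$loci$start < ge & gmat$loci$end > gs)
    if (length(near) == 0L) next
    codes_all <- snp_table$geno[srow, ]
    missing_snp_samples <- setdiff(samples, names(codes_all))
    if (length(missing_snp_samples) > 0L) {
      stop("samples missing from VCF: ", missing_snp_samples[1L])
    }
    codes <- codes_all[samples]
    for (j in near) {
      t_all <- gmat$geno[samples, j]
      enc <- lapply(c("any_alt", "hom_alt"), function(m) {
        e <- encode_snp(codes, m)
        r2_binary(t_all[e$keep], e$x)
      })
      r2s <- c(enc[[1L]]$r2, enc[[2L]]$r2)
      if (all(is.na(r2s))) next
      r2_max <- max(r2s, na.rm = TRUE)
      win <- which.max(replace(r2s, is.na(r2s), -Inf))
      rs <- c(enc[[1L]]$r, enc[[2L]]$r)
      if (r2_max > threshold) {
        out[[length(out) + 1L]] <- data.frame(
          locus_id = gmat$loci$locus_id[j], snp_id = sid,
          population = pop_label,
          distance_bp = snp_locus_distance(snp_table$sites$pos[srow],
                                           gmat$loci$start[j],
                                           gmat$loci$end[j]),
          r_enc1 = rs[1L], r2_enc1 = r2s[1L],
          r_enc2 = rs[2L], r2_enc2 = r2s[2L],
          r2_max = r2_max, negative_ld = rs[win] < 0,
          n_used = sum(codes != -1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out) == 0L) {
    data.frame(locus_id = character(), snp_id = character(),
               population = character(), distance_bp = integer(),
               r_enc1 = numeric(), r2_enc1 = numeric(), r_enc2 = numeric(),
               r2_enc2 = numeric(), r2_max = numeric(),
               negative_ld = logical(), n_used = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  class(res) <- c("ld_pairs", "data.frame")
  res
}
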