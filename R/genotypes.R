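#' Build the binary presence/absence genotype matrix
#'
#' Entries are 1 when the insertion is present in the sample (heterozygous
#' or homozygous -- short-read TE genotyping cannot distinguish the two) and
#' 0 when homozygous absent. There is no missing state: a sample without
#' evidence for a locus is 0.
#'
#' @param curation A `te_curation` from [curate_loci()], or a list with
#'   `loci` and `presence` in the same shape.
#' @param manifest `te_manifest` defining sample order.
#' @return A `te_genotype_matrix`: list with `geno` (integer matrix, samples
#'   x loci), `loci` (locus metadata, column order) and `samples`.
#' @export
build_genotype_matrix <- function(curation, manifest) {
  loci <- curation$loci
  presence <- curation$presence
  samples <- manifest$samples$sample_id
  carriers <- unique(unlist(presence, use.names = FALSE))
  unknown <- setdiff(carriers, samples)
  if (length(unknown) > 0L) {
    stop("sample in calls but not manifest: ", unknown[1L])
  }
  g <- matrix(0L, nrow = length(samples), ncol = nrow(loci),
              dimnames = list(samples, loci$locus_id))
  for (j in seq_len(nrow(loci))) {
    g[presence[[loci$locus_id[j]]], j] <- 1L
  }
  new_genotype_matrix(g, loci)
}

#' Per-country presence frequencies
#'
#' For each locus and country, the carrier count `k`, sample size `n` and
#' presence proportion `p = k/n` (the proportion of diploid individuals
#' carrying the insertion, not an allele frequency), plus a pooled global
#' row per locus under country label `"global"`.
#'
#' @param gmat A `te_genotype_matrix`.
#' @param manifest `te_manifest`; countries with zero samples are excluded
#'   with a warning.
#' @return data.frame of class `frequency_table` with columns `locus_id`,
#'   `chrom`, `start`, `end`, `family`, `te_class`, `category`, `country`,
#'   `k`, `n`, `p`.
#' @export
locus_frequencies <- function(gmat, manifest) {
  stopifnot(inherits(gmat, "te_genotype_matrix"))
  m <- manifest$samples
  m <- m[m$sample_id %in% rownames(gmat$geno), , drop = FALSE]
  counts <- table(m$country)
  empty <- setdiff(names(manifest$counts), names(counts))
  if (length(empty) > 0L) {
    warning("countries with no samples excluded: ",
            paste(empty, collapse = ", "))
  }
  countries <- sort(names(counts))
  if ("global" %in% countries) stop("'global' is a reserved country label")
  blocks <- lapply(countries, function(cc) {
    rows <- m$sample_id[m$country == cc]
    k <- colSums(gmat$geno[rows, , drop = FALSE])
    data.frame(gmat$loci, country = cc, k = as.integer(k),
               n = length(rows), p = as.numeric(k) / length(rows),
               stringsAsFactors = FALSE)
  })
  kg <- colSums(gmat$geno)
  blocks[[length(blocks) + 1L]] <- data.frame(
    gmat$loci, country = "global", k = as.integer(kg),
    n = nrow(gmat$geno), p = as.numeric(kg) / nrow(gmat$geno),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Write a frequency table
#' @param freq A `frequency_table`.
#' @param path Output TSV path.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(as.data.frame(freq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
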