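#' Read SNP genotypes from a VCF
#'
#' Diploid genotypes are collapsed to integer codes: hom-ref `0`, het `1`,
#' hom-alt `2`, missing `-1`. Multiallelic records are rejected; downstream
#' LD encodings assume a single alternate allele.
#'
#' @param path VCF 4.x path (plain text or bgzipped).
#' @return An object of class `snp_genotype_table`: list with `sites`
#'   (data.frame `snp_id`, `chrom`, `pos` -- 1-based, VCF convention) and
#'   `geno` (integer matrix, sites x samples).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multiallelic VCF record at ", fix[grepl(",", alt), "CHROM"][1L], ":",
         fix[grepl(",", alt), "POS"][1L])
  }
  fmt <- v@gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("VCF record lacks GT in FORMAT")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out[is.na(x) | x %in% c("./.", ".")] <- -1L
    if (anyNA(out)) stop("unrecognized GT value: ", x[which(is.na(out))[1L]])
    out
  }
  geno <- apply(gt, 2L, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                         dimnames = list(NULL, colnames(gt)))
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(id) | id == "."]
  rownames(geno) <- id
  structure(
    list(sites = data.frame(snp_id = id, chrom = unname(fix[, "CHROM"]),
                            pos = as.integer(fix[, "POS"]),
                            stringsAsFactors = FALSE),
         geno = geno),
    class = "snp_genotype_table"
  )
}

#' @export
print.snp_genotype_table <- function(x, ...) {
  cat("snp_genotype_table:", nrow(x$sites), "sites x", ncol(x$geno),
      "samples\n")
  invisible(x)
}

#' Read gene/exon annotation from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. Exons without a parent gene are kept as orphans.
#'
#' @param path GFF3 path.
#' @param repeats Optional repeat-region data.frame (from
#'   [read_repeat_bed()]) folded into the returned set.
#' @return An object of class `annotation_set`: list with `genes`
#'   (data.frame `id`, `chrom`, `start`, `end`), `exons` (same columns) and
#'   `repeats` (data.frame `chrom`, `start`, `end`, possibly empty).
#' @export
read_gff <- function(path, repeats = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0L | df$start >= df$end)) {
    stop("unparseable or invalid coordinates in GFF")
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, nrow(df))
  ids[is.na(ids)] <- paste0("feat", seq_len(sum(is.na(ids))))
  df$id <- ids
  genes <- df[df$type == "gene", c("id", "chrom", "start", "end")]
  exons <- df[df$type == "exon", c("id", "chrom", "start", "end")]
  rownames(genes) <- rownames(exons) <- NULL
  if (is.null(repeats)) {
    repeats <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, exons = exons, repeats = repeats),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$repeats), "repeat regions\n")
  invisible(x)
}

#' Read repeat regions from a BED file
#'
#' @param path BED3+ path (0-based half-open, as BED).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_repeat_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
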