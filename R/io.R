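#' Read a TE call table
#'
#' Reads per-sample transposable-element calls in the package's normalized
#' BED-like dialect: tab-separated `chrom, start, end, name, score, strand`
#' with an optional 7th column of supporting read counts. The `name` field
#' encodes `family|callclass|sample`, where `callclass` is `nonref`
#' (non-reference insertion presence call), `refabs` (reference-TE absence
#' call) or `refpres` (reference-TE presence call). Hybrid non-reference
#' calls join their two candidate family labels with `&` (file order is
#' authoritative for tie-breaking at resolution time).
#'
#' All coordinates are 0-based half-open (BED convention) on disk and
#' internally.
#'
#' @param path File path.
#' @param category `"reference"` or `"non_reference"`; rows whose call class
#'   belongs to the other category raise an error.
#' @param class_map Optional named character vector mapping family labels to
#'   TE classes (see [classify_family()]).
#' @return A `data.frame` of calls with columns `chrom`, `start`, `end`,
#'   `family`, `te_class`, `category`, `call_type`, `sample_id`,
#'   `hybrid_families` (string `"A&B"` or `""`) and `support` (integer, `NA`
#'   when the column is absent).
#' @export
read_te_calls <- function(path, category = c("reference", "non_reference"),
                          class_map = NULL) {
  category <- match.arg(category)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_calls())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 6L & nf != 7L)
  if (length(bad) > 0L) {
    stop("malformed call row at line ", bad[1L], ": expected 6 or 7 fields, got ",
         nf[bad[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed coordinates at line ", bad[1L])
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop("degenerate interval (start >= end) at line ", bad[1L])
  }
  name_parts <- strsplit(vapply(fields, `[[`, "", 4L), "|", fixed = TRUE)
  bad <- which(lengths(name_parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed name field at line ", bad[1L],
         ": expected 'family|callclass|sample'")
  }
  fam_raw <- vapply(name_parts, `[[`, "", 1L)
  callclass <- vapply(name_parts, `[[`, "", 2L)
  sample_id <- vapply(name_parts, `[[`, "", 3L)
  bad <- which(!callclass %in% c("nonref", "refabs", "refpres"))
  if (length(bad) > 0L) {
    stop("unknown call class '", callclass[bad[1L]], "' at line ", bad[1L])
  }
  row_cat <- ifelse(callclass == "nonref", "non_reference", "reference")
  bad <- which(row_cat != category)
  if (length(bad) > 0L) {
    stop("call class '", callclass[bad[1L]], "' at line ", bad[1L],
         " does not match category '", category, "'")
  }
  call_type <- c(nonref = "presence", refabs = "absence",
                 refpres = "presence")[callclass]
  hybrid <- grepl("&", fam_raw, fixed = TRUE)
  if (any(hybrid & row_cat == "reference")) {
    stop("hybrid family label on a reference call at line ",
         which(hybrid & row_cat == "reference")[1L])
  }
  family <- ifelse(hybrid,
                   vapply(strsplit(fam_raw, "&", fixed = TRUE), `[[`, "", 1L),
                   fam_raw)
  support <- rep(NA_integer_, length(lines))
  has7 <- nf == 7L
  if (any(has7)) {
    support[has7] <- suppressWarnings(
      as.integer(vapply(fields[has7], `[[`, "", 7L)))
    bad <- which(has7 & (is.na(support) | support < 0L))
    if (length(bad) > 0L) {
      stop("invalid support count at line ", bad[1L])
    }
  }
  data.frame(
    chrom = chrom, start = start, end = end,
    family = family,
    te_class = classify_family(family, class_map = class_map, warn = FALSE),
    category = row_cat,
    call_type = unname(call_type),
    sample_id = sample_id,
    hybrid_families = ifelse(hybrid, fam_raw, ""),
    support = support,
    stringsAsFactors = FALSE
  )
}

empty_calls <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             family = character(), te_class = character(),
             category = character(), call_type = character(),
             sample_id = character(), hybrid_families = character(),
             support = integer(), stringsAsFactors = FALSE)
}

#' Write a TE call table in the normalized dialect
#'
#' Inverse of [read_te_calls()]; round-trips are the identity on valid call
#' tables.
#'
#' @param calls Call `data.frame` as returned by [read_te_calls()].
#' @param path Output path.
#' @export
write_te_calls <- function(calls, path) {
  stopifnot(all(calls$start < calls$end))
  callclass <- ifelse(calls$category == "non_reference", "nonref",
                      ifelse(calls$call_type == "absence", "refabs", "refpres"))
  fam <- ifelse(nzchar(calls$hybrid_families), calls$hybrid_families,
                calls$family)
  name <- paste(fam, callclass, calls$sample_id, sep = "|")
  has_support <- !is.na(calls$support)
  base_cols <- paste(calls$chrom, calls$start, calls$end, name, 0L, "+",
                     sep = "\t")
  out <- ifelse(has_support, paste(base_cols, calls$support, sep = "\t"),
                base_cols)
  writeLines(out, path)
  invisible(path)
}

#' Read all call files in a directory
#'
#' @param dir Directory containing call files.
#' @param category Passed to [read_te_calls()].
#' @param pattern Filename regex (default selects `*.ref.bed` or
#'   `*.nonref.bed` by category).
#' @inheritParams read_te_calls
#' @return A single combined call `data.frame`.
#' @export
read_call_dir <- function(dir, category = c("reference", "non_reference"),
                          pattern = NULL, class_map = NULL) {
  category <- match.arg(category)
  if (is.null(pattern)) {
    pattern <- if (category == "reference") "\\.ref\\.bed$" else "\\.nonref\\.bed$"
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    return(empty_calls())
  }
  do.call(rbind, lapply(files, read_te_calls, category = category,
                        class_map = class_map))
}

#' Read a sample manifest
#'
#' A manifest maps each sequenced sample to its country of origin; per-country
#' sample sizes are the denominators for all carrier-proportion statistics.
#'
#' @param path TSV with header columns `sample_id` and `country`.
#' @return An object of class `te_manifest`: list with `samples`
#'   (data.frame `sample_id`, `country`) and `counts` (named integer vector
#'   of per-country sample sizes).
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "country") %in% names(df))) {
    stop("manifest must have columns 'sample_id' and 'country'")
  }
  as_manifest(df[, c("sample_id", "country")])
}

#' Build a manifest from a data frame
#'
#' @param df data.frame with columns `sample_id`, `country`.
#' @return A `te_manifest` object.
#' @export
as_manifest <- function(df) {
  if (nrow(df) == 0L) stop("no samples in manifest")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in manifest: ", dup[1L])
  }
  counts <- table(df$country)
  structure(
    list(samples = df,
         counts = stats::setNames(as.integer(counts), names(counts))),
    class = "te_manifest"
  )
}

#' @export
print.te_manifest <- function(x, ...) {
  cat("te_manifest:", nrow(x$samples), "samples,",
      length(x$counts), "countries\n")
  print(x$counts)
  invisible(x)
}

#' Write a manifest
#' @param manifest A `te_manifest`.
#' @param path Output TSV path.
#' @export
write_sample_manifest <- function(manifest, path) {
  utils::write.table(manifest$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference-TE annotation table
#'
#' RepeatMasker-style intervals with family labels, normalized to a TSV with
#' header `chrom, start, end, family, te_class` in 0-based half-open
#' coordinates.
#'
#' @param path TSV path.
#' @return data.frame with those columns plus `length = end - start`.
#' @export
read_reference_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "family", "te_class")
  if (!all(need %in% names(df))) {
    stop("reference annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("invalid interval in reference annotation")
  df$length <- df$end - df$start
  df
}

#' Write a reference-TE annotation table
#' @param annot data.frame as from [read_reference_annotation()].
#' @param path Output TSV path.
#' @export
write_reference_annotation <- function(annot, path) {
  utils::write.table(annot[, c("chrom", "start", "end", "family", "te_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binary genotype matrix
#'
#' On-disk layout: one row per locus with metadata columns (`locus_id`,
#' `chrom`, `start`, `end`, `family`, `te_class`, `category`) followed by one
#' 0/1 column per sample. Write then read is the identity.
#'
#' @param gmat A `te_genotype_matrix` (see [build_genotype_matrix()]).
#' @param path Output TSV path.
#' @export
write_genotype_matrix <- function(gmat, path) {
  stopifnot(inherits(gmat, "te_genotype_matrix"))
  g <- gmat$geno
  if (!all(g %in% c(0L, 1L))) stop("genotype entries must be 0 or 1")
  meta <- gmat$loci[, c("locus_id", "chrom", "start", "end", "family",
                        "te_class", "category")]
  out <- cbind(meta, as.data.frame(t(g), optional = TRUE))
  names(out) <- c(names(meta), rownames(g))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary genotype matrix
#'
#' @param path TSV written by [write_genotype_matrix()].
#' @return A `te_genotype_matrix`.
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("locus_id", "chrom", "start", "end", "family", "te_class",
                 "category")
  if (!all(meta_cols %in% names(df))) {
    stop("genotype matrix file lacks locus metadata columns")
  }
  sample_cols <- setdiff(names(df), meta_cols)
  if (nrow(df) == 0L) {
    g <- matrix(integer(), nrow = length(sample_cols), ncol = 0L,
                dimnames = list(sample_cols, character()))
    return(new_genotype_matrix(g, df[, meta_cols]))
  }
  g <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  storage.mode(g) <- "integer"
  if (!all(g %in% c(0L, 1L))) stop("genotype entries must be 0 or 1")
  colnames(g) <- df$locus_id
  rownames(g) <- sample_cols
  new_genotype_matrix(g, df[, meta_cols])
}

new_genotype_matrix <- function(geno, loci) {
  stopifnot(ncol(geno) == nrow(loci))
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci,
                 samples = rownames(geno)),
            class = "te_genotype_matrix")
}

#' @export
print.te_genotype_matrix <- function(x, ...) {
  cat("te_genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "loci\n")
  tab <- table(x$loci$category)
  cat(paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a focal-SNP or IR-gene list
#'
#' Focal SNPs: TSV with header `snp_id, chrom, pos, gene_id` (`pos` 1-based,
#' VCF convention). IR genes: TSV with header
#' `gene_id, chrom, start, end, label` (0-based half-open).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_focal_snps <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "gene_id")
  if (!all(need %in% names(df))) {
    stop("focal SNP list must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_focal_snps
#' @export
read_ir_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("IR gene list must have columns: ", paste(need, collapse = ", "))
  }
  df
}
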