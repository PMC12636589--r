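#' Top absolute frequency differences between two countries
#'
#' Ranks loci by `|pA - pB|` descending (ties broken by `(chrom, start)`
#' ascending) and returns the top `n`, flagging candidates for spatially
#' varying selection.
#'
#' @param freq A `frequency_table` from [locus_frequencies()].
#' @param pair Character vector of two country labels.
#' @param n Number of loci to report (default 10); if larger than the locus
#'   count, all loci are returned with a warning.
#' @return data.frame with `rank`, `locus_id`, `chrom`, `start`, `end`,
#'   `family`, `te_class`, `category`, `pA`, `pB`, `abs_dp`.
#' @export
top_frequency_differences <- function(freq, pair, n = 10) {
  stopifnot(length(pair) == 2L)
  fa <- freq[freq$country == pair[1L], ]
  fb <- freq[freq$country == pair[2L], ]
  if (nrow(fa) == 0L || nrow(fb) == 0L) {
    stop("pair countries not present in frequency table")
  }
  fb <- fb[match(fa$locus_id, fb$locus_id), ]
  if (anyNA(fb$locus_id)) stop("frequency table incomplete for pair")
  df <- data.frame(
    locus_id = fa$locus_id, chrom = fa$chrom, start = fa$start, end = fa$end,
    family = fa$family, te_class = fa$te_class, category = fa$category,
    pA = fa$p, pB = fb$p, abs_dp = abs(fa$p - fb$p),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$abs_dp, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  if (n > nrow(df)) {
    warning("n = ", n, " exceeds locus count ", nrow(df), "; returning all")
    n <- nrow(df)
  }
  out <- df[seq_len(n), , drop = FALSE]
  out <- cbind(rank = seq_len(n), out)
  rownames(out) <- NULL
  out
}

#' Differentiation scan over all country pairs
#'
#' Runs [top_frequency_differences()] for every country pair, deduplicates
#' the cross-pair union of top loci (a locus highly differentiated in
#' several pairs is counted once), and reports the mean top-`n` `|dp|` per
#' pair plus the grand mean across pairs, separately per locus category.
#'
#' @param freq A `frequency_table`.
#' @param n Top loci per pair (default 10).
#' @param categories Locus categories to scan (default both).
#' @return An object of class `diff_scan`: list with `per_pair` (data.frame
#'   long over pairs and categories), `union_loci` (deduplicated data.frame),
#'   `pair_means` and `grand_means` (named by category).
#' @export
differentiation_scan <- function(freq, n = 10,
                                 categories = c("reference", "non_reference")) {
  countries <- setdiff(sort(unique(freq$country)), "global")
  if (length(countries) < 2L) stop("need >= 2 countries")
  pairs <- utils::combn(countries, 2L)
  per_pair <- list(); pm <- list()
  for (cat_i in categories) {
    fsub <- freq[freq$category == cat_i, , drop = FALSE]
    if (nrow(fsub) == 0L) next
    for (i in seq_len(ncol(pairs))) {
      top <- top_frequency_differences(fsub, pairs[, i], n = n)
      top$popA <- pairs[1L, i]; top$popB <- pairs[2L, i]
      per_pair[[length(per_pair) + 1L]] <- top
      pm[[length(pm) + 1L]] <- data.frame(
        category = cat_i, popA = pairs[1L, i], popB = pairs[2L, i],
        mean_abs_dp = mean(top$abs_dp), stringsAsFactors = FALSE)
    }
  }
  per_pair <- do.call(rbind, per_pair)
  pair_means <- do.call(rbind, pm)
  grand <- tapply(pair_means$mean_abs_dp, pair_means$category, mean)
  union_loci <- per_pair[!duplicated(per_pair$locus_id),
                         setdiff(names(per_pair), c("rank", "pA", "pB",
                                                    "popA", "popB"))]
  rownames(union_loci) <- NULL
  structure(list(per_pair = per_pair, union_loci = union_loci,
                 pair_means = pair_means,
                 grand_means = grand[categories[categories %in% names(grand)]]),
            class = "diff_scan")
}

#' @export
print.diff_scan <- function(x, ...) {
  cat("diff_scan:", nrow(x$union_loci), "distinct top loci across",
      nrow(x$pair_means), "pair/category combinations\n")
  print(x$grand_means)
  invisible(x)
}

#' Genes within a window of each locus
#'
#' A gene hits a locus iff the gene span expanded by `window` bp on both
#' sides intersects the locus interval. The signed distance is 0 when the
#' locus overlaps the gene span, positive when the locus lies downstream of
#' the gene end and negative when upstream of the gene start.
#'
#' @param loci Locus data.frame (`locus_id`, `chrom`, `start`, `end`).
#' @param genes Gene data.frame (`id` or `gene_id`, `chrom`, `start`, `end`).
#' @param window Padding in bp (default 10000).
#' @return data.frame with `locus_id`, `gene_id`, `signed_distance`.
#' @export
gene_proximity <- function(loci, genes, window = 10000) {
  gene_id <- if ("gene_id" %in% names(genes)) genes$gene_id else genes$id
  if (nrow(loci) == 0L || nrow(genes) == 0L) {
    return(data.frame(locus_id = character(), gene_id = character(),
                      signed_distance = integer(), stringsAsFactors = FALSE))
  }
  gl <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(genes$start - window, 0) + 1L,
                                                genes$end + window))
  hits <- GenomicRanges::findOverlaps(gl, gg)
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  sd_ <- integer(length(li))
  for (h in seq_along(li)) {
    ls <- loci$start[li[h]]; le <- loci$end[li[h]]
    gs <- genes$start[gi[h]]; ge <- genes$end[gi[h]]
    sd_[h] <- if (le > gs && ls < ge) 0L
      else if (ls >= ge) ls - ge
      else -(gs - le)
  }
  out <- data.frame(locus_id = loci$locus_id[li], gene_id = gene_id[gi],
                    signed_distance = sd_, stringsAsFactors = FALSE)
  out[order(out$locus_id, out$gene_id), , drop = FALSE]
}

#' Exon-overlap classification and frequency comparison
#'
#' Classifies each locus as exonic (its interval intersects any exon) or
#' non-exonic, flags non-exonic loci overlapping annotated repeats, and
#' compares mean presence frequencies across the classes, per locus
#' category, globally and per country. Elevated frequencies of exonic
#' insertions relative to repeat-free non-exonic ones argue against a
#' detection bias explanation.
#'
#' @param freq A `frequency_table`.
#' @param annotation An `annotation_set` (see [read_gff()]); its `repeats`
#'   component defines the repeat regions.
#' @param point_breakpoint Use the interval midpoint instead of the full
#'   interval for overlap tests (default `FALSE`).
#' @return An object of class `exon_overlap_report`: list with `fractions`
#'   (per category: fraction of loci overlapping exons), `means` (mean
#'   global frequency per category and class), `country_means` and
#'   `locus_class` (per-locus classification).
#' @export
exon_overlap_stats <- function(freq, annotation, point_breakpoint = FALSE) {
  loci <- unique(freq[, c("locus_id", "chrom", "start", "end", "category")])
  if (point_breakpoint) {
    mid <- (loci$start + loci$end) %/% 2L
    qs <- mid; qe <- mid + 1L
  } else {
    qs <- loci$start; qe <- loci$end
  }
  gl <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(qs + 1L, qe))
  overlaps_any <- function(df) {
    if (nrow(df) == 0L) return(rep(FALSE, nrow(loci)))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    GenomicRanges::countOverlaps(gl, gr) > 0L
  }
  exonic <- overlaps_any(annotation$exons)
  in_repeat <- overlaps_any(annotation$repeats)
  cls <- ifelse(exonic, "exonic",
                ifelse(in_repeat, "nonexonic_repeat", "nonexonic_nonrepeat"))
  locus_class <- data.frame(loci, exonic = exonic,
                            class = cls, stringsAsFactors = FALSE)
  cats <- unique(loci$category)
  fractions <- vapply(cats, function(cc) {
    mean(exonic[loci$category == cc])
  }, numeric(1))
  class_of <- stats::setNames(cls, loci$locus_id)
  exo_of <- stats::setNames(exonic, loci$locus_id)
  mean_by <- function(fsub) {
    e <- exo_of[fsub$locus_id]
    k <- class_of[fsub$locus_id]
    c(exonic = mean(fsub$p[e]),
      nonexonic = mean(fsub$p[!e]),
      nonexonic_nonrepeat = mean(fsub$p[k == "nonexonic_nonrepeat"]))
  }
  gmeans <- list(); cmeans <- list()
  countries <- setdiff(unique(freq$country), "global")
  for (cc in cats) {
    fg <- freq[freq$country == "global" & freq$category == cc, ]
    gmeans[[cc]] <- mean_by(fg)
    for (ctry in countries) {
      fc <- freq[freq$country == ctry & freq$category == cc, ]
      cmeans[[paste(cc, ctry, sep = ".")]] <-
        data.frame(category = cc, country = ctry, t(mean_by(fc)),
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(fractions = fractions,
                 means = do.call(rbind, gmeans),
                 country_means = do.call(rbind, cmeans),
                 locus_class = locus_class),
            class = "exon_overlap_report")
}

#' @export
print.exon_overlap_report <- function(x, ...) {
  cat("exon_overlap_report\n fraction exonic by category:\n")
  print(round(x$fractions, 4))
  cat(" mean global frequency by class:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' High-frequency TE scan within insecticide-resistance genes
#'
#' Reports loci whose interval lies entirely within a listed gene span and
#' whose presence proportion reaches `threshold` in at least one country.
#'
#' @param freq A `frequency_table`.
#' @param ir_genes data.frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `label`.
#' @param threshold Minimum per-country presence proportion, inclusive
#'   (default 0.5).
#' @return data.frame with `locus_id`, `gene_id`, `country`, `p` (one row
#'   per qualifying locus/gene/country triple), plus locus metadata.
#' @export
high_frequency_gene_scan <- function(freq, ir_genes, threshold = 0.5) {
  fc <- freq[freq$country != "global" & freq$p >= threshold, , drop = FALSE]
  out <- list()
  for (g in seq_len(nrow(ir_genes))) {
    inside <- fc$chrom == ir_genes$chrom[g] &
      fc$start >= ir_genes$start[g] & fc$end <= ir_genes$end[g]
    if (any(inside)) {
      hit <- fc[inside, c("locus_id", "chrom", "start", "end", "family",
                          "te_class", "category", "country", "p")]
      hit$gene_id <- ir_genes$gene_id[g]
      out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) {
    return(data.frame(locus_id = character(), gene_id = character(),
                      country = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$locus_id, res$country), , drop = FALSE]
}
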