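#' Site frequency spectrum of carrier counts
#'
#' Histogram of per-locus carrier counts within one population sample. The
#' fixed-absent class (`k = 0`) is tallied but reported separately from the
#' segregating/fixed-present classes `k = 1..n`.
#'
#' @param gmat A `te_genotype_matrix`.
#' @param manifest `te_manifest`.
#' @param population Country label; `NULL` uses all samples.
#' @return An object of class `sfs_result`: list with `population`, `n`
#'   (sample size), `counts` (integer vector named `1..n`) and `zero_class`
#'   (number of loci with no carriers in the population).
#' @export
sfs <- function(gmat, manifest, population = NULL) {
  rows <- pop_samples(gmat, manifest, population)
  n <- length(rows)
  k <- colSums(gmat$geno[rows, , drop = FALSE])
  tab <- table(factor(k, levels = 0:n))
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(population = if (is.null(population)) "all" else population,
                 n = n, counts = counts[-1L], zero_class = counts[[1L]]),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat("sfs_result:", x$population, "(n =", x$n, "samples);",
      sum(x$counts), "loci with carriers,", x$zero_class, "at k = 0\n")
  invisible(x)
}

pop_samples <- function(gmat, manifest, population) {
  m <- manifest$samples
  rows <- if (is.null(population)) {
    m$sample_id
  } else {
    m$sample_id[m$country == population]
  }
  rows <- intersect(rows, rownames(gmat$geno))
  if (length(rows) == 0L) {
    stop("no samples for population: ", population)
  }
  rows
}

#' Joint site frequency spectrum for a pair of populations
#'
#' @param gmat A `te_genotype_matrix`.
#' @param manifest `te_manifest`.
#' @param popA,popB Country labels.
#' @return An object of class `joint_sfs_result`: list with `pair`, `nA`,
#'   `nB` and `J`, an `(nA+1) x (nB+1)` integer matrix whose `[i+1, j+1]`
#'   entry counts loci with `i` carriers in A and `j` in B. Row/column sums
#'   equal the single-population SFS including the zero classes.
#' @export
joint_sfs <- function(gmat, manifest, popA, popB) {
  rA <- pop_samples(gmat, manifest, popA)
  rB <- pop_samples(gmat, manifest, popB)
  kA <- colSums(gmat$geno[rA, , drop = FALSE])
  kB <- colSums(gmat$geno[rB, , drop = FALSE])
  nA <- length(rA); nB <- length(rB)
  J <- table(factor(kA, levels = 0:nA), factor(kB, levels = 0:nB))
  J <- matrix(as.integer(J), nrow = nA + 1L,
              dimnames = list(0:nA, 0:nB))
  structure(list(pair = c(popA, popB), nA = nA, nB = nB, J = J),
            class = "joint_sfs_result")
}

#' @export
print.joint_sfs_result <- function(x, ...) {
  cat("joint_sfs_result:", x$pair[1L], "(n =", x$nA, ") x", x$pair[2L],
      "(n =", x$nB, ");", sum(x$J), "loci\n")
  invisible(x)
}

#' Per-locus FST from carrier counts
#'
#' FST = (HT - HS) / HT on presence proportions, where HT = 2p(1-p) with p
#' the pooled-individual carrier proportion (treating the two countries as
#' one population) and HS is the unweighted average of the within-country
#' expected heterozygosities 2pA(1-pA) and 2pB(1-pB). Undefined (NA) when
#' HT = 0. With equal sample sizes FST lies in [0, 1]; with unequal sizes it
#' can fall slightly outside and is reported as computed.
#'
#' Vectorized over loci.
#'
#' @param kA,kB Carrier counts in countries A and B.
#' @param nA,nB Sample sizes.
#' @return Numeric vector of FST values (`NA` where undefined).
#' @export
fst_locus <- function(kA, nA, kB, nB) {
  stopifnot(nA >= 1, nB >= 1)
  if (any(kA > nA) || any(kB > nB) || any(kA < 0) || any(kB < 0)) {
    stop("carrier count outside [0, n]")
  }
  pA <- kA / nA
  pB <- kB / nB
  p <- (kA + kB) / (nA + nB)
  ht <- 2 * p * (1 - p)
  hs <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
  ifelse(ht > 0, (ht - hs) / ht, NA_real_)
}

#' Pairwise FST summaries for all country pairs
#'
#' For every (unordered) pair of countries: per-locus FST over loci with
#' HT > 0, the arithmetic mean over defined loci, and a histogram of FST in
#' 10 bins of width 0.1 (`[0,0.1), ..., [0.9,1.0]`). Loci with FST outside
#' [0, 1] (possible with unequal sample sizes) are excluded from the
#' histogram and counted in `n_outside_01`.
#'
#' @param gmat A `te_genotype_matrix`.
#' @param manifest `te_manifest` (needs >= 2 countries with samples).
#' @param bins Number of histogram bins over [0, 1] (default 10).
#' @return An object of class `fst_summary`: list with `summary` (data.frame
#'   `popA`, `popB`, `n_defined`, `mean_fst`, `n_outside_01`), `hist`
#'   (matrix pairs x bins) and `per_locus` (data.frame of per-locus values,
#'   long over pairs).
#' @export
pairwise_fst_summary <- function(gmat, manifest, bins = 10) {
  m <- manifest$samples[manifest$samples$sample_id %in% rownames(gmat$geno), ]
  countries <- sort(unique(m$country))
  if (length(countries) < 2L) stop("need >= 2 countries")
  ks <- do.call(cbind, lapply(countries, function(cc) {
    colSums(gmat$geno[m$sample_id[m$country == cc], , drop = FALSE])
  }))
  colnames(ks) <- countries
  ns <- stats::setNames(as.integer(table(m$country)[countries]), countries)
  pairs <- utils::combn(countries, 2L)
  breaks <- seq(0, 1, length.out = bins + 1L)
  rows <- list(); hists <- list(); per_locus <- list()
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    f <- fst_locus(ks[, a], ns[[a]], ks[, b], ns[[b]])
    def <- f[!is.na(f)]
    inside <- def[def >= 0 & def <= 1]
    h <- graphics::hist(inside, breaks = breaks, plot = FALSE,
                        right = FALSE, include.lowest = TRUE)$counts
    # hist(right = FALSE) makes bins [a,b); the final bin still includes 1
    rows[[i]] <- data.frame(popA = a, popB = b, n_defined = length(def),
                            mean_fst = mean(def),
                            n_outside_01 = length(def) - length(inside),
                            stringsAsFactors = FALSE)
    hists[[i]] <- h
    per_locus[[i]] <- data.frame(popA = a, popB = b,
                                 locus_id = gmat$loci$locus_id,
                                 fst = f, stringsAsFactors = FALSE)
  }
  hist_mat <- do.call(rbind, hists)
  dimnames(hist_mat) <- list(paste(pairs[1L, ], pairs[2L, ], sep = "-"),
                             paste0("[", format(breaks[-length(breaks)]),
                                    ",", format(breaks[-1L]), ")"))
  structure(list(summary = do.call(rbind, rows), hist = hist_mat,
                 per_locus = do.call(rbind, per_locus)),
            class = "fst_summary")
}

#' @export
print.fst_summary <- function(x, ...) {
  cat("fst_summary over", nrow(x$summary), "country pairs\n")
  print(x$summary)
  invisible(x)
}

#' PCA of the binary genotype matrix
#'
#' Each locus column is mean-centered (no variance scaling) and the centered
#' samples x loci matrix is decomposed by SVD. The per-component variance
#' fraction is the squared singular value over the total; component signs
#' are fixed so the loading of largest magnitude on each component is
#' positive, making the output deterministic.
#'
#' @param gmat A `te_genotype_matrix` (or plain numeric matrix) with >= 2
#'   samples and >= 2 loci.
#' @param n_components Number of components to keep (default all).
#' @return An object of class `te_pca`: list with `scores` (samples x
#'   components), `loadings`, `variance_fraction` (sums to 1 over all
#'   components) and `sdev`.
#' @export
te_pca <- function(gmat, n_components = NULL) {
  x <- if (inherits(gmat, "te_genotype_matrix")) gmat$geno else gmat
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 loci")
  storage.mode(x) <- "double"
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total <= 0) {
    warning("constant genotype matrix: all variance fractions are 0")
    varfrac <- rep(0, length(pc$sdev))
  } else {
    varfrac <- pc$sdev^2 / total
  }
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  keep <- seq_len(if (is.null(n_components)) ncol(pc$x) else
    min(n_components, ncol(pc$x)))
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 variance_fraction = varfrac,
                 sdev = pc$sdev),
            class = "te_pca")
}

#' @export
print.te_pca <- function(x, ...) {
  cat("te_pca:", nrow(x$scores), "samples,", ncol(x$scores),
      "components kept\n")
  vf <- x$variance_fraction[seq_len(min(5L, length(x$variance_fraction)))]
  cat("variance fractions:", paste(sprintf("%.4f", vf), collapse = " "), "\n")
  invisible(x)
}
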