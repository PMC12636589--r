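# Independent brute-force oracles and small builders shared across tests.

# connected components of the "same chrom+family and interval distance
# <= max_gap" graph, by explicit all-pairs closure (no sweep, no sorting
# tricks); returns merged extents sorted like the package output.
oracle_cluster <- function(df, max_gap) {
  n <- nrow(df)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), family = character()))
  }
  dist_le <- function(i, j) {
    if (df$chrom[i] != df$chrom[j] || df$family[i] != df$family[j]) {
      return(FALSE)
    }
    gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
    max(gap, 0L) <= max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && dist_le(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sub <- df[comp == cc, , drop = FALSE]
    data.frame(chrom = sub$chrom[1L], start = min(sub$start),
               end = max(sub$end), family = sub$family[1L],
               n_constituent_calls = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$end, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# LD r^2 from the 2x2 haplotype-count table: D^2 / (p(1-p) q(1-q))
oracle_r2_table <- function(x, y) {
  px <- mean(x); py <- mean(y); pxy <- mean(x * y)
  D <- pxy - px * py
  D^2 / (px * (1 - px) * py * (1 - py))
}

random_calls <- function(n, families = c("famA/DNA", "famB/LTR"),
                         chroms = c("chr1", "chr2"), span = 6000L,
                         category = "non_reference",
                         samples = c("S1", "S2", "S3")) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(5:400, n, replace = TRUE)
  fam <- sample(families, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    family = fam,
    te_class = classify_family(fam, warn = FALSE),
    category = category,
    call_type = if (category == "non_reference") "presence" else "absence",
    sample_id = sample(samples, n, replace = TRUE),
    hybrid_families = "", support = NA_integer_,
    stringsAsFactors = FALSE
  )
}

make_calls <- function(chrom, start, end, family, sample_id,
                       category = "non_reference",
                       call_type = "presence", hybrid = "") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             family = family,
             te_class = classify_family(family, warn = FALSE),
             category = category, call_type = call_type,
             sample_id = sample_id, hybrid_families = hybrid,
             support = NA_integer_, stringsAsFactors = FALSE)
}

toy_manifest <- function(counts) {
  as_manifest(data.frame(
    sample_id = unlist(lapply(names(counts), function(cc)
      sprintf("%s_%02d", cc, seq_len(counts[[cc]])))),
    country = rep(names(counts), counts),
    stringsAsFactors = FALSE
  ))
}

toy_gmat <- function(geno, chrom = "chr1", category = "non_reference",
                     family = "famA/DNA") {
  nL <- ncol(geno)
  start <- seq(1000L, by = 5000L, length.out = nL)
  loci <- data.frame(
    locus_id = paste0("L", seq_len(nL)),
    chrom = chrom, start = start, end = start + 10L,
    family = family, te_class = classify_family(family, warn = FALSE),
    category = category, stringsAsFactors = FALSE
  )
  colnames(geno) <- loci$locus_id
  tepop:::new_genotype_matrix(geno, loci)
}

# small but complete synthetic study, cached per session
small_config <- function(seed = 11) {
  fixture_config(
    seed = seed,
    countries = c(Alpha = 10L, Beta = 12L, Gamma = 8L),
    n_ref = 60L, n_nonref = 160L,
    n_fixed_ref = 6L, n_all_but_one_ref = 6L, n_short_ref = 8L,
    n_merge_pair_ref = 5L, n_singleton_nonref = 10L, n_non_te = 8L,
    ir = list(h = 0.5, d = 0.02, country = "Alpha", q_unlinked = 0.3)
  )
}

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "tepop-small-fixture")
    .fixture_cache$fx <- make_fixture(small_config(), dir)
    .fixture_cache$run <- run_fixture_pipeline(dir)
  }
  list(fx = .fixture_cache$fx, run = .fixture_cache$run)
}
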