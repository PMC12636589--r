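#' Classify a TE family label
#'
#' Family labels carry their consensus-library class as a `name/Class`
#' suffix (RepeatMasker style, e.g. `"Tc1-4/DNA"`); an explicit `class_map`
#' takes precedence over the suffix. Non-TE repeat classes (satellites,
#' simple repeats, buffer regions) are flagged `EXCLUDED` and their loci are
#' dropped during curation. Unrecognized class strings fall back to
#' `Unknown`.
#'
#' @param family Character vector of family labels.
#' @param class_map Optional named character vector `family -> class`.
#' @param warn Warn on unrecognized class strings (default `TRUE`).
#' @return Character vector over
#'   `{DNA, LTR, LINE, SINE, RC, Unknown, EXCLUDED}`.
#' @export
classify_family <- function(family, class_map = NULL, warn = TRUE) {
  if (any(!nzchar(family))) stop("empty family label")
  cls <- rep(NA_character_, length(family))
  if (!is.null(class_map)) {
    hit <- family %in% names(class_map)
    cls[hit] <- unname(class_map[family[hit]])
  }
  no_map <- is.na(cls)
  has_suffix <- no_map & grepl("/", family, fixed = TRUE)
  cls[has_suffix] <- sub("^[^/]*/", "", family[has_suffix])
  normalize_te_class(cls, family, warn = warn)
}

normalize_te_class <- function(cls, family, warn = TRUE) {
  known_te <- c("DNA", "LTR", "LINE", "SINE", "RC", "Unknown")
  non_te <- c("Satellite", "Simple_repeat", "buffer")
  base <- sub("/.*$", "", cls)  # "DNA/TcMar" -> "DNA"
  out <- rep("Unknown", length(cls))
  out[!is.na(base) & base %in% known_te] <- base[!is.na(base) & base %in% known_te]
  out[!is.na(base) & base == "Helitron"] <- "RC"
  out[!is.na(base) & base %in% non_te] <- "EXCLUDED"
  unknown <- !is.na(base) &
    !base %in% c(known_te, non_te, "Helitron")
  if (warn && any(unknown)) {
    warning("unrecognized TE class for famil",
            if (sum(unknown) > 1) "ies: " else "y: ",
            paste(unique(family[unknown]), collapse = ", "),
            "; mapped to Unknown")
  }
  out
}

#' Resolve a hybrid-family call by read support
#'
#' Detector calls ambiguously assigned to two TE families are resolved by
#' counting TE-supporting reads mapped within a 2 kb window around the call:
#' the family of the pair with more supporting reads wins; on a tie
#' (including zero reads for both) the first family of the hybrid label wins.
#' Reads naming a family outside the pair are ignored.
#'
#' @param call A single call (one-row data.frame or list) with a nonempty
#'   `hybrid_families` label `"A&B"`.
#' @param region_reads data.frame with columns `read_id` and `family`.
#' @return The winning family label (character scalar).
#' @export
resolve_hybrid_family <- function(call, region_reads) {
  lab <- if (is.list(call) && !is.null(call$hybrid_families)) {
    call$hybrid_families
  } else {
    as.character(call)
  }
  pair <- strsplit(lab, "&", fixed = TRUE)[[1L]]
  if (length(pair) != 2L || any(!nzchar(pair))) {
    stop("hybrid call must carry exactly two family labels")
  }
  reads <- region_reads$family[region_reads$family %in% pair]
  n1 <- sum(reads == pair[1L])
  n2 <- sum(reads == pair[2L])
  if (n2 > n1) pair[2L] else pair[1L]
}

#' Resolve all hybrid calls in a call table
#'
#' @param calls Call data.frame (see [read_te_calls()]).
#' @param hybrid_support data.frame of per-call read support with columns
#'   `chrom`, `start`, `end`, `sample_id`, `family`, `n_reads` (one row per
#'   family per hybrid call). Calls with no support rows resolve to the
#'   first family of their label.
#' @param class_map Passed to [classify_family()].
#' @return The call table with `family` and `te_class` resolved.
#' @export
resolve_hybrid_calls <- function(calls, hybrid_support = NULL,
                                 class_map = NULL) {
  idx <- which(nzchar(calls$hybrid_families))
  if (length(idx) == 0L) return(calls)
  if (!is.null(hybrid_support)) {
    skey <- paste(hybrid_support$chrom, hybrid_support$start,
                  hybrid_support$end, hybrid_support$sample_id, sep = "\r")
  }
  for (i in idx) {
    if (is.null(hybrid_support)) {
      reads <- data.frame(read_id = character(), family = character())
    } else {
      rows <- hybrid_support[skey == paste(calls$chrom[i], calls$start[i],
                                           calls$end[i], calls$sample_id[i],
                                           sep = "\r"), , drop = FALSE]
      reads <- data.frame(
        read_id = sequence(rows$n_reads),
        family = rep(rows$family, rows$n_reads),
        stringsAsFactors = FALSE
      )
    }
    calls$family[i] <- resolve_hybrid_family(calls[i, ], reads)
  }
  calls$te_class[idx] <- classify_family(calls$family[idx],
                                         class_map = class_map, warn = FALSE)
  calls
}

# single-linkage interval merging within (chrom, family) groups;
# gap <= max_gap merges (overlap = gap 0). A left-to-right sweep over
# start-sorted intervals with a running cluster end equals the transitive
# closure of the pairwise distance relation, so repetition to fixpoint is
# implicit. Returns merged loci with constituent counts and, optionally,
# per-locus sample sets.
merge_intervals_grouped <- function(df, max_gap, with_samples = FALSE) {
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), te_class = character(),
                      n_constituent_calls = integer(),
                      stringsAsFactors = FALSE)
    return(list(loci = out, samples = list()))
  }
  key <- paste(df$chrom, df$family, sep = "\r")
  ord <- order(key, df$start, df$end)
  k <- key[ord]; s <- df$start[ord]; e <- df$end[ord]
  n <- length(ord)
  cluster <- integer(n)
  cid <- 0L
  run_end <- -Inf
  for (i in seq_len(n)) {
    if (i == 1L || k[i] != k[i - 1L] || s[i] - run_end > max_gap) {
      cid <- cid + 1L
      run_end <- e[i]
    } else {
      run_end <- max(run_end, e[i])
    }
    cluster[i] <- cid
  }
  first <- which(!duplicated(cluster))
  oi <- ord[first]
  loci <- data.frame(
    chrom = df$chrom[oi],
    start = as.integer(tapply(s, cluster, min)),
    end = as.integer(tapply(e, cluster, max)),
    family = df$family[oi],
    te_class = df$te_class[oi],
    n_constituent_calls = as.integer(tabulate(cluster)),
    stringsAsFactors = FALSE
  )
  samples <- if (with_samples) {
    lapply(split(df$sample_id[ord], cluster), function(x) sort(unique(x)))
  } else {
    list()
  }
  o2 <- order(loci$chrom, loci$start, loci$end, loci$family)
  loci <- loci[o2, , drop = FALSE]
  rownames(loci) <- NULL
  if (with_samples) samples <- unname(samples)[o2]
  list(loci = loci, samples = samples)
}

make_locus_id <- function(category, chrom, start, end, family) {
  prefix <- ifelse(category == "reference", "ref", "nonref")
  paste(prefix, chrom, start, end, family, sep = "|")
}

#' Merge one genome's present reference TEs into loci
#'
#' Reference TEs of the same family lying within `max_gap` bp of each other
#' in one genome are treated as a single insertion: merging is repeated to a
#' fixpoint (equivalently, transitive closure of the pairwise distance
#' relation), and the merged extent runs from the leftmost start to the
#' rightmost end. Merging never crosses genomes: two genomes share a locus
#' only if their merged loci have identical `(chrom, family, start, end)`,
#' so a genome carrying three of another genome's four merged TEs carries a
#' different insertion.
#'
#' @param per_genome_present_calls Calls (or annotation-style intervals) for
#'   a single sample, with columns `chrom`, `start`, `end`, `family`,
#'   `te_class`, `category`; all `category` must be `"reference"`.
#' @param max_gap Maximum inter-interval distance in bp (default 1000;
#'   overlapping intervals have distance 0).
#' @return data.frame of merged loci sorted by `(chrom, start)` with a
#'   `n_constituent_calls` column.
#' @export
merge_reference_calls <- function(per_genome_present_calls, max_gap = 1000) {
  df <- per_genome_present_calls
  if (nrow(df) > 0L) {
    if (length(unique(df$category)) > 1L || any(df$category != "reference")) {
      stop("merge_reference_calls expects reference-category calls only")
    }
    if (length(unique(df$sample_id)) > 1L) {
      stop("merge_reference_calls operates on a single genome")
    }
  }
  m <- merge_intervals_grouped(df, max_gap)
  loci <- m$loci
  loci$category <- rep("reference", nrow(loci))
  loci$locus_id <- make_locus_id(loci$category, loci$chrom, loci$start,
                                 loci$end, loci$family)
  loci[, c("locus_id", "chrom", "start", "end", "family", "te_class",
           "category", "n_constituent_calls")]
}

#' Cluster non-reference insertion calls across genomes into loci
#'
#' Non-reference calls of the same family within `max_gap` bp of each other
#' (in any pair of genomes) are single-linkage clustered to a fixpoint; the
#' locus extent is the minimum start to the maximum end over the cluster,
#' and a sample is a carrier iff it contributes at least one call.
#'
#' @param all_calls Non-reference presence calls across all samples; hybrid
#'   families must already be resolved.
#' @param max_gap Maximum inter-call distance in bp (default 1000).
#' @return list with `loci` (data.frame of TELocus rows) and `presence`
#'   (named list: `locus_id` -> character vector of carrier sample ids).
#' @export
cluster_nonreference_loci <- function(all_calls, max_gap = 1000) {
  df <- all_calls
  if (nrow(df) > 0L) {
    if (any(df$category != "non_reference")) {
      stop("cluster_nonreference_loci expects non-reference calls only")
    }
    if (any(nzchar(df$hybrid_families) & is.na(df$family))) {
      stop("hybrid calls must be resolved before clustering")
    }
  }
  m <- merge_intervals_grouped(df, max_gap, with_samples = TRUE)
  loci <- m$loci
  loci$category <- rep("non_reference", nrow(loci))
  loci$locus_id <- make_locus_id(loci$category, loci$chrom, loci$start,
                                 loci$end, loci$family)
  presence <- stats::setNames(m$samples, loci$locus_id)
  loci <- loci[, c("locus_id", "chrom", "start", "end", "family", "te_class",
                   "category", "n_constituent_calls")]
  list(loci = loci, presence = presence)
}

#' Derive reference loci and carriers from absence calls
#'
#' For each genome, the present reference set is the reference annotation
#' minus that genome's absence calls (matched by exact interval and family);
#' the present set is merged with [merge_reference_calls()] and a sample
#' carries a locus iff its per-genome merging produced that exact locus.
#'
#' @param absence_calls Reference-category absence calls across samples.
#' @param annotation Reference-TE annotation (see
#'   [read_reference_annotation()]).
#' @param manifest `te_manifest`; defines the sample universe (samples with
#'   no absence calls are present for every reference TE).
#' @param max_gap Merge distance in bp.
#' @param class_map Passed to [classify_family()].
#' @return list with `loci` and `presence` as in
#'   [cluster_nonreference_loci()].
#' @export
reference_loci_from_absences <- function(absence_calls, annotation, manifest,
                                         max_gap = 1000, class_map = NULL) {
  if (nrow(absence_calls) > 0L) {
    if (any(absence_calls$category != "reference") ||
        any(absence_calls$call_type != "absence")) {
      stop("expected reference absence calls")
    }
    unknown <- setdiff(absence_calls$sample_id, manifest$samples$sample_id)
    if (length(unknown) > 0L) {
      stop("sample in calls but not manifest: ", unknown[1L])
    }
  }
  ann_key <- paste(annotation$chrom, annotation$start, annotation$end,
                   annotation$family, sep = "\r")
  if (anyDuplicated(ann_key)) stop("duplicate entries in reference annotation")
  call_key <- paste(absence_calls$chrom, absence_calls$start,
                    absence_calls$end, absence_calls$family, sep = "\r")
  if (!all(call_key %in% ann_key)) {
    stop("reference absence call does not match any annotation entry")
  }
  ann <- data.frame(
    chrom = annotation$chrom, start = annotation$start, end = annotation$end,
    family = annotation$family,
    te_class = classify_family(annotation$family, class_map = class_map,
                               warn = FALSE),
    category = "reference", stringsAsFactors = FALSE
  )
  samples <- manifest$samples$sample_id
  absent_by_sample <- split(call_key, absence_calls$sample_id)
  per_sample <- lapply(samples, function(s) {
    absent <- absent_by_sample[[s]]
    present <- if (is.null(absent)) ann else
      ann[!(ann_key %in% absent), , drop = FALSE]
    if (nrow(present) == 0L) return(NULL)
    present$sample_id <- s
    merged <- merge_reference_calls(present, max_gap = max_gap)
    merged$sample_id <- s
    merged
  })
  merged_all <- do.call(rbind, per_sample)
  if (is.null(merged_all) || nrow(merged_all) == 0L) {
    loci <- merge_reference_calls(empty_calls())
    return(list(loci = loci, presence = list()))
  }
  presence <- lapply(split(merged_all$sample_id, merged_all$locus_id), sort)
  first <- merged_all[!duplicated(merged_all$locus_id), , drop = FALSE]
  ord <- order(first$chrom, first$start, first$end, first$family)
  loci <- first[ord, setdiff(names(first), "sample_id"), drop = FALSE]
  rownames(loci) <- NULL
  list(loci = loci, presence = presence[loci$locus_id])
}

#' Family-activity filter
#'
#' A family shows evidence of recent activity iff it has at least
#' `min_loci` distinct non-reference loci and at least one non-reference
#' locus carried by `min_carriers` or more samples, evaluated on the pooled
#' dataset. All loci (both categories) of failing families are removed.
#'
#' @param loci Locus data.frame (both categories).
#' @param carrier_counts Named integer vector, `locus_id` -> carrier count.
#' @param min_loci,min_carriers Thresholds (defaults 2 and 2).
#' @return Logical vector, `TRUE` for surviving loci.
#' @export
family_activity_filter <- function(loci, carrier_counts, min_loci = 2,
                                   min_carriers = 2) {
  nr <- loci$category == "non_reference"
  k <- carrier_counts[loci$locus_id]
  fam_nloci <- table(loci$family[nr])
  fam_nonsingleton <- tapply(k[nr] >= min_carriers, loci$family[nr], any)
  ok_fams <- names(fam_nloci)[as.integer(fam_nloci) >= min_loci &
                                as.logical(fam_nonsingleton[names(fam_nloci)])]
  loci$family %in% ok_fams
}

#' Global frequency filters
#'
#' A reference locus survives iff it is absent in at least `min_absent`
#' samples (removing fixed TEs and those present in all but one genome); a
#' non-reference locus survives iff carried by at least `min_carriers`
#' samples (removing singletons). Applied to the pooled global sample, not
#' per country.
#'
#' @param loci Locus data.frame.
#' @param carrier_counts Named integer vector, `locus_id` -> carrier count.
#' @param n_samples Total number of samples.
#' @param min_absent,min_carriers Thresholds (defaults 2 and 2).
#' @return Logical vector, `TRUE` for surviving loci.
#' @export
frequency_filters <- function(loci, carrier_counts, n_samples,
                              min_absent = 2, min_carriers = 2) {
  k <- carrier_counts[loci$locus_id]
  if (any(k > n_samples)) stop("carrier count exceeds sample size")
  ifelse(loci$category == "reference",
         (n_samples - k) >= min_absent,
         k >= min_carriers)
}

#' Minimum-length filter for reference loci
#'
#' Short reference TEs are prone to false absence calls (an insert can span
#' them by chance), so reference loci shorter than `min_len` bp are removed;
#' non-reference loci pass through untouched.
#'
#' @param loci Locus data.frame.
#' @param min_len Minimum merged length in bp, inclusive (default 600).
#' @return Logical vector, `TRUE` for surviving loci.
#' @export
length_filter <- function(loci, min_len = 600) {
  loci$category != "reference" | (loci$end - loci$start) >= min_len
}

#' Size-stratified site frequency spectra for reference loci
#'
#' Diagnostic run before the length filter: reference loci are partitioned
#' by merged length into `[1, b1)`, `[b1, b2]` and `(b2, Inf)` strata
#' (defaults 200 and 600 bp) and an SFS of carrier counts is computed per
#' stratum. An excess of high-frequency loci in the short strata indicates
#' fixed TEs miscalled as absent in a few genomes.
#'
#' @param loci Reference-category locus data.frame.
#' @param carrier_counts Named integer vector, `locus_id` -> carrier count.
#' @param n_samples Total sample count.
#' @param boundaries Two stratum boundaries in bp (default `c(200, 600)`).
#' @return list with one SFS per stratum (`lt<b1>`, `<b1>to<b2>`, `gt<b2>`),
#'   each an integer vector of counts named `0..n_samples`, plus
#'   `stratum_sizes`.
#' @export
size_stratified_sfs <- function(loci, carrier_counts, n_samples,
                                boundaries = c(200, 600)) {
  stopifnot(length(boundaries) == 2L, boundaries[1L] < boundaries[2L])
  loci <- loci[loci$category == "reference", , drop = FALSE]
  len <- loci$end - loci$start
  b1 <- boundaries[1L]; b2 <- boundaries[2L]
  stratum <- ifelse(len < b1, 1L, ifelse(len <= b2, 2L, 3L))
  k <- carrier_counts[loci$locus_id]
  tab <- function(kk) {
    out <- integer(n_samples + 1L)
    names(out) <- 0:n_samples
    t0 <- table(factor(kk, levels = 0:n_samples))
    out[] <- as.integer(t0)
    out
  }
  out <- list(tab(k[stratum == 1L]), tab(k[stratum == 2L]),
              tab(k[stratum == 3L]))
  names(out) <- c(paste0("lt", b1), paste0(b1, "to", b2), paste0("gt", b2))
  out$stratum_sizes <- stats::setNames(tabulate(stratum, 3L), names(out)[1:3])
  out
}

#' Run the full curation cascade
#'
#' Orchestrates the post-detection curation of raw calls into a final set of
#' polymorphic TE loci: hybrid-family resolution, per-genome merging of
#' reference TEs, cross-genome clustering of non-reference insertions, then
#' the locus-level filter cascade (non-TE exclusion, family-activity,
#' global frequency filters, reference length filter) with exact
#' bookkeeping. The size-stratified SFS diagnostic is computed just before
#' the length filter.
#'
#' @param ref_calls Reference-category absence calls (data.frame).
#' @param nonref_calls Non-reference presence calls (data.frame).
#' @param annotation Reference-TE annotation.
#' @param manifest `te_manifest`.
#' @param hybrid_support Optional hybrid read-support table (see
#'   [resolve_hybrid_calls()]).
#' @param max_gap Merge/cluster distance in bp (default 1000).
#' @param min_ref_len Reference length cutoff in bp (default 600).
#' @param min_absent,min_carriers Frequency-filter thresholds (default 2).
#' @param class_map Passed to [classify_family()].
#' @return An object of class `te_curation`: list with `loci` (survivors),
#'   `presence` (carrier map for survivors), `report` (`filter_report`),
#'   `all_loci` (every formed locus with a `fate` column naming its first
#'   failing stage or `"survive"`), and `size_sfs`.
#' @export
curate_loci <- function(ref_calls, nonref_calls, annotation, manifest,
                        hybrid_support = NULL, max_gap = 1000,
                        min_ref_len = 600, min_absent = 2, min_carriers = 2,
                        class_map = NULL) {
  n_samples <- nrow(manifest$samples)
  unknown <- setdiff(unique(nonref_calls$sample_id), manifest$samples$sample_id)
  if (length(unknown) > 0L) {
    stop("sample in calls but not manifest: ", unknown[1L])
  }
  nonref_calls <- resolve_hybrid_calls(nonref_calls, hybrid_support,
                                       class_map = class_map)
  nr <- cluster_nonreference_loci(nonref_calls, max_gap = max_gap)
  rf <- reference_loci_from_absences(ref_calls, annotation, manifest,
                                     max_gap = max_gap, class_map = class_map)
  loci <- rbind(rf$loci, nr$loci)
  rownames(loci) <- NULL
  presence <- c(rf$presence, nr$presence)
  k <- stats::setNames(vapply(presence, length, integer(1)), names(presence))

  fate <- rep("survive", nrow(loci))
  alive <- rep(TRUE, nrow(loci))

  drop <- alive & loci$te_class == "EXCLUDED"
  fate[drop] <- "non_te"; alive <- alive & !drop

  keep <- family_activity_filter(loci[alive, , drop = FALSE], k,
                                 min_carriers = min_carriers)
  drop <- alive; drop[alive] <- !keep
  fate[drop] <- "family_activity"; alive <- alive & !drop

  keep <- frequency_filters(loci[alive, , drop = FALSE], k, n_samples,
                            min_absent = min_absent,
                            min_carriers = min_carriers)
  drop <- alive; drop[alive] <- !keep
  fate[drop] <- ifelse(loci$category[drop] == "reference",
                       "reference_frequency", "nonreference_singleton")
  alive <- alive & !drop

  size_sfs <- size_stratified_sfs(loci[alive, , drop = FALSE], k, n_samples)

  keep <- length_filter(loci[alive, , drop = FALSE], min_len = min_ref_len)
  drop <- alive; drop[alive] <- !keep
  fate[drop] <- "length"; alive <- alive & !drop

  all_loci <- loci
  all_loci$carrier_count <- unname(k[loci$locus_id])
  all_loci$fate <- fate
  survivors <- loci[alive, , drop = FALSE]
  rownames(survivors) <- NULL
  report <- structure(list(
    input = nrow(loci),
    removed = c(
      non_te = sum(fate == "non_te"),
      family_activity = sum(fate == "family_activity"),
      reference_frequency = sum(fate == "reference_frequency"),
      nonreference_singleton = sum(fate == "nonreference_singleton"),
      length = sum(fate == "length")
    ),
    survivors = nrow(survivors)
  ), class = "filter_report")
  structure(list(loci = survivors, presence = presence[survivors$locus_id],
                 report = report, all_loci = all_loci, size_sfs = size_sfs),
            class = "te_curation")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: input =", x$input, "loci\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed at %-23s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  cat("  survivors:", x$survivors, "\n")
  invisible(x)
}

#' @export
print.te_curation <- function(x, ...) {
  print(x$report)
  invisible(x)
}
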