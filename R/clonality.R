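#' Mutations shared by two tumours
#'
#' Two tumours share a mutation when both carry the identical nucleotide
#' substitution at the same genomic coordinate. Identity is exact on
#' (contig, position, ref, alt).
#'
#' @param a,b `callset` objects (normally already filtered).
#' @return Sorted character vector of shared mutation keys.
#' @export
shared_mutations <- function(a, b) {
  sort(intersect(unique(mutation_keys(a)), unique(mutation_keys(b))))
}

#' Pairwise mutation-sharing matrix for a cohort
#'
#' Computes, for every pair of samples, the number of identical mutations
#' shared; the diagonal holds each sample's total mutation count. This is
#' the tabular analogue of the sample-by-sample shared-mutation heatmap
#' used to assess tumour relatedness.
#'
#' @param cohort List of `callset` objects with unique sample ids.
#' @return An object of class `sharing_matrix`: list with `samples`,
#'   `totals`, and the symmetric `shared` count matrix (totals on the
#'   diagonal).
#' @export
sharing_matrix <- function(cohort) {
  ids <- vapply(cohort, function(cs) cs$sample_id, character(1))
  if (anyDuplicated(ids)) stop_msclone("duplicate sample ids in cohort")
  keys <- lapply(cohort, function(cs) unique(mutation_keys(cs)))
  n <- length(cohort)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(keys[[i]])
    if (i < n) for (j in seq(i + 1L, n)) {
      s <- length(intersect(keys[[i]], keys[[j]]))
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  structure(list(samples = ids, totals = diag(m), shared = m),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("<sharing_matrix> totals on diagonal, shared counts off-diagonal\n")
  print(x$shared)
  invisible(x)
}

#' Fraction of mutations shared by two tumours
#'
#' @param a,b `callset` objects.
#' @param denominator Which count to divide by: the first sample's total
#'   (default; the putative primary), the second's, the union, or the
#'   smaller of the two totals.
#' @return Shared fraction in `[0, 1]`.
#' @export
shared_fraction <- function(a, b,
                            denominator = c("first", "second", "union", "min")) {
  denominator <- match.arg(denominator)
  ka <- unique(mutation_keys(a)); kb <- unique(mutation_keys(b))
  d <- switch(denominator,
              first = length(ka), second = length(kb),
              union = length(union(ka, kb)),
              min = min(length(ka), length(kb)))
  if (d == 0L) stop_msclone("shared_fraction: chosen denominator (%s) is zero",
                            denominator)
  length(intersect(ka, kb)) / d
}

#' Remove hotspot mutations from a key set
#'
#' Recurrent hotspot mutations (such as EGFR p.L858R) can arise
#' independently in unrelated tumours, so sharing one is weak evidence of a
#' clonal relationship and such keys are excluded before relatedness is
#' judged.
#'
#' @param keys Character vector of mutation keys.
#' @param hotspots A hotspot table as returned by [hotspot_list()], or a
#'   character vector of keys.
#' @return `keys` with hotspot entries removed.
#' @export
exclude_hotspots <- function(keys, hotspots) {
  setdiff(keys, hotspot_keys(hotspots))
}

#' Hotspot list constructor
#'
#' @param contig,pos,ref,alt Coordinate-style hotspot identity.
#' @param gene,protein_change Optional label-style identity (e.g. `"EGFR"`,
#'   `"p.L858R"`), carried as annotation.
#' @return Data frame of hotspot definitions.
#' @export
hotspot_list <- function(contig, pos, ref, alt, gene = "", protein_change = "") {
  data.frame(contig = as.character(contig), pos = as.integer(pos),
             ref = as.character(ref), alt = as.character(alt),
             gene = as.character(gene),
             protein_change = as.character(protein_change),
             stringsAsFactors = FALSE)
}

hotspot_keys <- function(hotspots) {
  if (is.character(hotspots)) return(hotspots)
  if (is.null(hotspots) || nrow(hotspots) == 0L) return(character())
  sprintf("%s:%d:%s>%s", hotspots$contig, hotspots$pos, hotspots$ref,
          hotspots$alt)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. Delegates to
#' [stats::fisher.test()], which implements exactly this rule.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(6, 9, 111, 326) # ~0.23
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop_msclone("fisher_exact_2x2 requires non-negative integer counts")
  }
  if (sum(counts) == 0) stop_msclone("fisher_exact_2x2: all-zero table")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Cohort reference counts for comparison tests
#'
#' @param n_mutated_samples,n_samples Hotspot prevalence in an external
#'   cohort: mutated samples over total samples.
#' @param n_shared_mutations,n_total_mutations Mutation-sharing rate in an
#'   external cohort: exonic mutations shared between any tumour pair over
#'   total exonic mutations.
#' @return An object of class `cohort_reference`.
#' @export
cohort_reference <- function(n_mutated_samples = NA_integer_,
                             n_samples = NA_integer_,
                             n_shared_mutations = NA_integer_,
                             n_total_mutations = NA_integer_) {
  if (!is.na(n_mutated_samples) && n_mutated_samples > n_samples) {
    stop_msclone("n_mutated_samples exceeds n_samples")
  }
  if (!is.na(n_shared_mutations) && n_shared_mutations > n_total_mutations) {
    stop_msclone("n_shared_mutations exceeds n_total_mutations")
  }
  structure(list(n_mutated_samples = n_mutated_samples, n_samples = n_samples,
                 n_shared_mutations = n_shared_mutations,
                 n_total_mutations = n_total_mutations),
            class = "cohort_reference")
}

#' Hotspot prevalence comparison against a reference cohort
#'
#' Tests whether a hotspot mutation is more prevalent in this series
#' (each tumour counted as if from a unique patient) than in a large
#' external cohort; a non-significant result means the sharing is
#' compatible with independent acquisition.
#'
#' @param k_series Hotspot-mutated tumours in the series.
#' @param n_series Tumours in the series.
#' @param cohort A [cohort_reference()] with prevalence counts.
#' @return Two-sided Fisher p-value.
#' @export
#' @examples
#' hotspot_prevalence_test(6, 15, cohort_reference(111, 437)) # ~0.23
hotspot_prevalence_test <- function(k_series, n_series, cohort) {
  if (k_series > n_series) stop_msclone("k_series exceeds n_series")
  fisher_exact_2x2(k_series, n_series - k_series,
                   cohort$n_mutated_samples,
                   cohort$n_samples - cohort$n_mutated_samples)
}

#' Shared-mutation rate comparison against a reference cohort
#'
#' Tests whether the rate of exonic mutations shared between tumour pairs
#' in this series exceeds the rate observed between unrelated tumours of an
#' external cohort.
#'
#' @param shared_series Shared exonic mutations in the series.
#' @param total_series Total exonic mutations in the series.
#' @param cohort A [cohort_reference()] with sharing counts.
#' @return Two-sided Fisher p-value.
#' @export
#' @examples
#' shared_mutation_rate_test(1, 884, cohort_reference(
#'   n_shared_mutations = 20, n_total_mutations = 8413)) # ~0.72
shared_mutation_rate_test <- function(shared_series, total_series, cohort) {
  if (shared_series > total_series) {
    stop_msclone("shared_series exceeds total_series")
  }
  fisher_exact_2x2(shared_series, total_series - shared_series,
                   cohort$n_shared_mutations,
                   cohort$n_total_mutations - cohort$n_shared_mutations)
}

#' Match structural variants between two tumours
#'
#' Greedy nearest-first matching of breakpoint pairs: two SVs match when
#' their types agree and both breakpoints lie within `tolerance` base pairs;
#' each record is matched at most once.
#'
#' @param a,b SV data frames (see [sv_record()]), or `callset`s.
#' @param tolerance Maximum per-breakpoint distance in bp (default 10,
#'   absorbing caller jitter around base-precise clipped-read breakpoints).
#' @return Data frame of matched index pairs `idx_a`, `idx_b` with the
#'   maximum breakpoint distance of each match.
#' @export
shared_svs <- function(a, b, tolerance = 10) {
  if (inherits(a, "callset")) a <- a$svs
  if (inherits(b, "callset")) b <- b$svs
  if (tolerance < 0) stop_msclone("tolerance must be >= 0")
  out <- data.frame(idx_a = integer(), idx_b = integer(), dist = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  cand <- expand.grid(idx_a = seq_len(nrow(a)), idx_b = seq_len(nrow(b)))
  same <- a$sv_type[cand$idx_a] == b$sv_type[cand$idx_b] &
    a$contig_a[cand$idx_a] == b$contig_a[cand$idx_b] &
    a$contig_b[cand$idx_a] == b$contig_b[cand$idx_b]
  cand <- cand[same, , drop = FALSE]
  da <- abs(a$pos_a[cand$idx_a] - b$pos_a[cand$idx_b])
  db <- abs(a$pos_b[cand$idx_a] - b$pos_b[cand$idx_b])
  cand$dist <- pmax(da, db)
  cand <- cand[cand$dist <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$idx_a, cand$idx_b), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  for (k in seq_len(nrow(cand))) {
    i <- cand$idx_a[k]; j <- cand$idx_b[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out <- rbind(out, cand[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Default classification policy
#'
#' Policy thresholds for [classify_pair()]. These are operating defaults of
#' this package, not published constants: the underlying reasoning is
#' case-by-case (a metastasis retains a large fraction of its founder's
#' mutations; a single shared non-hotspot mutation is judged against the
#' sharing rate among unrelated tumours).
#'
#' @param min_shared Minimum shared non-hotspot mutations for a
#'   clonally-related verdict (default 2).
#' @param min_fraction Minimum shared fraction (of the smaller total, so the
#'   verdict is symmetric in the pair) for a clonally-related verdict.
#' @param alpha Significance level for the single-shared-mutation branch.
#' @return A list of policy parameters.
#' @export
classify_policy <- function(min_shared = 2L, min_fraction = 0.05,
                            alpha = 0.05) {
  list(min_shared = as.integer(min_shared), min_fraction = min_fraction,
       alpha = alpha)
}

#' Classify a tumour pair as independent or clonally related
#'
#' Decision rule, applied to the shared mutations after hotspot exclusion:
#'
#' 1. `shared_non_hotspot == 0` — `independent` (hotspot-only sharing is
#'    compatible with independent acquisition of a recurrent mutation).
#' 2. `shared_non_hotspot >= min_shared` **and** shared fraction (relative
#'    to the smaller of the two totals) `>= min_fraction` —
#'    `clonally_related`.
#' 3. Exactly one shared non-hotspot mutation — compared with the sharing
#'    rate in a reference cohort of unrelated tumours via
#'    [shared_mutation_rate_test()]; non-significant (`p >= alpha`) means
#'    `independent`, significant means `indeterminate`.
#' 4. Anything else — `indeterminate`.
#'
#' @param a,b `callset` objects, normally from the same patient.
#' @param hotspots Hotspot definitions (see [hotspot_list()]); may be empty.
#' @param cohort A [cohort_reference()] with sharing-rate counts; required
#'   only when the single-shared-mutation branch is reached.
#' @param policy A [classify_policy()].
#' @param series_total Total mutation count used as the series denominator
#'   in the single-shared branch; defaults to the size of the pair's key
#'   union.
#' @return An object of class `relationship_call` with the verdict, the
#'   supporting counts and a trace of every branch taken.
#' @export
classify_pair <- function(a, b, hotspots = NULL, cohort = NULL,
                          policy = classify_policy(), series_total = NULL) {
  ka <- unique(mutation_keys(a)); kb <- unique(mutation_keys(b))
  shared <- intersect(ka, kb)
  shared_nh <- exclude_hotspots(shared, hotspots)
  notes <- character()
  if (!is.null(a$patient_id) && !is.null(b$patient_id) &&
      !identical(a$patient_id, b$patient_id)) {
    notes <- c(notes, "cross-patient comparison")
  }
  notes <- c(notes, sprintf(
    "shared=%d, shared_non_hotspot=%d (hotspots excluded: %d)",
    length(shared), length(shared_nh), length(shared) - length(shared_nh)))
  denom <- min(length(ka), length(kb))
  frac <- if (denom > 0) length(shared_nh) / denom else 0
  notes <- c(notes, sprintf(
    "policy: min_shared=%d, min_fraction=%g, alpha=%g; fraction=%.4f (min-total denominator)",
    policy$min_shared, policy$min_fraction, policy$alpha, frac))

  if (length(shared_nh) == 0L) {
    verdict <- "independent"
    notes <- c(notes, "no shared non-hotspot mutations -> independent")
  } else if (length(shared_nh) >= policy$min_shared &&
             frac >= policy$min_fraction) {
    verdict <- "clonally_related"
    notes <- c(notes, "shared count and fraction above policy thresholds -> clonally_related")
  } else if (length(shared_nh) == 1L) {
    if (is.null(cohort) || is.na(cohort$n_shared_mutations)) {
      stop_msclone("classify_pair: single shared non-hotspot mutation needs a cohort reference")
    }
    tot <- series_total %||% length(union(ka, kb))
    p <- shared_mutation_rate_test(1L, tot, cohort)
    notes <- c(notes, sprintf(
      "single shared mutation: rate test 1/%d vs %d/%d, p=%.4f",
      tot, cohort$n_shared_mutations, cohort$n_total_mutations, p))
    if (p >= policy$alpha) {
      verdict <- "independent"
      notes <- c(notes, "sharing rate not elevated over reference cohort -> independent")
    } else {
      verdict <- "indeterminate"
      notes <- c(notes, "sharing rate elevated but only one mutation -> indeterminate")
    }
  } else {
    verdict <- "indeterminate"
    notes <- c(notes, "shared mutations present but below policy thresholds -> indeterminate")
  }

  structure(list(pair = c(a$sample_id, b$sample_id), verdict = verdict,
                 shared_total = length(shared),
                 shared_non_hotspot = length(shared_nh),
                 shared_fraction = frac, evidence = notes),
            class = "relationship_call")
}

#' @export
print.relationship_call <- function(x, ...) {
  cat(sprintf("<relationship_call> %s vs %s: %s (shared %d, non-hotspot %d, fraction %.3f)\n",
              x$pair[1], x$pair[2], x$verdict, x$shared_total,
              x$shared_non_hotspot, x$shared_fraction))
  for (n in x$evidence) cat("  -", n, "\n")
  invisible(x)
}
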