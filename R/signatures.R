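#' Classify a substitution into the six pyrimidine-normalised classes
#'
#' Substitutions with a purine reference base are reverse-complemented onto
#' the pyrimidine strand, so e.g. G>T is reported as C>A. Vectorised.
#'
#' @param ref,alt Single reference and alternate bases.
#' @return Factor-free character vector over
#'   `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
#' @examples
#' classify_substitution(c("C", "G"), c("A", "T")) # both "C>A"
classify_substitution <- function(ref, alt) {
  if (any(!(ref %in% BASES)) || any(!(alt %in% BASES))) {
    stop_msclone("substitution bases must be in {A,C,G,T}")
  }
  if (any(ref == alt)) stop_msclone("ref == alt is not a substitution")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  paste0(r, ">", a)
}

#' Six-class mutation spectrum of a call set
#'
#' @param calls A `callset` or SNV data frame.
#' @return Named integer vector of class `spectrum_counts` over the six
#'   substitution classes; sums to the number of SNVs.
#' @export
spectrum_counts <- function(calls) {
  df <- if (inherits(calls, "callset")) calls$snvs else calls
  counts <- setNames(integer(6), SUBSTITUTION_CLASSES)
  if (nrow(df) > 0L) {
    tab <- table(factor(classify_substitution(df$ref, df$alt),
                        levels = SUBSTITUTION_CLASSES))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = c("spectrum_counts", "integer"))
}

#' Test for a difference between two mutation spectra
#'
#' Exact-style test on the 2x6 contingency table of substitution-class
#' counts. For small tables (total `<= exact_limit`) the exact network
#' algorithm is used; larger tables fall back to Monte-Carlo estimation of
#' the exact p-value with a fixed seed.
#'
#' @param a,b `spectrum_counts` (or plain named count vectors).
#' @param reps Monte-Carlo replicates when the exact path is infeasible.
#' @param seed Seed for the Monte-Carlo path.
#' @param exact_limit Largest table total handled exactly.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
compare_spectra <- function(a, b, reps = 1e5, seed = 1L, exact_limit = 200L) {
  if (sum(a) == 0 || sum(b) == 0) {
    stop_msclone("compare_spectra: a spectrum with zero total is untestable")
  }
  tab <- rbind(as.integer(a), as.integer(b))
  keep <- colSums(tab) > 0   # all-zero classes carry no information
  tab <- tab[, keep, drop = FALSE]
  if (sum(tab) <= exact_limit) {
    stats::fisher.test(tab, workspace = 2e7)$p.value
  } else {
    withr::with_seed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = as.integer(reps))$p.value)
  }
}

#' Pearson correlation between two mutation spectra
#'
#' Correlates the six class fractions of two spectra. A spectrum whose
#' fractions are constant across classes has zero variance and no defined
#' correlation; `NA` is returned with a warning in that case.
#'
#' @param a,b `spectrum_counts` (or plain count vectors); totals must be
#'   positive.
#' @return Pearson r in `[-1, 1]`, or `NA` if undefined.
#' @export
spectrum_correlation <- function(a, b) {
  if (sum(a) == 0 || sum(b) == 0) {
    stop_msclone("spectrum_correlation requires non-empty spectra")
  }
  fa <- a / sum(a); fb <- b / sum(b)
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    warning("spectrum_correlation undefined for a constant spectrum; returning NA")
    return(NA_real_)
  }
  stats::cor(as.numeric(fa), as.numeric(fb))
}

#' APOBEC motif and context counts around mutated cytosines
#'
#' Accumulates the four quantities behind the TCW enrichment statistic over
#' all mutated C/G sites of a call set:
#'
#' * `mutations_tcw` — mutated cytosines (and guanines) in a TCW (or WGA)
#'   motif, restricted to the APOBEC-type substitutions TCW>TTW/TGW and
#'   WGA>WAA/WCA (i.e. C>T/C>G on the pyrimidine strand);
#' * `mutations_cg` — all mutated cytosines or guanines, any substitution;
#' * `context_tcw` — TCW (or WGA) motif occurrences within the
#'   41-nucleotide window centred on each mutated C/G. A motif counts when
#'   its central C/G lies inside the window; its single-base flanks are
#'   read from the reference, so motifs at window edges are not lost to
#'   truncation. Windows are truncated at contig ends and accumulated per
#'   mutation, so overlapping windows count repeatedly;
#' * `context_cg` — cytosines and guanines within those windows.
#'
#' @param reference A `reference_contig`.
#' @param calls A `callset` or SNV data frame; positions must lie on the
#'   reference, and the reference base at each position must equal `ref`.
#' @param window_flank Bases to each side of the mutated site (default 20,
#'   i.e. a 41-nt window).
#' @return An object of class `apobec_counts` (a named list of the four
#'   counts plus the number of truncated windows).
#' @export
context_counts_41nt <- function(reference, calls, window_flank = 20L) {
  df <- if (inherits(calls, "callset")) calls$snvs else calls
  n <- nchar(reference$sequence)
  if (nrow(df) > 0L && any(df$pos < 1L | df$pos > n)) {
    stop_msclone("call position outside the reference contig")
  }
  if (nrow(df) > 0L) {
    ref_base <- ref_base_at(reference, df$pos)
    if (any(ref_base != df$ref)) {
      stop_msclone("reference allele mismatch at %s",
                   mutation_keys(df)[which(ref_base != df$ref)[1]])
    }
  }
  cg <- df[df$ref %in% c("C", "G"), , drop = FALSE]
  counts <- list(mutations_tcw = 0L, mutations_cg = nrow(cg),
                 context_tcw = 0L, context_cg = 0L, truncated_windows = 0L)
  if (nrow(cg) == 0L) return(structure(counts, class = "apobec_counts"))

  apobec_type <- (cg$ref == "C" & cg$alt %in% c("T", "G")) |
    (cg$ref == "G" & cg$alt %in% c("A", "C"))
  in_motif <- in_tcw_motif(reference, cg$pos)
  counts$mutations_tcw <- sum(apobec_type & in_motif)

  lo <- pmax(1L, cg$pos - window_flank)
  hi <- pmin(n, cg$pos + window_flank)
  counts$truncated_windows <- sum(lo > cg$pos - window_flank |
                                  hi < cg$pos + window_flank)
  chars <- strsplit(reference$sequence, "")[[1]]
  prev <- c("", chars[-n])
  nxt <- c(chars[-1L], "")
  # both orientations: C of a TCW on the displayed strand, or G of a WGA
  # (the reverse-complement image of TCW)
  motif <- (chars == "C" & prev == "T" & nxt %in% c("A", "T")) |
    (chars == "G" & nxt == "A" & prev %in% c("A", "T"))
  is_cg <- chars %in% c("C", "G")
  idx <- unlist(mapply(seq.int, lo, hi, SIMPLIFY = FALSE))
  counts$context_cg <- sum(is_cg[idx])
  counts$context_tcw <- sum(motif[idx])
  structure(counts, class = "apobec_counts")
}

#' @export
print.apobec_counts <- function(x, ...) {
  cat(sprintf("<apobec_counts> mutations: %d TCW / %d C|G; context: %d TCW / %d C|G (%d truncated windows)\n",
              x$mutations_tcw, x$mutations_cg, x$context_tcw, x$context_cg,
              x$truncated_windows))
  invisible(x)
}

#' APOBEC TCW enrichment
#'
#' Fold-enrichment of APOBEC-type mutations at TCW motifs relative to the
#' availability of TCW contexts around the mutated cytosines/guanines:
#'
#' `E = (mutations_tcw / mutations_cg) / (context_tcw / context_cg)`
#'
#' Equals 1 under proportional (motif-blind) targeting of C/G sites.
#'
#' @param counts An `apobec_counts` object (see [context_counts_41nt()]).
#' @return Non-negative enrichment ratio.
#' @export
#' @examples
#' apobec_enrichment(structure(list(mutations_tcw = 30, mutations_cg = 60,
#'   context_tcw = 1000, context_cg = 8000), class = "apobec_counts")) # 4
apobec_enrichment <- function(counts) {
  for (f in c("mutations_cg", "context_tcw", "context_cg")) {
    if (counts[[f]] <= 0) {
      stop_msclone("apobec_enrichment: %s is zero, enrichment undefined", f)
    }
  }
  (counts$mutations_tcw / counts$mutations_cg) /
    (counts$context_tcw / counts$context_cg)
}

#' Significance of APOBEC TCW enrichment
#'
#' Two-sided Fisher's exact test comparing the in/out-of-motif split of the
#' APOBEC-type mutations with the in/out-of-motif split of all C/G context
#' positions in the same 41-nt windows.
#'
#' @param counts An `apobec_counts` object.
#' @return Two-sided Fisher p-value.
#' @export
apobec_significance <- function(counts) {
  if (counts$mutations_cg == 0) {
    stop_msclone("apobec_significance: no mutated C/G sites")
  }
  fisher_exact_2x2(counts$mutations_tcw,
                   counts$mutations_cg - counts$mutations_tcw,
                   counts$context_tcw,
                   counts$context_cg - counts$context_tcw)
}

#' APOBEC enrichment with significance for one tumour
#'
#' Convenience wrapper running [context_counts_41nt()],
#' [apobec_enrichment()] and [apobec_significance()].
#'
#' @inheritParams context_counts_41nt
#' @return List with `e_tcw`, `p_value` and the underlying `counts`.
#' @export
apobec_report <- function(reference, calls, window_flank = 20L) {
  counts <- context_counts_41nt(reference, calls, window_flank)
  list(e_tcw = apobec_enrichment(counts),
       p_value = apobec_significance(counts), counts = counts)
}

trinuc_context_levels <- function() {
  out <- character(0)
  for (cls in SUBSTITUTION_CLASSES) {
    r <- substr(cls, 1, 1)
    for (up in BASES) for (down in BASES) {
      out <- c(out, sprintf("%s[%s]%s", up, cls, down))
    }
  }
  out
}

#' 96-class trinucleotide mutation spectrum
#'
#' Counts each SNV in its trinucleotide context, strand-normalised so the
#' mutated base is a pyrimidine (purine-reference calls are
#' reverse-complemented, context included). Calls lacking a flanking base
#' (at contig ends) are excluded and reported via the `n_excluded`
#' attribute. Marginalising over contexts reproduces [spectrum_counts()]
#' up to those exclusions.
#'
#' @param reference A `reference_contig`.
#' @param calls A `callset` or SNV data frame.
#' @return Named integer vector of class `trinuc_spectrum` over the 96
#'   context classes, with attribute `n_excluded`.
#' @export
trinuc_spectrum <- function(reference, calls) {
  df <- if (inherits(calls, "callset")) calls$snvs else calls
  n <- nchar(reference$sequence)
  counts <- setNames(integer(96), trinuc_context_levels())
  excluded <- 0L
  if (nrow(df) > 0L) {
    ok <- df$pos > 1L & df$pos < n
    excluded <- sum(!ok)
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) > 0L) {
    up <- ref_base_at(reference, df$pos - 1L)
    down <- ref_base_at(reference, df$pos + 1L)
    purine <- df$ref %in% c("A", "G")
    cls <- classify_substitution(df$ref, df$alt)
    u <- ifelse(purine, complement_base(down), up)
    d <- ifelse(purine, complement_base(up), down)
    lab <- sprintf("%s[%s]%s", u, cls, d)
    tab <- table(factor(lab, levels = names(counts)))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = c("trinuc_spectrum", "integer"),
            n_excluded = excluded)
}
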