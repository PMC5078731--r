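#' Generate a random reference contig
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction. The contig
#' is the substrate for mutation placement and for motif-context analysis,
#' which uses a 41-nucleotide window centred on each mutated base; sequences
#' shorter than 41 bases are therefore rejected.
#'
#' @param length Sequence length in bases (>= 41).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same contig.
#' @param name Contig name used in all downstream coordinates.
#' @return An object of class `reference_contig`: a list with elements
#'   `name` and `sequence` (a single character string over ACGT).
#' @export
#' @examples
#' ref <- generate_reference(1000, 0.4, seed = 1)
#' nchar(ref$sequence)
generate_reference <- function(length, gc_fraction, seed, name = "chrS") {
  if (!is_count(length) || length < 41) {
    stop_msclone("reference length must be >= 41 (41-nt context window undefined below that); got %s", length)
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop_msclone("gc_fraction must lie strictly between 0 and 1")
  }
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- withr::with_seed(seed, paste(
    sample(BASES, length, replace = TRUE, prob = p), collapse = ""))
  structure(list(name = name, sequence = seq), class = "reference_contig")
}

#' @export
print.reference_contig <- function(x, ...) {
  n <- nchar(x$sequence)
  gc <- ref_base_counts(x)
  cat(sprintf("<reference_contig> %s: %d bp, GC %.3f\n", x$name, n,
              (gc[["C"]] + gc[["G"]]) / n))
  invisible(x)
}

ref_base_counts <- function(reference) {
  tab <- table(strsplit(reference$sequence, "")[[1]])
  counts <- setNames(integer(4), BASES)
  counts[names(tab)] <- as.integer(tab)
  counts
}

ref_base_at <- function(reference, pos) {
  substring(reference$sequence, pos, pos)
}

# Positions (1-based) whose reference base is one of `bases`.
ref_positions_of <- function(reference, bases) {
  which(strsplit(reference$sequence, "")[[1]] %in% bases)
}

# TRUE for each position that sits in an APOBEC target motif on either
# strand: a C preceded by T and followed by W (TpCpW), or a G preceded by W
# and followed by A (WpGpA, the reverse-complement image of TCW).
in_tcw_motif <- function(reference, pos) {
  n <- nchar(reference$sequence)
  base <- ref_base_at(reference, pos)
  prev <- ifelse(pos > 1, ref_base_at(reference, pos - 1), "")
  nxt <- ifelse(pos < n, ref_base_at(reference, pos + 1), "")
  (base == "C" & prev == "T" & nxt %in% c("A", "T")) |
    (base == "G" & nxt == "A" & prev %in% c("A", "T"))
}

#' Reverse-complement a reference contig
#'
#' Returns the opposite-strand view of a contig. Position `p` on the input
#' maps to `length - p + 1` on the output. Used mainly to check
#' strand-symmetry of spectrum and motif statistics.
#'
#' @param reference A `reference_contig`.
#' @return A `reference_contig` holding the reverse-complemented sequence.
#' @export
revcomp_reference <- function(reference) {
  structure(list(name = reference$name, sequence = revcomp(reference$sequence)),
            class = "reference_contig")
}
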