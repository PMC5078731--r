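#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov cor cor.test dhyper fisher.test median quantile
#'   rbeta rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table
NULL

# Single place for the six pyrimidine-normalised substitution classes.
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x Character vector of DNA strings over `{A,C,G,T}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TCA") # "TGA"
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) unname(COMPLEMENT[x])

stop_msclone <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
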