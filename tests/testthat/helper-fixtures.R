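# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the package's own writers.

# A reference contig from a literal sequence (pads with A to the 41-base
# minimum when asked).
literal_reference <- function(seq, name = "chrT", pad_to = 41L) {
  if (nchar(seq) < pad_to) {
    seq <- paste0(seq, strrep("A", pad_to - nchar(seq)))
  }
  structure(list(name = name, sequence = seq), class = "reference_contig")
}

# An SNV table whose records all pass every filter unless overridden.
passing_snvs <- function(n = 1L, contig = "chrT", pos = seq_len(n), ref = "C",
                         alt = "A", ...) {
  args <- list(contig = contig, pos = pos, ref = ref, alt = alt,
               depth_tumor = 50L, depth_normal = 50L, vaf_tumor = 0.4,
               vaf_normal = 0, both_strands = TRUE, dbsnp = FALSE,
               somatic_p = 1e-8, caller = "mutect,varscan")
  over <- list(...)
  args[names(over)] <- over
  do.call(snv_record, args)
}

# A callset holding `keys` (strings "pos:REF>ALT" or plain positions).
callset_with_keys <- function(sample_id, positions, patient_id = "P1",
                              ref = "C", alt = "A", ...) {
  callset(sample_id, patient_id,
          snvs = passing_snvs(length(positions), pos = positions, ref = ref,
                              alt = alt, ...))
}

# Random record tables spanning the filter decision boundaries.
random_snvs <- function(n, seed) {
  withr::with_seed(seed, snv_record(
    contig = "chrT", pos = seq_len(n),
    ref = sample(c("C", "T"), n, TRUE), alt = "A" ,
    depth_tumor = sample(0:25, n, TRUE),
    depth_normal = sample(0:20, n, TRUE),
    vaf_tumor = runif(n, 0, 0.3),
    vaf_normal = sample(c(0, 0, 0, 0.01, 0.1), n, TRUE),
    both_strands = sample(c(TRUE, TRUE, FALSE), n, TRUE),
    dbsnp = sample(c(FALSE, FALSE, FALSE, TRUE), n, TRUE),
    somatic_p = 10^runif(n, -8, -2),
    caller = "mutect,varscan"))
}

random_indels <- function(n, seed) {
  withr::with_seed(seed, indel_record(
    contig = "chrT", pos = seq_len(n), ref = "CA", alt = "C",
    depth_tumor = sample(2:10, n, TRUE),
    depth_normal = sample(2:10, n, TRUE),
    mismatch_rate_normal = runif(n, 0.2, 0.8),
    mismatch_rate_mutant = runif(n, 0.2, 0.8),
    mapq_normal = runif(n, 15, 30),
    mapq_mutant = runif(n, 15, 30),
    median_end_offset = sample(2:10, n, TRUE)))
}

random_svs <- function(n, seed) {
  withr::with_seed(seed, {
    total <- sample(2:9, n, TRUE)
    end_a <- vapply(total, function(t) sample(0:t, 1), integer(1))
    end_b <- vapply(total, function(t) sample(0:t, 1), integer(1))
    sv_record(contig_a = "chrT", pos_a = seq_len(n), contig_b = "chrT",
              pos_b = seq_len(n) + 5000L, sv_type = "DEL",
              clipped_reads_total = total, clipped_reads_end_a = end_a,
              clipped_reads_end_b = end_b)
  })
}

# Reverse-complement an SNV table onto the opposite strand of `reference`.
revcomp_calls <- function(snvs, reference) {
  n <- nchar(reference$sequence)
  out <- snvs
  out$pos <- n - snvs$pos + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out$ref <- unname(comp[snvs$ref])
  out$alt <- unname(comp[snvs$alt])
  out
}

# Independently written two-sided Fisher oracle: exhaustive hypergeometric
# enumeration with the minimum-likelihood rule (relative tolerance as in
# the conventional implementation).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0) stop("empty table")
  x <- max(0, k - n2):min(k, m)
  p <- dhyper(x, m, n2, k)
  sum(p[p <= dhyper(a, m, n2, k) * (1 + 1e-7)])
}

default_cohort_ref <- function() cohort_reference(111L, 437L, 20L, 8413L)
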