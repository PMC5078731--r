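#' Construct a per-tumour somatic call set
#'
#' A call set bundles all filtered (or to-be-filtered) somatic events of one
#' tumour sample: SNVs, small indels and structural variants, plus the sample
#' metadata carried through every downstream analysis.
#'
#' @param sample_id Sample identifier, unique within a cohort.
#' @param patient_id Patient identifier.
#' @param smoking Smoking status, `"never"` or `"former"`.
#' @param snvs Data frame of SNV records (see [snv_record()] for columns).
#' @param indels Data frame of indel records; zero rows allowed.
#' @param svs Data frame of structural-variant records; zero rows allowed.
#' @return An object of class `callset`.
#' @export
callset <- function(sample_id, patient_id, smoking = "never",
                    snvs = empty_snv_df(), indels = empty_indel_df(),
                    svs = empty_sv_df()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  smoking <- match.arg(smoking, c("never", "former"))
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 smoking = smoking, snvs = snvs, indels = indels, svs = svs),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %s (patient %s, %s smoker): %d SNVs, %d indels, %d SVs\n",
              x$sample_id, x$patient_id, x$smoking,
              nrow(x$snvs), nrow(x$indels), nrow(x$svs)))
  invisible(x)
}

#' Build SNV records
#'
#' Vectorised constructor for the SNV table used throughout the package.
#' One row per somatic single-nucleotide call.
#'
#' @param contig,pos,ref,alt Coordinates (1-based) and alleles.
#' @param depth_tumor,depth_normal Total read depths.
#' @param vaf_tumor,vaf_normal Variant allele fractions in `[0, 1]`.
#' @param both_strands Logical; variant seen on both strands.
#' @param dbsnp Logical; position listed in the dbSNP build used as a panel.
#' @param somatic_p Somatic p-value reported by the VarScan-side caller.
#' @param caller Comma-separated subset of `"varscan","mutect"`.
#' @param effect One of `nonsynonymous`, `splice`, `synonymous`, `other`.
#' @param gene Gene symbol or `""`.
#' @param validated One of `validated`, `failed`, `not_tested`.
#' @return A data frame with one row per call.
#' @export
snv_record <- function(contig, pos, ref, alt, depth_tumor, depth_normal,
                       vaf_tumor, vaf_normal, both_strands = TRUE,
                       dbsnp = FALSE, somatic_p = NA_real_,
                       caller = "varscan,mutect", effect = "nonsynonymous",
                       gene = "", validated = "not_tested") {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   depth_tumor = as.integer(depth_tumor),
                   depth_normal = as.integer(depth_normal),
                   vaf_tumor = as.numeric(vaf_tumor),
                   vaf_normal = as.numeric(vaf_normal),
                   both_strands = as.logical(both_strands),
                   dbsnp = as.logical(dbsnp),
                   somatic_p = as.numeric(somatic_p),
                   caller = as.character(caller),
                   effect = as.character(effect),
                   gene = as.character(gene),
                   validated = as.character(validated),
                   stringsAsFactors = FALSE)
  bad <- df$ref == df$alt
  if (any(bad)) stop_msclone("ref == alt in SNV record(s) at row %s", which(bad)[1])
  if (any(df$pos < 1L)) stop_msclone("SNV positions must be >= 1")
  df
}

empty_snv_df <- function() snv_record(character(), integer(), character(),
                                      character(), integer(), integer(),
                                      numeric(), numeric(), logical(),
                                      logical(), numeric(), character(),
                                      character(), character(), character())

#' @rdname snv_record
#' @param mismatch_rate_normal,mismatch_rate_mutant Average per-allele
#'   mismatch rates.
#' @param mapq_normal,mapq_mutant Mean mapping qualities per allele.
#' @param median_end_offset Median distance of the indel from read ends (bp).
#' @export
indel_record <- function(contig, pos, ref, alt, depth_tumor, depth_normal,
                         mismatch_rate_normal, mismatch_rate_mutant,
                         mapq_normal, mapq_mutant, median_end_offset) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   depth_tumor = as.integer(depth_tumor),
                   depth_normal = as.integer(depth_normal),
                   mismatch_rate_normal = as.numeric(mismatch_rate_normal),
                   mismatch_rate_mutant = as.numeric(mismatch_rate_mutant),
                   mapq_normal = as.numeric(mapq_normal),
                   mapq_mutant = as.numeric(mapq_mutant),
                   median_end_offset = as.numeric(median_end_offset),
                   stringsAsFactors = FALSE)
  if (any(nchar(df$ref) == nchar(df$alt))) {
    stop_msclone("indel records require length-changing alleles")
  }
  df
}

empty_indel_df <- function() indel_record(character(), integer(), character(),
                                          character(), integer(), integer(),
                                          numeric(), numeric(), numeric(),
                                          numeric(), numeric())

#' @rdname snv_record
#' @param contig_a,pos_a,contig_b,pos_b Breakpoint pair coordinates.
#' @param sv_type One of `DEL`, `DUP`, `INV`, `TRA`.
#' @param clipped_reads_total Clipped reads spanning the breakpoint pair.
#' @param clipped_reads_end_a,clipped_reads_end_b Clipped-read support at
#'   each breakpoint end.
#' @export
sv_record <- function(contig_a, pos_a, contig_b, pos_b, sv_type,
                      clipped_reads_total, clipped_reads_end_a,
                      clipped_reads_end_b) {
  df <- data.frame(contig_a = as.character(contig_a), pos_a = as.integer(pos_a),
                   contig_b = as.character(contig_b), pos_b = as.integer(pos_b),
                   sv_type = as.character(sv_type),
                   clipped_reads_total = as.integer(clipped_reads_total),
                   clipped_reads_end_a = as.integer(clipped_reads_end_a),
                   clipped_reads_end_b = as.integer(clipped_reads_end_b),
                   stringsAsFactors = FALSE)
  if (any(df$clipped_reads_end_a > df$clipped_reads_total |
          df$clipped_reads_end_b > df$clipped_reads_total)) {
    stop_msclone("per-end clipped-read counts cannot exceed the total")
  }
  df
}

empty_sv_df <- function() sv_record(character(), integer(), character(),
                                    integer(), character(), integer(),
                                    integer(), integer())

#' Mutation identity keys
#'
#' A mutation is identified by (contig, position, ref allele, alt allele);
#' two tumours share a mutation when they carry the identical nucleotide
#' substitution at the same genomic coordinate.
#'
#' @param x A `callset` or an SNV data frame.
#' @return Character vector of keys `"contig:pos:ref>alt"`.
#' @export
mutation_keys <- function(x) {
  df <- if (inherits(x, "callset")) x$snvs else x
  if (nrow(df) == 0L) return(character())
  sprintf("%s:%d:%s>%s", df$contig, df$pos, df$ref, df$alt)
}
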