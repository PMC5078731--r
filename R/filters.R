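#' Post-caller somatic variant filters
#'
#' These functions implement the fixed rule sets applied on top of each
#' caller's built-in filtering. Thresholds follow the published criteria
#' exactly, including whether each comparison is strict or inclusive. All
#' filters are pure subset operations: rows are kept or dropped unchanged,
#' in input order.
#'
#' * VarScan-side SNVs: germline depth >= 10, tumour depth >= 4, tumour
#'   VAF >= 10%, somatic p-value < 1e-4 (strict).
#' * MuTect-side SNVs: tumour depth >= 15, germline depth >= 6, variant on
#'   both strands, tumour VAF >= 10%, germline VAF exactly 0, not in dbSNP.
#' * Indels: depth > 5 in both samples, per-allele mismatch rates < 0.5,
#'   per-allele mapping qualities > 20, median distance from read ends > 5 bp
#'   (all strict).
#' * Structural variants: >= 5 clipped reads spanning the breakpoint pair
#'   and >= 1 clipped read at each end.
#'
#' @param records SNV, indel or SV data frame (see [snv_record()]).
#' @return The subset of `records` passing the filter, order preserved.
#' @name variant_filters
NULL

#' @rdname variant_filters
#' @export
filter_snv_varscan <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$somatic_p)) {
    stop_msclone("somatic_p missing for record %s",
                 mutation_keys(records)[which(is.na(records$somatic_p))[1]])
  }
  keep <- records$depth_normal >= 10L &
    records$depth_tumor >= 4L &
    records$vaf_tumor >= 0.10 &
    records$somatic_p < 1e-4
  records[keep, , drop = FALSE]
}

#' @rdname variant_filters
#' @export
filter_snv_mutect <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- records$depth_tumor >= 15L &
    records$depth_normal >= 6L &
    records$both_strands &
    records$vaf_tumor >= 0.10 &
    records$vaf_normal == 0 &
    !records$dbsnp
  records[keep, , drop = FALSE]
}

#' @rdname variant_filters
#' @export
filter_indels <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- records$depth_tumor > 5L &
    records$depth_normal > 5L &
    records$mismatch_rate_normal < 0.5 &
    records$mismatch_rate_mutant < 0.5 &
    records$mapq_normal > 20 &
    records$mapq_mutant > 20 &
    records$median_end_offset > 5
  records[keep, , drop = FALSE]
}

#' @rdname variant_filters
#' @export
filter_svs <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- records$clipped_reads_total >= 5L &
    records$clipped_reads_end_a >= 1L &
    records$clipped_reads_end_b >= 1L
  records[keep, , drop = FALSE]
}

#' Combine SNV call lists from two callers
#'
#' Merges the VarScan-passing and MuTect-passing lists by mutation identity
#' (contig, position, ref, alt). Three modes are supported:
#'
#' * `union`: every identity called by either caller; duplicate identities
#'   are collapsed to one record with the caller sets merged.
#' * `intersection`: identities present in both lists.
#' * `expanded_confident`: the expanded high-confidence set — all validated
#'   mutations plus everything called by both callers.
#'
#' @param varscan_pass,mutect_pass SNV data frames that already passed the
#'   respective caller-side filters.
#' @param mode `"union"`, `"intersection"` or `"expanded_confident"`.
#' @param validated SNV data frame of validated mutations; required for
#'   `expanded_confident`.
#' @return SNV data frame; `caller` reflects the merged caller sets.
#' @export
combine_callsets <- function(varscan_pass, mutect_pass,
                             mode = c("union", "intersection",
                                      "expanded_confident"),
                             validated = NULL) {
  mode <- match.arg(mode)
  kv <- mutation_keys(varscan_pass)
  km <- mutation_keys(mutect_pass)

  merge_callers <- function(df, keys, extra_keys, extra_caller) {
    if (nrow(df) == 0L) return(df)
    hit <- keys %in% extra_keys
    df$caller[hit] <- vapply(df$caller[hit], function(x) {
      paste(sort(union(strsplit(x, ",")[[1]], extra_caller)), collapse = ",")
    }, character(1))
    df
  }

  if (mode == "union") {
    v <- merge_callers(varscan_pass, kv, km, "mutect")
    extra <- mutect_pass[!(km %in% kv), , drop = FALSE]
    out <- rbind(v, extra)
    return(out[!duplicated(mutation_keys(out)), , drop = FALSE])
  }

  inter <- merge_callers(varscan_pass[kv %in% km, , drop = FALSE],
                         kv[kv %in% km], km, "mutect")
  inter <- inter[!duplicated(mutation_keys(inter)), , drop = FALSE]
  if (mode == "intersection") return(inter)

  if (is.null(validated)) {
    stop_msclone("expanded_confident mode requires the validated mutation list")
  }
  out <- rbind(validated, inter)
  out[!duplicated(mutation_keys(out)), , drop = FALSE]
}

#' Apply all caller-side filters to a call set
#'
#' Convenience wrapper: splits a call set's SNVs by caller provenance,
#' applies the VarScan-side and MuTect-side rules, combines them (default:
#' union, as used for the primary analysis), and filters indels and SVs.
#'
#' @param cs A `callset`.
#' @param snv_mode Combination mode passed to [combine_callsets()].
#' @return A filtered `callset`.
#' @export
filter_callset <- function(cs, snv_mode = "union") {
  has_caller <- function(df, who) grepl(who, df$caller, fixed = TRUE)
  vs <- cs$snvs[has_caller(cs$snvs, "varscan"), , drop = FALSE]
  mu <- cs$snvs[has_caller(cs$snvs, "mutect"), , drop = FALSE]
  validated <- cs$snvs[cs$snvs$validated == "validated", , drop = FALSE]
  snvs <- combine_callsets(filter_snv_varscan(vs), filter_snv_mutect(mu),
                           mode = snv_mode,
                           validated = if (snv_mode == "expanded_confident")
                             validated else NULL)
  callset(cs$sample_id, cs$patient_id, cs$smoking, snvs = snvs,
          indels = filter_indels(cs$indels), svs = filter_svs(cs$svs))
}
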