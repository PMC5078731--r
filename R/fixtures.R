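# On-disk interchange formats. SNVs travel as VCF v4.2 with the package's
# INFO keys; indels/SVs and CN segments as tab-delimited tables; the
# reference as FASTA; ground truth as JSON.

VCF_INFO_KEYS <- c("DP_T", "DP_N", "VAF_T", "VAF_N", "BSTR", "DBSNP",
                   "SOMP", "CALLER", "EFFECT", "GENE", "VALSTAT")

vcf_header <- function(reference) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$name,
            nchar(reference$sequence)),
    "##INFO=<ID=DP_T,Number=1,Type=Integer,Description=\"Tumour read depth\">",
    "##INFO=<ID=DP_N,Number=1,Type=Integer,Description=\"Normal read depth\">",
    "##INFO=<ID=VAF_T,Number=1,Type=Float,Description=\"Tumour variant allele fraction\">",
    "##INFO=<ID=VAF_N,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "##INFO=<ID=BSTR,Number=1,Type=Integer,Description=\"Variant seen on both strands (0/1)\">",
    "##INFO=<ID=DBSNP,Number=1,Type=Integer,Description=\"Position in dbSNP panel (0/1)\">",
    "##INFO=<ID=SOMP,Number=1,Type=Float,Description=\"VarScan somatic p-value\">",
    "##INFO=<ID=CALLER,Number=.,Type=String,Description=\"Calling algorithms\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=VALSTAT,Number=1,Type=String,Description=\"Validation status\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

fmt_float <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.17g", x))
}

#' Write SNVs of a call set as VCF v4.2
#'
#' @param snvs SNV data frame (see [snv_record()]).
#' @param reference The `reference_contig` the coordinates refer to.
#' @param path Output file path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, reference, path) {
  info <- sprintf(
    "DP_T=%d;DP_N=%d;VAF_T=%s;VAF_N=%s;BSTR=%d;DBSNP=%d;SOMP=%s;CALLER=%s;EFFECT=%s;GENE=%s;VALSTAT=%s",
    snvs$depth_tumor, snvs$depth_normal, fmt_float(snvs$vaf_tumor),
    fmt_float(snvs$vaf_normal), as.integer(snvs$both_strands),
    as.integer(snvs$dbsnp), fmt_float(snvs$somatic_p), snvs$caller,
    snvs$effect, ifelse(snvs$gene == "", ".", snvs$gene), snvs$validated)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", snvs$contig, snvs$pos,
                  snvs$ref, snvs$alt, info)
  writeLines(c(vcf_header(reference), body), path)
  invisible(path)
}

#' Read SNVs from a VCF written by this package
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) carrying the package's INFO
#' keys back into an SNV data frame; the inverse of [write_snv_vcf()].
#'
#' @param path VCF file path.
#' @return SNV data frame.
#' @export
read_snv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) return(empty_snv_df())
  info_num <- function(key) as.numeric(vcfR::extract.info(vcf, element = key))
  info_chr <- function(key) as.character(vcfR::extract.info(vcf, element = key))
  gene <- info_chr("GENE")
  snv_record(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             depth_tumor = info_num("DP_T"), depth_normal = info_num("DP_N"),
             vaf_tumor = info_num("VAF_T"), vaf_normal = info_num("VAF_N"),
             both_strands = info_num("BSTR") == 1,
             dbsnp = info_num("DBSNP") == 1, somatic_p = info_num("SOMP"),
             caller = info_chr("CALLER"), effect = info_chr("EFFECT"),
             gene = ifelse(is.na(gene) | gene == ".", "", gene),
             validated = info_chr("VALSTAT"))
}

#' Read and write SEG-style copy-number tables
#'
#' Tab-delimited with columns `sample_id`, `contig`, `start`, `end`,
#' `log2_ratio`; 1-based inclusive coordinates.
#'
#' @param segments Segment data frame.
#' @param path File path.
#' @return The segments (read) or `path` invisibly (write).
#' @export
write_seg <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer",
                                  "integer", "numeric"))
  cn_segment(df$sample_id, df$contig, df$start, df$end, df$log2_ratio)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write a simulated cohort to disk
#'
#' Emits the reference FASTA, one VCF plus indel/SV tables per sample, one
#' pooled SEG table, the hotspot table, the sample metadata, the
#' ground-truth labels (JSON) and a manifest listing every file with its
#' MD5 checksum.
#'
#' @param cohort An `msclone_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame (`file`, `md5`), invisibly written to
#'   `manifest.json` as well.
#' @export
write_fixtures <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_msclone("cannot create output directory %s", dir)
  }
  ref <- cohort$reference
  fa <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(fa, file.path(dir, "reference.fasta"))
  files <- "reference.fasta"
  for (cs in cohort$callsets) {
    v <- sprintf("%s.vcf", cs$sample_id)
    write_snv_vcf(cs$snvs, ref, file.path(dir, v))
    it <- sprintf("%s.indels.tsv", cs$sample_id)
    write_tsv(cs$indels, file.path(dir, it))
    st <- sprintf("%s.svs.tsv", cs$sample_id)
    write_tsv(cs$svs, file.path(dir, st))
    files <- c(files, v, it, st)
  }
  write_seg(cohort$segments, file.path(dir, "cohort.seg"))
  write_tsv(cohort$hotspots, file.path(dir, "hotspots.tsv"))
  write_tsv(cohort$sample_info, file.path(dir, "samples.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  files <- c(files, "cohort.seg", "hotspots.tsv", "samples.tsv", "truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  invisible(manifest)
}

#' Read a cohort back from a fixture directory
#'
#' Inverse of [write_fixtures()] (the simulation config is not recoverable
#' and is left `NULL`).
#'
#' @param dir Directory written by [write_fixtures()].
#' @return An `msclone_cohort`.
#' @export
read_cohort <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  reference <- structure(list(name = names(fa)[1],
                              sequence = as.character(fa[[1]])),
                         class = "reference_contig")
  info <- read_tsv(file.path(dir, "samples.tsv"))
  callsets <- lapply(seq_len(nrow(info)), function(i) {
    sid <- info$sample_id[i]
    callset(sid, info$patient_id[i], info$smoking[i],
            snvs = read_snv_vcf(file.path(dir, sprintf("%s.vcf", sid))),
            indels = read_indel_tsv(file.path(dir, sprintf("%s.indels.tsv", sid))),
            svs = read_sv_tsv(file.path(dir, sprintf("%s.svs.tsv", sid))))
  })
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  hs <- read_tsv(file.path(dir, "hotspots.tsv"),
                 colClasses = c("character", "integer", "character",
                                "character", "character", "character"))
  structure(list(reference = reference, callsets = callsets,
                 segments = read_seg(file.path(dir, "cohort.seg")),
                 truth = truth, hotspots = hs, sample_info = info,
                 config = NULL),
            class = "msclone_cohort")
}

read_indel_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c("character", "integer", "character",
                                      "character", "integer", "integer",
                                      "numeric", "numeric", "numeric",
                                      "numeric", "numeric"))
  if (nrow(df) == 0L) return(empty_indel_df())
  do.call(indel_record, df)
}

read_sv_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c("character", "integer", "character",
                                      "integer", "character", "integer",
                                      "integer", "integer"))
  if (nrow(df) == 0L) return(empty_sv_df())
  do.call(sv_record, df)
}
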