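#' Pipeline run configuration
#'
#' Either a simulation configuration or a fixture directory must be given
#' (not neither): the pipeline analyses simulated cohorts and on-disk
#' cohorts through exactly the same code path.
#'
#' @param sim A [sim_config()], or `NULL` when reading real inputs.
#' @param input_dir Fixture directory (see [write_fixtures()]), or `NULL`.
#' @param out_dir Output directory for reports and intermediates; `NULL`
#'   disables writing.
#' @param reference_length,gc_fraction Reference parameters used when
#'   simulating.
#' @param cohort External-cohort reference counts for the
#'   single-shared-mutation branch of [classify_pair()]; defaults to the
#'   published sharing rate among unrelated lung adenocarcinomas (20 shared
#'   of 8,413 exonic mutations) and hotspot prevalence (111 of 437).
#' @param policy A [classify_policy()].
#' @param snv_mode Caller-combination mode (see [combine_callsets()]).
#' @param cn_percentile Background percentile for
#'   [relatedness_from_background()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL, out_dir = NULL,
                       reference_length = 100000L, gc_fraction = 0.4,
                       cohort = cohort_reference(111L, 437L, 20L, 8413L),
                       policy = classify_policy(), snv_mode = "union",
                       cn_percentile = 0.95) {
  if (is.null(sim) && is.null(input_dir)) {
    stop_msclone("run_config needs either a sim_config or an input_dir")
  }
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 reference_length = as.integer(reference_length),
                 gc_fraction = gc_fraction, cohort = cohort, policy = policy,
                 snv_mode = snv_mode, cn_percentile = cn_percentile),
            class = "run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full relatedness pipeline
#'
#' Composes the analysis stages in order: cohort acquisition (simulation or
#' fixture input), post-caller variant filtering, pairwise shared-mutation
#' clonality classification, mutation-spectrum and APOBEC enrichment
#' analysis, and copy-number correlation against the inter-patient
#' background. One report per patient is produced; the overall verdict is
#' `contains_metastasis` as soon as any pair is clonally related,
#' `all_independent` when every pair is independent, and
#' `mixed_indeterminate` otherwise.
#'
#' @param config A [run_config()].
#' @return List of per-patient reports (class `patient_report`), with the
#'   cohort and CN assessment attached as attributes; written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$input_dir)) {
    log_stage("input", "reading cohort from %s", config$input_dir)
    cohort <- read_cohort(config$input_dir)
  } else {
    log_stage("simulate", "%d patients, seed %d", config$sim$n_patients,
              config$sim$seed)
    reference <- generate_reference(config$reference_length,
                                    config$gc_fraction,
                                    seed = config$sim$seed)
    cohort <- simulate_cohort(config$sim, reference)
  }

  log_stage("filter", "filtering %d call sets (%s mode)",
            length(cohort$callsets), config$snv_mode)
  filtered <- lapply(cohort$callsets, filter_callset,
                     snv_mode = config$snv_mode)
  names(filtered) <- vapply(filtered, `[[`, "", "sample_id")

  log_stage("cna", "building region matrix from %d segments",
            nrow(cohort$segments))
  cn_assessment <- NULL
  if (nrow(cohort$segments) > 0L &&
      length(unique(cohort$sample_info$patient_id)) >= 2L) {
    mat <- build_region_matrix(cohort$segments)
    sp <- setNames(cohort$sample_info$patient_id,
                   cohort$sample_info$sample_id)
    cn_assessment <- relatedness_from_background(mat, sp,
                                                 config$cn_percentile)
  }

  reports <- lapply(split(seq_along(filtered),
                          cohort$sample_info$patient_id), function(idx) {
    patient_report(filtered[idx], cohort, config, cn_assessment)
  })
  reports <- reports[order(names(reports))]

  if (!is.null(config$out_dir)) {
    render_report(reports, format = "json", dir = config$out_dir)
    render_report(reports, format = "text", dir = config$out_dir)
    render_report(reports, format = "tsv", dir = config$out_dir)
  }
  attr(reports, "cn_assessment") <- cn_assessment
  attr(reports, "cohort") <- cohort
  reports
}

patient_report <- function(callsets, cohort, config, cn_assessment) {
  pid <- callsets[[1]]$patient_id
  log_stage("clonality", "patient %s (%d tumours)", pid, length(callsets))
  sm <- sharing_matrix(callsets)
  pairs <- utils::combn(length(callsets), 2, simplify = FALSE)
  calls <- lapply(pairs, function(ij) {
    classify_pair(callsets[[ij[1]]], callsets[[ij[2]]],
                  hotspots = cohort$hotspots, cohort = config$cohort,
                  policy = config$policy)
  })
  spectra <- lapply(callsets, spectrum_counts)
  apobec <- lapply(callsets, function(cs) {
    rep <- tryCatch(apobec_report(cohort$reference, cs),
                    error = function(e) NULL)
    if (is.null(rep)) list(e_tcw = NA_real_, p_value = NA_real_)
    else rep[c("e_tcw", "p_value")]
  })
  names(spectra) <- names(apobec) <- vapply(callsets, `[[`, "", "sample_id")
  spec_cmp <- lapply(pairs, function(ij) {
    a <- spectra[[ij[1]]]; b <- spectra[[ij[2]]]
    p <- tryCatch(compare_spectra(a, b), error = function(e) NA_real_)
    r <- tryCatch(suppressWarnings(spectrum_correlation(a, b)),
                  error = function(e) NA_real_)
    list(pair = c(names(spectra)[ij[1]], names(spectra)[ij[2]]),
         p_difference = p, pearson_r = r)
  })
  p_raw <- vapply(spec_cmp, function(x) x$p_difference, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  for (i in seq_along(spec_cmp)) spec_cmp[[i]]$p_adjusted_bh <- p_adj[i]

  verdicts <- vapply(calls, `[[`, "", "verdict")
  overall <- if (any(verdicts == "clonally_related")) "contains_metastasis"
             else if (all(verdicts == "independent")) "all_independent"
             else "mixed_indeterminate"

  cn_pairs <- NULL
  if (!is.null(cn_assessment)) {
    cn_pairs <- cn_assessment$pairs[cn_assessment$pairs$patient == pid, ,
                                    drop = FALSE]
  }
  structure(list(patient_id = pid, relationship_calls = calls,
                 sharing = sm, spectra = spectra,
                 spectrum_comparisons = spec_cmp, apobec = apobec,
                 cn_pairs = cn_pairs, overall_verdict = overall),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s: %s\n", x$patient_id, x$overall_verdict))
  for (rc in x$relationship_calls) {
    cat(sprintf("  %s vs %s: %s (shared %d)\n", rc$pair[1], rc$pair[2],
                rc$verdict, rc$shared_total))
  }
  invisible(x)
}

report_to_list <- function(r) {
  list(patient_id = r$patient_id,
       overall_verdict = r$overall_verdict,
       relationship_calls = lapply(r$relationship_calls, unclass),
       sharing = list(samples = r$sharing$samples,
                      matrix = r$sharing$shared),
       spectra = lapply(r$spectra, function(s) as.list(unclass(s))),
       spectrum_comparisons = r$spectrum_comparisons,
       apobec = r$apobec,
       cn_pairs = r$cn_pairs)
}

#' Render patient reports to files
#'
#' @param reports List of `patient_report` objects.
#' @param format `"json"`, `"text"` or `"tsv"` (sharing matrices, totals
#'   on the diagonal).
#' @param dir Output directory.
#' @return Character vector of files written.
#' @export
render_report <- function(reports, format = c("json", "text", "tsv"), dir) {
  if (!length(reports)) stop_msclone("render_report: no reports")
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  if (format == "json") {
    path <- file.path(dir, "reports.json")
    jsonlite::write_json(lapply(reports, report_to_list), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- path
  } else if (format == "text") {
    path <- file.path(dir, "reports.txt")
    txt <- unlist(lapply(reports, function(r) {
      c(sprintf("Patient %s: %s", r$patient_id, r$overall_verdict),
        vapply(r$relationship_calls, function(rc) {
          sprintf("  %s vs %s: %s (shared %d, non-hotspot %d, fraction %.3f)",
                  rc$pair[1], rc$pair[2], rc$verdict, rc$shared_total,
                  rc$shared_non_hotspot, rc$shared_fraction)
        }, character(1)), "")
    }))
    writeLines(txt, path)
    files <- path
  } else {
    for (r in reports) {
      path <- file.path(dir, sprintf("sharing_%s.tsv", r$patient_id))
      m <- r$sharing$shared
      write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, path)
    }
  }
  invisible(files)
}

#' Associations between mutation burden and clinical covariates
#'
#' One-way analysis of variance for categorical covariates (e.g. sex,
#' smoking status) and Pearson product-moment correlation for numeric
#' covariates (e.g. age, tumour size), applied to per-sample mutation
#' burden.
#'
#' @param data Data frame with a numeric `burden` column plus covariates.
#' @param covariates Character vector of column names to test; defaults to
#'   every column except `burden` and `sample_id`.
#' @return Data frame with covariate, test type, statistic, and p-value;
#'   degenerate covariates (fewer than 2 levels or fewer than 3
#'   observations per group) are flagged `not_testable`.
#' @export
burden_associations <- function(data, covariates = NULL) {
  covariates <- covariates %||%
    setdiff(names(data), c("burden", "sample_id", "patient_id"))
  rows <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2L) {
        return(data.frame(covariate = cv, test = "pearson",
                          statistic = NA_real_, p_value = NA_real_,
                          status = "not_testable"))
      }
      ct <- stats::cor.test(data$burden, x)
      data.frame(covariate = cv, test = "pearson",
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 status = "ok")
    } else {
      grp <- factor(x)
      if (nlevels(grp) < 2L || min(table(grp)) < 3L) {
        return(data.frame(covariate = cv, test = "anova",
                          statistic = NA_real_, p_value = NA_real_,
                          status = "not_testable"))
      }
      fit <- summary(stats::aov(data$burden ~ grp))[[1]]
      data.frame(covariate = cv, test = "anova",
                 statistic = fit[["F value"]][1],
                 p_value = fit[["Pr(>F)"]][1], status = "ok")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
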