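#' Copy-number segment table constructor
#'
#' Segment-level log2 tumour/normal ratios, 1-based inclusive coordinates.
#'
#' @param sample_id,contig,start,end,log2_ratio Column vectors.
#' @return Data frame of segments.
#' @export
cn_segment <- function(sample_id, contig, start, end, log2_ratio) {
  df <- data.frame(sample_id = as.character(sample_id),
                   contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   log2_ratio = as.numeric(log2_ratio),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop_msclone("segment start > end")
  df
}

#' Call copy-number gains and losses from segment log2 ratios
#'
#' A segment is a gain when its log2 ratio is strictly greater than
#' `gain_threshold` (default +0.3) and a loss when strictly less than
#' `loss_threshold` (default -0.3); everything else is neutral.
#'
#' @param segments Segment data frame (see [cn_segment()]).
#' @param gain_threshold,loss_threshold Log2-ratio thresholds.
#' @return `segments` with an added `call` column in
#'   `{gain, loss, neutral}`.
#' @export
call_gain_loss <- function(segments, gain_threshold = 0.3,
                           loss_threshold = -0.3) {
  if (loss_threshold >= 0 || gain_threshold <= 0) {
    stop_msclone("need loss_threshold < 0 < gain_threshold")
  }
  segments$call <- ifelse(segments$log2_ratio > gain_threshold, "gain",
                          ifelse(segments$log2_ratio < loss_threshold,
                                 "loss", "neutral"))
  segments
}

check_no_overlap <- function(segments) {
  by_sc <- split(segments, list(segments$sample_id, segments$contig),
                 drop = TRUE)
  for (grp in by_sc) {
    grp <- grp[order(grp$start), , drop = FALSE]
    if (nrow(grp) > 1L && any(grp$start[-1] <= grp$end[-nrow(grp)])) {
      stop_msclone("overlapping segments within sample %s on %s",
                   grp$sample_id[1], grp$contig[1])
    }
  }
  invisible(TRUE)
}

#' Partition segments into breakpoint-union regions
#'
#' Splits the genome at the union of all samples' segment breakpoints, so
#' every sample's profile is constant within each region. The result is
#' the minimal tiling covering the union of all input spans: sorted,
#' non-overlapping, and such that every input segment is a union of
#' consecutive regions.
#'
#' @param segments Segment data frame pooled across samples; segments of
#'   one sample must not overlap.
#' @return Data frame of regions (`contig`, `start`, `end`).
#' @export
partition_regions <- function(segments) {
  check_no_overlap(segments)
  out <- lapply(split(segments, segments$contig), function(grp) {
    d <- IRanges::disjoin(IRanges::IRanges(grp$start, grp$end))
    data.frame(contig = grp$contig[1], start = IRanges::start(d),
               end = IRanges::end(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-by-sample copy-number matrix
#'
#' Fills each (region, sample) cell with the log2 ratio of the sample's
#' segment containing that region. Regions not covered by a sample are
#' `NA` in the value matrix and flagged in the mask.
#'
#' @param segments Segment data frame pooled across samples.
#' @param regions Regions from [partition_regions()]; computed if missing.
#' @return Object of class `cn_region_matrix`: list with `regions`,
#'   `values` (regions x samples, `NA` where uncovered) and `mask`
#'   (`TRUE` where covered).
#' @export
build_region_matrix <- function(segments, regions = NULL) {
  if (is.null(regions)) regions <- partition_regions(segments)
  samples <- sort(unique(segments$sample_id))
  vals <- matrix(NA_real_, nrow(regions), length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    for (ct in unique(seg$contig)) {
      ridx <- which(regions$contig == ct)
      if (!length(ridx)) next
      segc <- seg[seg$contig == ct, , drop = FALSE]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(regions$start[ridx], regions$end[ridx]),
        IRanges::IRanges(segc$start, segc$end))
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      # by construction each region lies inside at most one segment/sample
      stopifnot(!anyDuplicated(qh))
      vals[ridx[qh], s] <- segc$log2_ratio[sh]
    }
  }
  structure(list(regions = regions, values = vals, mask = !is.na(vals)),
            class = "cn_region_matrix")
}

#' @export
print.cn_region_matrix <- function(x, ...) {
  cat(sprintf("<cn_region_matrix> %d regions x %d samples (%.1f%% covered)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Pairwise copy-number profile correlation
#'
#' Pearson correlation of two samples' region-level log2 ratios. Regions
#' uncovered in either sample are dropped pairwise (rather than
#' zero-filled, which would inflate correlation). Optionally weights
#' regions by their length.
#'
#' @param matrix A `cn_region_matrix`.
#' @param pair Character vector of the two sample ids.
#' @param weighting `"none"` (default) or `"region_length"`.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when either
#'   profile is constant over the shared regions.
#' @export
pairwise_cn_correlation <- function(matrix, pair,
                                    weighting = c("none", "region_length")) {
  weighting <- match.arg(weighting)
  x <- matrix$values[, pair[1]]
  y <- matrix$values[, pair[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop_msclone("fewer than 3 shared covered regions for %s vs %s",
                                 pair[1], pair[2])
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant copy-number profile; correlation undefined (NA)")
    return(NA_real_)
  }
  if (weighting == "none") return(stats::cor(x, y))
  w <- (matrix$regions$end - matrix$regions$start + 1)[ok]
  cv <- stats::cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)
  cv$cor[1, 2]
}

#' Copy-number relatedness against an inter-patient background
#'
#' Builds the empirical background distribution of copy-number profile
#' correlations from all inter-patient sample pairs, then flags an
#' intra-patient pair as CN-related when its correlation strictly exceeds
#' the configured percentile of that background.
#'
#' @param matrix A `cn_region_matrix` covering the cohort.
#' @param sample_patient Named character vector mapping sample id to
#'   patient id.
#' @param percentile Background quantile an intra-patient correlation must
#'   exceed (default 0.95).
#' @param weighting Passed to [pairwise_cn_correlation()].
#' @return List with `background` (inter-patient correlations), `pairs`
#'   (data frame of intra-patient pairs with correlation and `cn_related`
#'   flag), `threshold`, and `degenerate` (`TRUE` when the background has
#'   no spread).
#' @export
relatedness_from_background <- function(matrix, sample_patient,
                                        percentile = 0.95,
                                        weighting = "none") {
  samples <- colnames(matrix$values)
  if (any(is.na(sample_patient[samples]))) {
    stop_msclone("sample_patient map is missing some samples of the matrix")
  }
  if (length(unique(sample_patient[samples])) < 2L) {
    stop_msclone("background requires samples from at least 2 patients")
  }
  pairs <- utils::combn(samples, 2L)
  cors <- apply(pairs, 2L, function(p)
    suppressWarnings(pairwise_cn_correlation(matrix, p, weighting)))
  intra <- sample_patient[pairs[1, ]] == sample_patient[pairs[2, ]]
  background <- cors[!intra]
  bg_ok <- background[!is.na(background)]
  degenerate <- length(bg_ok) == 0L || stats::sd(bg_ok) == 0
  # the 100th percentile is vacuous: nothing can strictly exceed it
  threshold <- if (percentile >= 1) Inf
  else if (length(bg_ok)) stats::quantile(bg_ok, percentile, names = FALSE)
  else NA_real_
  intra_df <- data.frame(sample_a = pairs[1, intra],
                         sample_b = pairs[2, intra],
                         patient = unname(sample_patient[pairs[1, intra]]),
                         correlation = cors[intra],
                         stringsAsFactors = FALSE)
  intra_df$cn_related <- !is.na(intra_df$correlation) &
    !is.na(threshold) & intra_df$correlation > threshold
  list(background = background, pairs = intra_df, threshold = threshold,
       percentile = percentile, degenerate = degenerate)
}

#' Merge adjacent same-call segments and annotate recurrent regions
#'
#' Within each sample, adjacent segments carrying the same gain/loss call
#' are merged. A merged segment is then annotated with a recurrent region
#' when it overlaps at least half (`min_overlap`, inclusive) of that
#' region's length and the call direction matches (`gain` with `amplified`,
#' `loss` with `lost`).
#'
#' @param called_segments Segments with a `call` column
#'   (see [call_gain_loss()]).
#' @param recurrent Data frame of recurrent regions with columns `contig`,
#'   `start`, `end`, `direction` (`amplified`/`lost`) and `label`.
#' @param min_overlap Minimum fraction of the recurrent region covered
#'   (default 0.5).
#' @return Merged segment data frame with an added `recurrent_label`
#'   column (comma-joined labels, `""` when none).
#' @export
annotate_recurrent <- function(called_segments, recurrent, min_overlap = 0.5) {
  merged <- do.call(rbind, lapply(
    split(called_segments,
          list(called_segments$sample_id, called_segments$contig),
          drop = TRUE),
    function(grp) {
      grp <- grp[order(grp$start), , drop = FALSE]
      run <- cumsum(c(TRUE, grp$call[-1] != grp$call[-nrow(grp)] |
                        grp$start[-1] != grp$end[-nrow(grp)] + 1L))
      do.call(rbind, lapply(split(grp, run), function(g) {
        data.frame(sample_id = g$sample_id[1], contig = g$contig[1],
                   start = min(g$start), end = max(g$end),
                   log2_ratio = sum(g$log2_ratio * (g$end - g$start + 1)) /
                     sum(g$end - g$start + 1),
                   call = g$call[1], stringsAsFactors = FALSE)
      }))
    }))
  rownames(merged) <- NULL
  merged$recurrent_label <- ""
  if (is.null(recurrent) || nrow(recurrent) == 0L) return(merged)
  dir_for_call <- c(gain = "amplified", loss = "lost")
  for (i in seq_len(nrow(merged))) {
    if (merged$call[i] == "neutral") next
    hit <- recurrent$contig == merged$contig[i] &
      recurrent$direction == dir_for_call[[merged$call[i]]]
    if (!any(hit)) next
    rr <- recurrent[hit, , drop = FALSE]
    ov <- pmax(0, pmin(merged$end[i], rr$end) -
                 pmax(merged$start[i], rr$start) + 1)
    frac <- ov / (rr$end - rr$start + 1)
    labs <- rr$label[frac >= min_overlap]
    merged$recurrent_label[i] <- paste(labs, collapse = ",")
  }
  merged
}
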