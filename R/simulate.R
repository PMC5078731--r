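#' Simulation configuration for a synthetic multi-tumour cohort
#'
#' Defines the study conditions the generator emulates: patients carrying
#' two or three synchronous tumours that are either independent primaries
#' (no shared non-hotspot mutations, by construction) or contain a
#' primary/metastasis pair sharing a trunk fraction of mutations;
#' smoker-type (C>A-dominated) versus never-smoker (C>T-dominated)
#' substitution spectra; an APOBEC process preferentially hitting TpCpW
#' sites; recurrent hotspot mutations that can arise independently in
#' different tumours; read depths and VAFs spanning the variant-filter
#' boundaries; and segment-level copy-number profiles with shared versus
#' private gains and losses.
#'
#' Defaults mirror a six-patient cohort: 15 lung tumours of which one
#' patient additionally carries a nodal metastasis of its largest tumour
#' (trunk fraction 0.26), two former smokers, four never smokers.
#'
#' @param n_patients Number of patients.
#' @param tumors_per_patient Tumours per patient (2 or 3), recycled.
#' @param relationship `"independent"` or `"metastatic"` per patient,
#'   recycled. For a metastatic patient the last tumour is a metastasis of
#'   the second-to-last; all other pairs are independent.
#' @param trunk_fraction Probability that a founder mutation is truncal
#'   (shared by the metastasis); forced to 0 for independent patients.
#' @param n_mutations SNVs per tumour, recycled over patients.
#' @param smoking `"never"` or `"former"` per patient, recycled.
#' @param spectrum_weights List with elements `never` and `former`: six
#'   non-negative weights over `C>A, C>G, C>T, T>A, T>C, T>G` summing to 1.
#' @param apobec_intensity Target TCW fold-enrichment (>= 1) of the
#'   APOBEC-type substitutions (C>T and C>G at cytosines); 1 means
#'   motif-blind placement. The per-site sampling weight is solved from
#'   the reference's motif composition so that the realised enrichment
#'   matches this value.
#' @param hotspot_rate Probability that a tumour independently acquires
#'   each designated hotspot mutation.
#' @param n_hotspots Number of designated hotspot sites on the reference.
#' @param depth_model List with `mean_tumor`, `mean_normal` (Poisson
#'   means) and `vaf_shape1`, `vaf_shape2` (Beta parameters of the tumour
#'   VAF).
#' @param cn_model List controlling copy-number profiles: `n_bins`
#'   segments tiling the contig, `n_events` gain/loss events per tumour,
#'   `event_log2` magnitude, `noise_sd` per-segment noise, and
#'   `share_fraction` of events a metastasis inherits from its founder.
#' @param n_indels,n_svs Small indels and structural variants per tumour.
#' @param sv_share Deletions copied from founder to metastasis.
#' @param seed Integer master seed; per-patient streams are derived as
#'   `seed + patient_index` so each patient is independently reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 6L,
                       tumors_per_patient = c(3L, 2L, 2L, 2L, 3L, 3L),
                       relationship = c("metastatic", rep("independent", 5)),
                       trunk_fraction = 0.26,
                       n_mutations = 120L,
                       smoking = c("former", "never", "former", "never",
                                   "never", "never"),
                       spectrum_weights = default_spectrum_weights(),
                       apobec_intensity = 2,
                       hotspot_rate = 0.15,
                       n_hotspots = 2L,
                       depth_model = list(mean_tumor = 60, mean_normal = 60,
                                          vaf_shape1 = 6, vaf_shape2 = 14),
                       cn_model = list(n_bins = 200L, n_events = 6L,
                                       event_log2 = 0.8, noise_sd = 0.1,
                                       share_fraction = 0.8),
                       n_indels = 4L, n_svs = 8L, sv_share = 2L,
                       seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients > 0) {
    tumors_per_patient <- rep_len(as.integer(tumors_per_patient), n_patients)
    relationship <- rep_len(relationship, n_patients)
    smoking <- rep_len(smoking, n_patients)
    n_mutations <- rep_len(as.integer(n_mutations), n_patients)
  }
  if (!all(tumors_per_patient %in% 2:3)) {
    stop_msclone("tumors_per_patient must be 2 or 3")
  }
  if (!all(relationship %in% c("independent", "metastatic"))) {
    stop_msclone("relationship must be 'independent' or 'metastatic'")
  }
  for (w in spectrum_weights) {
    if (length(w) != 6L || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop_msclone("spectrum_weights must be 6 non-negative values summing to 1")
    }
  }
  if (trunk_fraction < 0 || trunk_fraction > 1) {
    stop_msclone("trunk_fraction must be in [0, 1]")
  }
  if (apobec_intensity < 1) stop_msclone("apobec_intensity must be >= 1")
  structure(list(n_patients = n_patients,
                 tumors_per_patient = tumors_per_patient,
                 relationship = relationship,
                 trunk_fraction = trunk_fraction,
                 n_mutations = n_mutations, smoking = smoking,
                 spectrum_weights = spectrum_weights,
                 apobec_intensity = apobec_intensity,
                 hotspot_rate = hotspot_rate, n_hotspots = n_hotspots,
                 depth_model = depth_model, cn_model = cn_model,
                 n_indels = as.integer(n_indels), n_svs = as.integer(n_svs),
                 sv_share = as.integer(sv_share), seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_spectrum_weights <- function() {
  list(never = c("C>A" = 0.10, "C>G" = 0.10, "C>T" = 0.45,
                 "T>A" = 0.08, "T>C" = 0.20, "T>G" = 0.07),
       former = c("C>A" = 0.45, "C>G" = 0.08, "C>T" = 0.22,
                  "T>A" = 0.08, "T>C" = 0.12, "T>G" = 0.05))
}

# Designated hotspot sites: deterministic scan of the reference for T bases
# (a T>G transversion analogous to the common EGFR L858R c.2573T>G), evenly
# spread along the contig and independent of any RNG state.
default_hotspots <- function(reference, n_hotspots) {
  if (n_hotspots == 0L) {
    return(hotspot_list(character(), integer(), character(), character(),
                        gene = character(), protein_change = character()))
  }
  t_pos <- ref_positions_of(reference, "T")
  t_pos <- t_pos[t_pos > 41 & t_pos < nchar(reference$sequence) - 41]
  idx <- round(seq(1, length(t_pos), length.out = n_hotspots + 2L))[
    seq_len(n_hotspots) + 1L]
  hotspot_list(contig = reference$name, pos = t_pos[idx], ref = "T",
               alt = "G", gene = sprintf("HS%d", seq_len(n_hotspots)),
               protein_change = sprintf("p.analog%d", seq_len(n_hotspots)))
}

# Per-site sampling weight giving the requested fold-enrichment at TCW.
# With a fraction f of C/G sites in motif and weight w on those sites, the
# expected in-motif fraction of placed mutations is wf / (wf + 1 - f); the
# estimator divides by the context availability ~ f, so solving
# wf/(wf+1-f) = intensity * f gives w = i(1-f) / (1 - i f). Requires
# i < 1/f; intensities approaching that bound are rejected.
tcw_site_weight <- function(intensity, motif_fraction) {
  f <- motif_fraction
  if (intensity == 1) return(1)
  if (intensity * f >= 0.95) {
    stop_msclone(paste0("apobec_intensity %.2f unattainable: only %.1f%% of ",
                        "C/G sites are in a TCW/WGA motif"),
                 intensity, 100 * f)
  }
  intensity * (1 - f) / (1 - intensity * f)
}

# Draw mutation sites for one tumour. `avail` is a logical vector over the
# reference marking positions still free within the patient.
draw_snv_sites <- function(n, weights, reference, avail, pos_cg, pos_ta,
                           tcw_flag, tcw_weight) {
  classes <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE, prob = weights)
  pos <- integer(n)
  is_c <- substr(classes, 1, 1) == "C"
  apo <- classes %in% c("C>G", "C>T")
  free_cg <- avail[pos_cg]
  cg_pool <- pos_cg[free_cg]
  cg_w <- ifelse(tcw_flag[free_cg], tcw_weight, 1)
  n_apo <- sum(apo)
  if (n_apo > 0L) {
    if (length(cg_pool) < n_apo) stop_msclone("reference too short for requested mutation count")
    picked <- if (tcw_weight == 1) {
      sample(length(cg_pool), n_apo)
    } else {
      # weighted sampling without replacement via exponential keys
      order(stats::rexp(length(cg_pool)) / cg_w)[seq_len(n_apo)]
    }
    pos[apo] <- cg_pool[picked]
    cg_pool <- cg_pool[-picked]
  }
  n_ca <- sum(is_c & !apo)
  if (n_ca > 0L) {
    if (length(cg_pool) < n_ca) stop_msclone("reference too short for requested mutation count")
    pos[is_c & !apo] <- cg_pool[sample(length(cg_pool), n_ca)]
  }
  n_t <- sum(!is_c)
  if (n_t > 0L) {
    ta_pool <- pos_ta[avail[pos_ta]]
    if (length(ta_pool) < n_t) stop_msclone("reference too short for requested mutation count")
    pos[!is_c] <- ta_pool[sample(length(ta_pool), n_t)]
  }
  ref <- ref_base_at(reference, pos)
  target_alt <- substr(classes, 3, 3)
  alt <- ifelse(ref %in% c("C", "T"), target_alt, complement_base(target_alt))
  list(pos = pos, ref = ref, alt = alt)
}

# Sequencing-evidence fields drawn around the variant-filter boundaries.
draw_snv_evidence <- function(n, depth_model) {
  data.frame(
    depth_tumor = rpois(n, depth_model$mean_tumor),
    depth_normal = rpois(n, depth_model$mean_normal),
    vaf_tumor = rbeta(n, depth_model$vaf_shape1, depth_model$vaf_shape2),
    vaf_normal = ifelse(runif(n) < 0.95, 0, runif(n, 0, 0.03)),
    both_strands = runif(n) < 0.97,
    dbsnp = runif(n) < 0.02,
    somatic_p = 10^runif(n, -12, -3),
    caller = sample(c("mutect,varscan", "varscan", "mutect"), n,
                    replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    effect = sample(c("nonsynonymous", "splice", "synonymous", "other"), n,
                    replace = TRUE, prob = c(0.75, 0.05, 0.15, 0.05)),
    validated = sample(c("validated", "failed", "not_tested"), n,
                       replace = TRUE, prob = c(0.60, 0.03, 0.37)),
    stringsAsFactors = FALSE)
}

make_snv_df <- function(reference, sites, evidence, gene = "") {
  if (length(sites$pos) == 0L) return(empty_snv_df())
  snv_record(contig = reference$name, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, depth_tumor = evidence$depth_tumor,
             depth_normal = evidence$depth_normal,
             vaf_tumor = evidence$vaf_tumor,
             vaf_normal = evidence$vaf_normal,
             both_strands = evidence$both_strands, dbsnp = evidence$dbsnp,
             somatic_p = evidence$somatic_p, caller = evidence$caller,
             effect = evidence$effect, gene = gene,
             validated = evidence$validated)
}

draw_indels <- function(reference, n, avail) {
  if (n == 0L) return(empty_indel_df())
  pool <- which(avail)
  pool <- pool[pool < nchar(reference$sequence)]
  pos <- sort(sample(pool, n))
  ins <- runif(n) < 0.5
  ref <- ifelse(ins, ref_base_at(reference, pos),
                paste0(ref_base_at(reference, pos),
                       ref_base_at(reference, pos + 1L)))
  alt <- ifelse(ins, paste0(ref_base_at(reference, pos),
                            sample(BASES, n, replace = TRUE)),
                ref_base_at(reference, pos))
  indel_record(contig = reference$name, pos = pos, ref = ref, alt = alt,
               depth_tumor = rpois(n, 12), depth_normal = rpois(n, 12),
               mismatch_rate_normal = rbeta(n, 2, 8),
               mismatch_rate_mutant = rbeta(n, 2, 8),
               mapq_normal = pmax(0, rnorm(n, 40, 12)),
               mapq_mutant = pmax(0, rnorm(n, 40, 12)),
               median_end_offset = rpois(n, 12))
}

draw_svs <- function(reference, n) {
  if (n == 0L) return(empty_sv_df())
  len <- nchar(reference$sequence)
  pos_a <- sample(len, n)
  pos_b <- pmin(len, pos_a + sample(1000:10000, n, replace = TRUE))
  total <- rpois(n, 8)
  end_a <- rbinom(n, total, 0.5)
  sv_record(contig_a = reference$name, pos_a = pos_a,
            contig_b = reference$name, pos_b = pos_b,
            sv_type = sample(c("DEL", "DUP", "INV"), n, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)),
            clipped_reads_total = total, clipped_reads_end_a = end_a,
            clipped_reads_end_b = total - end_a)
}

# Copy-number profile over a fixed tiling of the contig. Events are runs of
# consecutive bins shifted by +/- event_log2; `inherit` passes a founder's
# events to its metastasis.
draw_cn_profile <- function(reference, sample_id, cn, inherit = NULL) {
  len <- nchar(reference$sequence)
  width <- floor(len / cn$n_bins)
  start <- (seq_len(cn$n_bins) - 1L) * width + 1L
  end <- c(start[-1L] - 1L, len)
  shift <- numeric(cn$n_bins)
  n_new <- cn$n_events - length(inherit)
  events <- inherit %||% list()
  for (i in seq_len(max(0L, n_new))) {
    w <- sample(3:10, 1)
    s <- sample(cn$n_bins - w, 1)
    events <- c(events, list(list(bins = s:(s + w - 1L),
                                  shift = sample(c(-1, 1), 1) * cn$event_log2)))
  }
  for (ev in events) shift[ev$bins] <- shift[ev$bins] + ev$shift
  list(segments = cn_segment(sample_id, reference$name, start, end,
                             rnorm(cn$n_bins, 0, cn$noise_sd) + shift),
       events = events)
}

#' Simulate all tumours of one patient
#'
#' Generates the call sets, copy-number segment tables and ground-truth
#' labels for one patient under a [sim_config()]. For a metastatic patient
#' the last tumour is a metastasis of the second-to-last: each founder
#' mutation is truncal with probability `trunk_fraction` and truncal
#' mutations are copied identically (same contig, position, ref and alt)
#' into the metastasis, which is then topped up with fresh private
#' mutations so every tumour carries exactly `n_mutations` SNVs. Mutation
#' sites never collide between tumours of a patient except by truncal
#' copying or independent hotspot acquisition.
#'
#' @param config A [sim_config()].
#' @param reference A `reference_contig` from [generate_reference()].
#' @param patient_index 1-based patient number; the patient's RNG stream is
#'   seeded with `config$seed + patient_index`.
#' @return List with `callsets` (list of `callset`), `segments` (CN
#'   segment data frame), `truth` (per-pair truth labels with truncal
#'   keys), and `hotspots` (the designated hotspot table).
#' @export
simulate_patient <- function(config, reference, patient_index) {
  pid <- sprintf("P%d", patient_index)
  k <- config$tumors_per_patient[patient_index]
  rel <- config$relationship[patient_index]
  n_mut <- config$n_mutations[patient_index]
  smoking <- config$smoking[patient_index]
  weights <- config$spectrum_weights[[smoking]]
  trunk_fraction <- if (rel == "independent") 0 else config$trunk_fraction
  hotspots <- default_hotspots(reference, config$n_hotspots)

  len <- nchar(reference$sequence)
  if (k * n_mut > 0.5 * len) {
    stop_msclone("reference too short to host %d non-colliding mutations", k * n_mut)
  }
  pos_cg <- ref_positions_of(reference, c("C", "G"))
  pos_ta <- ref_positions_of(reference, c("T", "A"))
  tcw_flag <- in_tcw_motif(reference, pos_cg)
  tcw_weight <- tcw_site_weight(config$apobec_intensity, mean(tcw_flag))

  withr::with_seed(config$seed + patient_index, {
    avail <- rep(TRUE, len)
    avail[hotspots$pos] <- FALSE

    tumors <- vector("list", k)
    sample_ids <- sprintf("%sT%d", pid, seq_len(k))
    met_idx <- if (rel == "metastatic") k else 0L
    founder_idx <- if (rel == "metastatic") k - 1L else 0L
    trunk_keys <- character()

    for (t in seq_len(k)) {
      hot_take <- runif(nrow(hotspots)) < config$hotspot_rate
      hot_df <- if (any(hot_take)) {
        hs <- hotspots[hot_take, , drop = FALSE]
        make_snv_df(reference,
                    list(pos = hs$pos, ref = hs$ref, alt = hs$alt),
                    draw_snv_evidence(nrow(hs), config$depth_model),
                    gene = hs$gene)
      } else empty_snv_df()

      if (t == met_idx) {
        founder <- tumors[[founder_idx]]$snvs
        non_hot <- founder[!(mutation_keys(founder) %in%
                               hotspot_keys(hotspots)), , drop = FALSE]
        truncal <- non_hot[runif(nrow(non_hot)) < trunk_fraction, ,
                           drop = FALSE]
        trunk_keys <- mutation_keys(truncal)
        # identical substitution identity, fresh sequencing evidence
        ev <- draw_snv_evidence(nrow(truncal), config$depth_model)
        trunk_df <- make_snv_df(reference,
                                list(pos = truncal$pos, ref = truncal$ref,
                                     alt = truncal$alt), ev,
                                gene = truncal$gene)
        trunk_df$validated <- truncal$validated
        n_priv <- max(0L, n_mut - nrow(trunk_df) - nrow(hot_df))
      } else {
        trunk_df <- empty_snv_df()
        n_priv <- max(0L, n_mut - nrow(hot_df))
      }
      priv_sites <- draw_snv_sites(n_priv, weights, reference, avail,
                                   pos_cg, pos_ta, tcw_flag, tcw_weight)
      avail[priv_sites$pos] <- FALSE
      priv_df <- make_snv_df(reference, priv_sites,
                             draw_snv_evidence(n_priv, config$depth_model))
      snvs <- rbind(trunk_df, hot_df, priv_df)
      indels <- draw_indels(reference, config$n_indels, avail)
      avail[indels$pos] <- FALSE
      svs <- draw_svs(reference, config$n_svs)
      tumors[[t]] <- callset(sample_ids[t], pid, smoking, snvs = snvs,
                             indels = indels, svs = svs)
    }

    if (rel == "metastatic" && config$sv_share > 0L) {
      founder_svs <- tumors[[founder_idx]]$svs
      dels <- which(founder_svs$sv_type == "DEL" &
                      founder_svs$clipped_reads_total >= 5L &
                      founder_svs$clipped_reads_end_a >= 1L &
                      founder_svs$clipped_reads_end_b >= 1L)
      take <- utils::head(dels, config$sv_share)
      if (length(take)) {
        tumors[[met_idx]]$svs <- rbind(founder_svs[take, , drop = FALSE],
                                       tumors[[met_idx]]$svs)
      }
    }

    cn_events <- NULL
    segments <- list()
    for (t in seq_len(k)) {
      inherit <- NULL
      if (t == met_idx) {
        n_inherit <- round(config$cn_model$share_fraction *
                             length(cn_events[[founder_idx]]))
        inherit <- utils::head(cn_events[[founder_idx]], n_inherit)
      }
      prof <- draw_cn_profile(reference, sample_ids[t], config$cn_model,
                              inherit)
      segments[[t]] <- prof$segments
      cn_events[[t]] <- prof$events
    }

    truth <- do.call(rbind, lapply(utils::combn(k, 2, simplify = FALSE),
      function(ij) {
        met_pair <- rel == "metastatic" &&
          all(sort(ij) == c(founder_idx, met_idx))
        data.frame(patient = pid, sample_a = sample_ids[ij[1]],
                   sample_b = sample_ids[ij[2]],
                   true_relationship = if (met_pair) "metastatic"
                                       else "independent",
                   trunk_keys = if (met_pair)
                     paste(trunk_keys, collapse = ";") else "",
                   stringsAsFactors = FALSE)
      }))

    list(callsets = tumors, segments = do.call(rbind, segments),
         truth = truth, hotspots = hotspots)
  })
}

#' Simulate a full cohort
#'
#' Runs [simulate_patient()] for every patient under a shared reference.
#' Fully deterministic for a fixed configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @param reference A `reference_contig`.
#' @return An object of class `msclone_cohort`: list with `reference`,
#'   `callsets` (flat list over all samples), `segments`, `truth`,
#'   `hotspots`, `sample_info` (sample/patient/smoking table) and the
#'   `config`.
#' @export
simulate_cohort <- function(config, reference) {
  callsets <- list(); segments <- list(); truth <- list()
  hotspots <- default_hotspots(reference, config$n_hotspots)
  for (i in seq_len(config$n_patients)) {
    p <- simulate_patient(config, reference, i)
    callsets <- c(callsets, p$callsets)
    segments[[i]] <- p$segments
    truth[[i]] <- p$truth
  }
  sample_info <- if (length(callsets)) {
    data.frame(sample_id = vapply(callsets, `[[`, "", "sample_id"),
               patient_id = vapply(callsets, `[[`, "", "patient_id"),
               smoking = vapply(callsets, `[[`, "", "smoking"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), patient_id = character(),
               smoking = character(), stringsAsFactors = FALSE)
  }
  structure(list(reference = reference, callsets = callsets,
                 segments = if (length(segments)) do.call(rbind, segments)
                            else cn_segment(character(), character(),
                                            integer(), integer(), numeric()),
                 truth = if (length(truth)) do.call(rbind, truth)
                         else NULL,
                 hotspots = hotspots, sample_info = sample_info,
                 config = config),
            class = "msclone_cohort")
}

#' @export
print.msclone_cohort <- function(x, ...) {
  cat(sprintf("<msclone_cohort> %d patients, %d samples, %d CN segments\n",
              x$config$n_patients, length(x$callsets), nrow(x$segments)))
  invisible(x)
}
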