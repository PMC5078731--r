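test_that("substitutions are normalised onto the pyrimidine strand", {
  expect_equal(classify_substitution("C", "A"), "C>A")
  expect_equal(classify_substitution("G", "T"), "C>A")
  expect_equal(classify_substitution("T", "C"), "T>C")
  expect_equal(classify_substitution("A", "G"), "T>C")
  expect_equal(classify_substitution(c("G", "A"), c("A", "T")),
               c("C>T", "T>A"))
  expect_error(classify_substitution("C", "C"), "substitution")
  expect_error(classify_substitution("N", "A"), "A,C,G,T")
})

test_that("six-class spectra conserve totals", {
  expect_equal(sum(spectrum_counts(callset("E", "P1"))), 0L)
  ten_ca <- callset_with_keys("A", 1:10, ref = "C", alt = "A")
  expect_equal(unclass(spectrum_counts(ten_ca)),
               c("C>A" = 10L, "C>G" = 0L, "C>T" = 0L,
                 "T>A" = 0L, "T>C" = 0L, "T>G" = 0L))
  mixed <- callset_with_keys("B", 1:4, ref = c("C", "G", "T", "A"),
                             alt = c("A", "T", "G", "C"))
  expect_equal(sum(spectrum_counts(mixed)), 4L)
})

test_that("smoker-type simulations are dominated by C>A", {
  ref <- generate_reference(30000, 0.4, seed = 2)
  wins <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_patients = 1, tumors_per_patient = 2,
                      relationship = "independent", n_mutations = 100L,
                      smoking = "former",
                      spectrum_weights = list(
                        never = default_spectrum_weights()$never,
                        former = c(0.6, 0.08, 0.12, 0.08, 0.08, 0.04)),
                      hotspot_rate = 0, n_hotspots = 0, seed = s)
    sc <- spectrum_counts(simulate_patient(cfg, ref, 1)$callsets[[1]])
    if (names(which.max(sc)) == "C>A") wins <- wins + 1L
  }
  expect_gte(wins, 99L)
})

test_that("concentrating all weight on one class yields >=90% of that class", {
  ref <- generate_reference(30000, 0.4, seed = 3)
  cfg <- sim_config(n_patients = 1, tumors_per_patient = 2,
                    relationship = "independent", n_mutations = 200L,
                    smoking = "former",
                    spectrum_weights = list(
                      never = default_spectrum_weights()$never,
                      former = c(1, 0, 0, 0, 0, 0)),
                    hotspot_rate = 0, n_hotspots = 0, seed = 31)
  sc <- spectrum_counts(simulate_patient(cfg, ref, 1)$callsets[[1]])
  expect_gte(sc[["C>A"]] / sum(sc), 0.9)
})

test_that("spectrum difference testing behaves like an exact test", {
  balanced <- structure(setNames(rep(20L, 6), names(spectrum_counts(callset("E", "P")))),
                        class = c("spectrum_counts", "integer"))
  expect_gt(compare_spectra(balanced, balanced, reps = 2e4, seed = 1), 0.9)
  a <- c(100L, 0L, 0L, 0L, 0L, 0L); b <- c(0L, 100L, 0L, 0L, 0L, 0L)
  expect_lte(compare_spectra(a, b, reps = 1e5, seed = 1), 1e-4)
  # collapsed to 2x2 the exact path equals the 2x2 Fisher test
  x <- c(30L, 10L, 0L, 0L, 0L, 0L); y <- c(12L, 25L, 0L, 0L, 0L, 0L)
  expect_equal(compare_spectra(x, y), fisher_exact_2x2(30, 10, 12, 25),
               tolerance = 1e-10)
  expect_error(compare_spectra(c(0L, 0L, 0L, 0L, 0L, 0L), a), "zero total")
})

test_that("Monte-Carlo spectrum p-values tighten with more replicates", {
  a <- c(90L, 60L, 50L, 40L, 30L, 30L)
  b <- c(60L, 75L, 45L, 55L, 25L, 40L)
  p_lo <- vapply(1:25, function(s) compare_spectra(a, b, reps = 500, seed = s),
                 numeric(1))
  p_hi <- vapply(1:25, function(s) compare_spectra(a, b, reps = 8000, seed = s),
                 numeric(1))
  expect_lt(sd(p_hi), 0.75 * sd(p_lo))
})

test_that("spectrum correlation matches the direct Pearson formula", {
  x <- c(50L, 10L, 10L, 10L, 10L, 10L)
  expect_equal(spectrum_correlation(x, x), 1.0)
  y <- c(10L, 50L, 10L, 10L, 10L, 10L)
  fx <- x / sum(x); fy <- y / sum(y)
  hand <- sum((fx - mean(fx)) * (fy - mean(fy))) /
    sqrt(sum((fx - mean(fx))^2) * sum((fy - mean(fy))^2))
  expect_equal(spectrum_correlation(x, y), hand)
  expect_equal(spectrum_correlation(x, y), -0.2, tolerance = 1e-12)
  flat <- rep(7L, 6)
  expect_warning(r <- spectrum_correlation(flat, x), "constant")
  expect_true(is.na(r))
})

test_that("motif and context counts follow the worked examples", {
  # TCA centred C mutated C>T: an APOBEC-type mutation in motif
  ref <- literal_reference("AAAAATCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  call <- passing_snvs(pos = 7L, ref = "C", alt = "T")
  ac <- context_counts_41nt(ref, call)
  expect_equal(ac$mutations_tcw, 1L)
  expect_equal(ac$mutations_cg, 1L)

  # GCC context: mutated C is not in a TCW motif
  ref2 <- literal_reference("AAAAAGCCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  call2 <- passing_snvs(pos = 8L, ref = "C", alt = "T")
  ac2 <- context_counts_41nt(ref2, call2)
  expect_equal(ac2$mutations_tcw, 0L)
  expect_equal(ac2$mutations_cg, 1L)

  # a window near the contig start truncates without error
  ref3 <- literal_reference(paste0("AATCA", strrep("A", 60)))
  call3 <- passing_snvs(pos = 4L, ref = "C", alt = "G")
  ac3 <- context_counts_41nt(ref3, call3)
  expect_equal(ac3$truncated_windows, 1L)
  expect_equal(ac3$mutations_tcw, 1L)

  expect_error(context_counts_41nt(ref, passing_snvs(pos = 999L)),
               "outside")
  expect_error(context_counts_41nt(ref, passing_snvs(pos = 1L, ref = "C")),
               "mismatch")
})

test_that("G>A calls on the reverse strand count as WGA-motif mutations", {
  # TGA at positions 6-8: the G is the reverse-complement image of a TCA C
  ref <- literal_reference("AAAAATGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  call <- passing_snvs(pos = 7L, ref = "G", alt = "A")
  ac <- context_counts_41nt(ref, call)
  expect_equal(ac$mutations_tcw, 1L)
  # the same G mutated G>T is not an APOBEC-type substitution
  ac2 <- context_counts_41nt(ref, passing_snvs(pos = 7L, ref = "G",
                                               alt = "T"))
  expect_equal(ac2$mutations_tcw, 0L)
  expect_equal(ac2$mutations_cg, 1L)
})

test_that("enrichment follows the four-count ratio with guarded degeneracies", {
  mk <- function(mt, mc, ct, cc) structure(
    list(mutations_tcw = mt, mutations_cg = mc, context_tcw = ct,
         context_cg = cc), class = "apobec_counts")
  expect_equal(apobec_enrichment(mk(10, 40, 500, 2000)), 1.0)
  expect_equal(apobec_enrichment(mk(0, 40, 500, 2000)), 0.0)
  expect_equal(apobec_enrichment(mk(30, 60, 1000, 8000)), 4.0)
  expect_error(apobec_enrichment(mk(1, 0, 10, 100)), "mutations_cg")
  expect_error(apobec_enrichment(mk(1, 10, 0, 100)), "context_tcw")
  expect_gt(apobec_significance(mk(10, 40, 500, 2000)), 0.5)
  expect_lt(apobec_significance(mk(35, 40, 500, 2000)), 1e-6)
  expect_error(apobec_significance(mk(0, 0, 500, 2000)), "no mutated")
})

test_that("trinucleotide spectra strand-normalise and marginalise correctly", {
  ref <- literal_reference("AACAA")
  one <- trinuc_spectrum(ref, passing_snvs(pos = 3L, ref = "C", alt = "T"))
  expect_equal(one[["A[C>T]A"]], 1L)
  expect_equal(sum(one), 1L)

  # G>A in TGA context is T[C>T]A after reverse complementing
  ref2 <- literal_reference("ATGAA")
  two <- trinuc_spectrum(ref2, passing_snvs(pos = 3L, ref = "G", alt = "A"))
  expect_equal(two[["T[C>T]A"]], 1L)

  # calls at the contig edge are excluded and reported
  edge <- trinuc_spectrum(ref, passing_snvs(pos = 1L, ref = "A", alt = "C"))
  expect_equal(sum(edge), 0L)
  expect_equal(attr(edge, "n_excluded"), 1L)

  # marginal over contexts equals the six-class spectrum
  ref3 <- generate_reference(30000, 0.4, seed = 4)
  cfg <- sim_config(n_patients = 1, tumors_per_patient = 2,
                    relationship = "independent", n_mutations = 150L,
                    hotspot_rate = 0, n_hotspots = 0, seed = 21)
  cs <- simulate_patient(cfg, ref3, 1)$callsets[[1]]
  tri <- trinuc_spectrum(ref3, cs)
  marg <- vapply(names(spectrum_counts(cs)), function(cl) {
    sum(tri[grepl(cl, names(tri), fixed = TRUE)])
  }, integer(1))
  expect_equal(marg + 0L, unclass(spectrum_counts(cs)) + 0L,
               ignore_attr = TRUE)
})

test_that("spectrum and APOBEC statistics are strand symmetric", {
  ref <- generate_reference(20000, 0.45, seed = 6)
  cfg <- sim_config(n_patients = 1, tumors_per_patient = 2,
                    relationship = "independent", n_mutations = 120L,
                    hotspot_rate = 0, n_hotspots = 0, seed = 23)
  cs <- simulate_patient(cfg, ref, 1)$callsets[[1]]
  ref_rc <- revcomp_reference(ref)
  snvs_rc <- revcomp_calls(cs$snvs, ref)

  expect_identical(unclass(spectrum_counts(snvs_rc)),
                   unclass(spectrum_counts(cs$snvs)))
  expect_identical(unclass(trinuc_spectrum(ref_rc, snvs_rc)),
                   unclass(trinuc_spectrum(ref, cs$snvs)))
  fwd <- context_counts_41nt(ref, cs$snvs)
  rev <- context_counts_41nt(ref_rc, snvs_rc)
  expect_identical(unclass(fwd)[1:4], unclass(rev)[1:4])
  expect_identical(apobec_enrichment(fwd), apobec_enrichment(rev))
  expect_identical(apobec_significance(fwd), apobec_significance(rev))
})
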