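test_that("shared mutations are exact identity intersections", {
  a <- callset_with_keys("A", 1:10)
  b <- callset_with_keys("B", 8:12)
  expect_length(shared_mutations(a, b), 3L)
  expect_identical(shared_mutations(a, b), shared_mutations(b, a))
  expect_length(shared_mutations(a, callset_with_keys("C", 100:105)), 0L)
  expect_length(shared_mutations(a, a), 10L)
  # same position, different alt allele is NOT shared
  d <- callset_with_keys("D", 1:10, alt = "G")
  expect_length(shared_mutations(a, d), 0L)
})

test_that("a 52-of-198 trunk construction is recovered exactly", {
  primary <- callset_with_keys("T3", 1:198)
  metastasis <- callset_with_keys("LN", c(1:52, 1000:1145))
  expect_length(shared_mutations(primary, metastasis), 52L)
  expect_equal(shared_fraction(primary, metastasis, "first"), 52 / 198)
})

test_that("sharing matrix holds totals on the diagonal and is symmetric", {
  cohort <- list(callset_with_keys("A", 1:5), callset_with_keys("B", 4:10),
                 callset_with_keys("C", 100:102))
  sm <- sharing_matrix(cohort)
  expect_equal(unname(diag(sm$shared)), c(5L, 7L, 3L))
  expect_identical(sm$shared, t(sm$shared))
  expect_true(all(sm$shared <= outer(sm$totals, sm$totals, pmin)))
  expect_equal(sm$shared["A", "B"], 2L)
  expect_equal(sm$shared["A", "C"], 0L)
  one <- sharing_matrix(list(callset_with_keys("A", 1:5)))
  expect_equal(unname(one$shared), matrix(5L))
  expect_error(sharing_matrix(list(callset_with_keys("A", 1),
                                   callset_with_keys("A", 2))), "duplicate")
})

test_that("shared fraction handles all denominators and degenerate input", {
  a <- callset_with_keys("A", 1:10); b <- callset_with_keys("B", 6:25)
  expect_equal(shared_fraction(a, b, "first"), 0.5)
  expect_equal(shared_fraction(a, b, "second"), 0.25)
  expect_equal(shared_fraction(a, b, "union"), 5 / 25)
  expect_equal(shared_fraction(a, b, "min"), 0.5)
  expect_equal(shared_fraction(a, a), 1.0)
  expect_equal(shared_fraction(a, callset_with_keys("C", 50:60)), 0)
  empty <- callset("E", "P1")
  expect_error(shared_fraction(empty, a, "first"), "denominator")
})

test_that("hotspot exclusion is a plain set difference", {
  keys <- c("chrT:1:C>A", "chrT:2:C>A", "chrT:3:C>A")
  expect_identical(exclude_hotspots(keys, NULL), keys)
  hs <- hotspot_list("chrT", 2, "C", "A")
  expect_identical(exclude_hotspots(keys, hs), keys[-2])
  all_hs <- hotspot_list("chrT", 1:3, "C", "A")
  expect_length(exclude_hotspots(keys, all_hs), 0L)
})

test_that("two-sided Fisher p-values match published and hand-derived values", {
  expect_equal(round(fisher_exact_2x2(6, 9, 111, 326), 2), 0.23)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  # margins 10/10: only the two extreme tables are as unlikely as observed
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("fisher_exact_2x2 agrees with hypergeometric enumeration on random tables", {
  withr::with_seed(11, {
    for (i in 1:200) {
      tab <- sample(0:12, 4, replace = TRUE)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                   fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-8)
    }
  })
})

test_that("cohort comparison tests reproduce the published p-values", {
  cr <- default_cohort_ref()
  expect_equal(round(hotspot_prevalence_test(6, 15, cr), 2), 0.23)
  expect_equal(round(shared_mutation_rate_test(1, 884, cr), 2), 0.72)
  expect_equal(hotspot_prevalence_test(0, 10, cohort_reference(0L, 100L)), 1.0)
  expect_lt(hotspot_prevalence_test(10, 10, cohort_reference(0L, 100L)), 1e-10)
  expect_equal(shared_mutation_rate_test(
    2, 100, cohort_reference(n_shared_mutations = 20L,
                             n_total_mutations = 1000L)), 1.0)
  expect_lt(shared_mutation_rate_test(
    50, 100, cohort_reference(n_shared_mutations = 1L,
                              n_total_mutations = 1000L)), 1e-10)
})

test_that("SV matching respects tolerance and matches each record once", {
  svs <- sv_record("chrT", c(100, 5000), "chrT", c(900, 9000), "DEL",
                   6L, 2L, 2L)
  expect_equal(nrow(shared_svs(svs, svs, tolerance = 0)), 2L)
  off <- svs; off$pos_a <- off$pos_a + 11L
  expect_equal(nrow(shared_svs(svs, off, tolerance = 10)), 0L)
  near <- svs; near$pos_a <- near$pos_a + 10L
  expect_equal(nrow(shared_svs(svs, near, tolerance = 10)), 2L)
  # patient-1-like: two shared deletions among private SVs
  a <- rbind(svs, sv_record("chrT", 20000, "chrT", 30000, "DUP", 7L, 3L, 3L))
  b <- rbind(svs, sv_record("chrT", 40000, "chrT", 50000, "INV", 7L, 3L, 3L))
  m <- shared_svs(a, b, tolerance = 10)
  expect_equal(nrow(m), 2L)
  # type mismatch never matches even at distance zero
  retyped <- svs; retyped$sv_type <- "DUP"
  expect_equal(nrow(shared_svs(svs, retyped, tolerance = 0)), 0L)
})

test_that("pair classification reproduces the three published scenarios", {
  cr <- default_cohort_ref()
  # trunk-sharing pair: 52 of 198 shared, none of them hotspots
  primary <- callset_with_keys("T3", 1:198)
  metastasis <- callset_with_keys("LN", c(1:52, 1000:1145))
  call <- classify_pair(primary, metastasis, cohort = cr)
  expect_equal(call$verdict, "clonally_related")

  # disjoint tumours
  t1 <- callset_with_keys("T1", 1:80)
  t2 <- callset_with_keys("T2", 200:279)
  expect_equal(classify_pair(t1, t2, cohort = cr)$verdict, "independent")

  # hotspot-only sharing: excluded, then independent
  hs <- hotspot_list("chrT", 500, "C", "A")
  h1 <- callset_with_keys("H1", c(500, 1:40))
  h2 <- callset_with_keys("H2", c(500, 100:139))
  hcall <- classify_pair(h1, h2, hotspots = hs, cohort = cr)
  expect_equal(hcall$verdict, "independent")
  expect_equal(hcall$shared_total, 1L)
  expect_equal(hcall$shared_non_hotspot, 0L)

  # single shared non-hotspot mutation judged against the cohort rate
  s1 <- callset_with_keys("S1", c(999, 1:84))
  s2 <- callset_with_keys("S2", c(999, 100:185))
  scall <- classify_pair(s1, s2, cohort = cr, series_total = 884L)
  expect_equal(scall$verdict, "independent")
  expect_match(paste(scall$evidence, collapse = " "), "p=0.7")
  expect_error(classify_pair(s1, s2), "cohort")
})

test_that("classification verdicts are invariant under argument swap", {
  cr <- default_cohort_ref()
  ref <- generate_reference(60000, 0.4, seed = 5)
  cfg <- sim_config(n_patients = 4, tumors_per_patient = 2,
                    relationship = c("metastatic", "independent"),
                    n_mutations = 80L, seed = 19)
  coh <- simulate_cohort(cfg, ref)
  for (i in seq(1, length(coh$callsets), by = 2)) {
    a <- coh$callsets[[i]]; b <- coh$callsets[[i + 1]]
    ab <- classify_pair(a, b, coh$hotspots, cohort = cr)
    ba <- classify_pair(b, a, coh$hotspots, cohort = cr)
    expect_equal(ab$verdict, ba$verdict)
    expect_equal(ab$shared_non_hotspot, ba$shared_non_hotspot)
  }
})
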