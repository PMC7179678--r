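test_that("rounding is half away from zero at reporting precision", {
  expect_equal(round_half_up(94.87179, 1), 94.9)
  expect_equal(round_half_up(99.6835, 1), 99.7)
  expect_equal(round_half_up(38.947), 39)
  expect_equal(round_half_up(86.585), 87)
  expect_equal(round_half_up(80.4878), 80)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.25, 1), 2.3)
})

test_that("concordance matches an independent tally and identity is 100%", {
  sc <- small_cohort(seed = 17, noise_sd = 0.03)
  cg <- call_genotypes(sc$cohort$run1)
  qc <- apply_qc(cg, sc$manifest)
  truth <- truth_as_genotypes(sc$cohort, rownames(qc$genotypes$calls))
  rep <- concordance(qc$genotypes, truth, sc$manifest)
  # double-entry: recompute by a naive loop over records
  snv_probes <- intersect(
    colnames(qc$genotypes$calls),
    sc$manifest$probe_id[sc$manifest$probe_class == "custom_pid_snv"])
  n_cmp <- 0L; n_match <- 0L
  for (s in rownames(qc$genotypes$calls)) {
    for (p in snv_probes) {
      g <- qc$genotypes$calls[s, p]
      t <- sc$cohort$truth[s, p]
      if (g != "nocall" && t != "missing") {
        n_cmp <- n_cmp + 1L
        if (g == t) n_match <- n_match + 1L
      }
    }
  }
  expect_equal(rep$n_compared, n_cmp)
  expect_equal(rep$n_matching, n_match)
  expect_equal(rep$percent_concordance,
               round_half_up(100 * n_match / n_cmp, 1))

  # truth equal to calls gives exactly 100.0
  truth_same <- truth_genotypes(data.frame(
    sample_id = rep(rownames(qc$genotypes$calls), length(snv_probes)),
    probe_id = rep(snv_probes, each = nrow(qc$genotypes$calls)),
    genotype = ifelse(
      as.vector(qc$genotypes$calls[, snv_probes]) == "nocall", "missing",
      as.vector(qc$genotypes$calls[, snv_probes]))))
  rep100 <- concordance(qc$genotypes, truth_same, sc$manifest)
  expect_equal(rep100$percent_concordance, 100.0)
  expect_equal(rep100$n_nonref_mismatches, 0L)
})

test_that("INDEL probes are excluded from the sequencing comparison", {
  man <- tiny_manifest()
  calls <- gm_from_calls(matrix(
    "AA", 1, 5, dimnames = list("S1", c("p2", "p1", "p3", "px1", "px2"))))
  truth <- truth_genotypes(data.frame(
    sample_id = "S1", probe_id = c("p1", "p2", "px1", "px2"),
    genotype = c("AA", "AA", "AA", "AB")))
  rep <- concordance(calls, truth, man)
  # px2 is an INDEL probe and p3 backbone: only 3 SNV custom probes compared
  expect_equal(rep$n_compared, 3L)
  expect_equal(rep$percent_concordance, 100.0)
})

test_that("sensitivity partitions variants and adds confirmed new ones", {
  cats <- c(rep("replicated_known", 33), rep("missed_probe_failed", 8),
            rep("missed_no_probe", 34), rep("new_confirmed", 38),
            rep("new_refuted", 3), rep("new_unconfirmable", 5))
  rep <- sensitivity_report(cats)
  expect_equal(unname(rep$counts[["replicated_known"]]), 33L)
  expect_equal(rep$sensitivity_known, 80)
  expect_equal(rep$sensitivity_overall, 87)
  expect_equal(rep$confirmation_percent, 92.7)
  expect_error(sensitivity_report("weird_category"), "unknown")
  # empty denominators are undefined, not zero
  expect_true(is.na(sensitivity_report(rep("missed_no_probe", 4))$
                      sensitivity_known))
  # adding a confirmed new variant never lowers overall sensitivity
  rep2 <- sensitivity_report(c(cats, "new_confirmed"))
  expect_gte(rep2$sensitivity_overall, rep$sensitivity_overall)
})

test_that("diagnostic yield counts patients", {
  dx <- data.frame(sample_id = sprintf("P%02d", 1:95),
                   status = c(rep("genetic_diagnosis", 37),
                              rep("no_diagnosis", 58)))
  y <- diagnostic_yield(dx)
  expect_equal(y$n_diagnosed, 37L)
  expect_equal(y$yield_percent, 39)
  expect_equal(diagnostic_yield(logical(5))$yield_percent, 0)
})

test_that("reproducibility compares shared post-QC custom genotypes", {
  sc <- small_cohort(seed = 23, noise_sd = 0.03)
  cg1 <- call_genotypes(sc$cohort$run1)
  qc1 <- apply_qc(cg1, sc$manifest)
  # identical runs: zero discordance, 100% patient replication
  dx <- data.frame(sample_id = sc$cohort$patients,
                   status = "genetic_diagnosis",
                   genes = "GENE001")
  rep_same <- reproducibility(qc1$genotypes, qc1$genotypes, sc$manifest,
                              dx, dx)
  expect_equal(rep_same$n_discordant, 0L)
  expect_equal(rep_same$discordance_percent, 0)
  expect_equal(rep_same$patient_percent, 100.0)

  # a genuine second run: discordance grows with noise (measured over all
  # probe classes; custom probes alone are nearly monomorphic and too
  # stable to carry the signal at this cohort size)
  disc <- vapply(c(0.04, 0.15), function(ns) {
    sci <- small_cohort(seed = 29, noise_sd = ns)
    g1 <- apply_qc(call_genotypes(sci$cohort$run1), sci$manifest)$genotypes
    g2 <- apply_qc(call_genotypes(sci$cohort$run2), sci$manifest)$genotypes
    reproducibility(g1, g2, sci$manifest,
                    scope_classes = c("custom_pid_snv", "custom_pid_indel",
                                      "backbone"))$discordance_percent
  }, numeric(1))
  expect_true(disc[2] > disc[1])
})

test_that("patient-level replication requires the same causal gene", {
  man <- tiny_manifest()
  gm <- gm_from_calls(matrix("AA", 2, 2, dimnames = list(c("P1", "P2"),
                                                         c("p1", "p2"))))
  d1 <- data.frame(sample_id = c("P1", "P2"),
                   status = "genetic_diagnosis", genes = c("G1", "G2"))
  d2 <- data.frame(sample_id = c("P1", "P2"),
                   status = c("genetic_diagnosis", "genetic_diagnosis"),
                   genes = c("G1", "OTHER"))
  rep <- reproducibility(gm, gm, man, d1, d2)
  expect_equal(rep$n_diagnosed_run1, 2L)
  expect_equal(rep$n_replicated, 1L)
  expect_equal(rep$patient_percent, 50.0)
})

test_that("the screen report serializes outcomes and summary statistics", {
  sc <- small_cohort(seed = 47, noise_sd = 0.03)
  cg <- call_genotypes(sc$cohort$run1)
  qc <- apply_qc(cg, sc$manifest)
  scr <- screen_snv(qc, sc$annotation, sc$manifest, cg$models,
                    sc$cohort$run1, sc$cohort$patients)
  path <- withr::local_tempfile(fileext = ".json")
  write_screen_report(scr, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$n_patients, length(sc$cohort$patients))
  expect_equal(rep$yield_percent,
               diagnostic_yield(scr$diagnoses)$yield_percent)
  expect_length(rep$patients, length(sc$cohort$patients))
})

test_that("the cost model reproduces the two-arm comparison and is linear", {
  cc <- cost_compare(cost_model(40, 1000, 100, 0.4))
  expect_equal(cc$initial_array_cost, 4000)
  expect_equal(cc$screen_then_sequence_total, 64000)
  expect_equal(cc$sequence_all_total, 100000)
  expect_equal(cc$saving, 36000)
  # perfect screen: only array costs; useless screen: lose the array costs
  expect_equal(cost_compare(cost_model(40, 1000, 50, 1))$
                 screen_then_sequence_total, 2000)
  expect_equal(cost_compare(cost_model(40, 1000, 50, 0))$saving, -2000)
  # saving is linear in cohort size
  s1 <- cost_compare(cost_model(40, 1000, 100, 0.4))$saving
  s2 <- cost_compare(cost_model(40, 1000, 200, 0.4))$saving
  expect_equal(s2, 2 * s1)
  expect_error(cost_model(-1, 1000, 10, 0.5), "positive")
})
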