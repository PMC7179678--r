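# Hand-built fixtures exercising each cascade filter, plus cohort-level
# properties on simulated data.

screen_fixture <- function() {
  man <- probe_manifest(data.frame(
    probe_id = c("a1", "a2", "a3", "x1"),
    chromosome = c("1", "2", "3", "X"),
    position = c(1000, 2000, 3000, 4000),
    ref_allele = "A", alt_allele = "B",
    gene = c("G1", "G2", "G3", "GX"),
    probe_class = "custom_pid_snv"))
  ann <- variant_annotation(data.frame(
    probe_id = c("a1", "a2", "a3", "x1"),
    pathogenicity = c("disease_causing", "disease_causing", "benign",
                      "disease_causing"),
    pop_frequency = c(0.004, 0.005, 0.001, 1e-4),
    inheritance = c("AD", "AD", "none", "XL")), man)
  calls <- matrix("AA", 3, 4, dimnames = list(c("P1", "P2", "P3"),
                                              c("a1", "a2", "a3", "x1")))
  calls["P1", "a1"] <- "AB"   # disease-causing, rare: survives
  calls["P1", "a2"] <- "AB"   # frequency exactly at the cutoff: dropped
  calls["P2", "a3"] <- "AB"   # benign: dropped at selection
  calls["P1", "x1"] <- "AB"   # X het; P1 is male: dropped
  calls["P2", "x1"] <- "BB"   # X hom; P2 male: hemizygous
  calls["P3", "x1"] <- "AB"   # X het; P3 female: retained
  list(man = man, ann = ann, gm = gm_from_calls(calls),
       sex = c(P1 = "male", P2 = "male", P3 = "female"))
}

test_that("selection keeps only disease-causing non-reference calls", {
  fx <- screen_fixture()
  c0 <- select_disease_causing(fx$gm, fx$ann)
  expect_setequal(paste(c0$sample_id, c0$probe_id),
                  c("P1 a1", "P1 a2", "P1 x1", "P2 x1", "P3 x1"))
  expect_equal(attr(c0, "n_dropped_not_disease_causing"), 1L)
})

test_that("frequency filter is strictly below the cutoff", {
  fx <- screen_fixture()
  c0 <- select_disease_causing(fx$gm, fx$ann)
  c1 <- frequency_filter(c0, fx$ann)
  expect_true(all(c1$probe_id != "a2"))       # 0.005 is not < 0.005
  expect_true("a1" %in% c1$probe_id)          # 0.004 survives
  # a common variant never survives
  ann2 <- fx$ann
  ann2$pop_frequency[ann2$probe_id == "a1"] <- 0.20
  expect_false("a1" %in% frequency_filter(c0, ann2)$probe_id)
})

test_that("recurrent variants are excluded in every carrier", {
  fx <- screen_fixture()
  c0 <- select_disease_causing(fx$gm, fx$ann)
  c2 <- recurrence_filter(c0, fx$gm)
  # x1 is carried by all three samples: removed everywhere
  expect_false(any(c2$probe_id == "x1"))
  expect_true("a1" %in% c2$probe_id)          # singleton survives
})

test_that("male X heterozygotes are dropped, male X homozygotes hemizygous", {
  fx <- screen_fixture()
  c0 <- select_disease_causing(fx$gm, fx$ann)
  c3 <- male_x_het_filter(c0, fx$sex, fx$man)
  key <- paste(c3$sample_id, c3$probe_id)
  expect_false("P1 x1" %in% key)              # male het dropped
  expect_true("P3 x1" %in% key)               # female het retained
  p2 <- c3[c3$sample_id == "P2" & c3$probe_id == "x1", ]
  expect_equal(p2$zygosity, "hemizygous")
  # ambiguous sex: retained and flagged
  sex2 <- fx$sex
  sex2["P1"] <- "ambiguous"
  c3b <- male_x_het_filter(c0, sex2, fx$man)
  p1 <- c3b[c3b$sample_id == "P1" & c3b$probe_id == "x1", ]
  expect_equal(nrow(p1), 1L)
  expect_true(p1$flagged_for_review)
})

test_that("cluster-quality check drops planted outliers and dropouts", {
  sc <- small_cohort(seed = 61, noise_sd = 0.02)
  run <- sc$cohort$run1
  cg <- call_genotypes(run)
  probes <- colnames(run$x)[1:3]
  samples <- rownames(run$x)[1:3]
  cand <- data.frame(sample_id = samples, probe_id = probes,
                     call = cg$primary$calls[cbind(1:3, 1:3)],
                     zygosity = "het", caller = "primary",
                     flagged_for_review = FALSE, filter_trail = "t")
  # candidate 2 moved 10 spreads off its cluster; candidate 3 near-zero
  # intensity; candidate 1 untouched
  pt <- polar_transform(run$x, run$y)
  spread <- cg$models$spread[match(cand$call[2], c("AA", "AB", "BB")),
                             probes[2]]
  center <- cg$models$centers[match(cand$call[2], c("AA", "AB", "BB")),
                              probes[2]]
  shift <- if (center > 0.5) -10 * spread else 10 * spread
  bad_angle <- min(max(center + shift, 0), 1)
  tot <- pt$total[samples[2], probes[2]]
  phi <- bad_angle * pi / 2
  run$x[samples[2], probes[2]] <- tot / (1 + tan(phi))
  run$y[samples[2], probes[2]] <- tot - run$x[samples[2], probes[2]]
  run$x[samples[3], probes[3]] <- run$x[samples[3], probes[3]] / 100
  run$y[samples[3], probes[3]] <- run$y[samples[3], probes[3]] / 100
  out <- cluster_quality_check(pidscreen:::new_candidates(cand),
                               cg$models, run)
  key <- paste(out$sample_id, out$probe_id)
  expect_true(paste(samples[1], probes[1]) %in% key)
  expect_false(paste(samples[2], probes[2]) %in% key)
  expect_false(paste(samples[3], probes[3]) %in% key)
})

test_that("inheritance matching implements AD, AR, compound het and XL", {
  man <- probe_manifest(data.frame(
    probe_id = c("r1", "r2", "d1", "h1"),
    chromosome = c("1", "1", "2", "X"),
    position = c(100, 200, 300, 400),
    ref_allele = "A", alt_allele = "B",
    gene = c("GAR", "GAR", "GAD", "GXL"),
    probe_class = "custom_pid_snv"))
  ann <- variant_annotation(data.frame(
    probe_id = c("r1", "r2", "d1", "h1"),
    pathogenicity = "disease_causing", pop_frequency = 1e-4,
    inheritance = c("AR", "AR", "AD", "XL")), man)
  sex <- c(P1 = "female", P2 = "female", P3 = "male", P4 = "female",
           P5 = "male", P6 = "female")
  cand <- pidscreen:::new_candidates(data.frame(
    sample_id = c("P1",        # single AR het: no diagnosis
                  "P2", "P2",  # two AR hets in one gene: compound het
                  "P3",        # AR hom: diagnosis
                  "P4",        # AD het: diagnosis
                  "P5",        # XL hemizygous male: diagnosis
                  "P6"),       # XL het female (carrier): no diagnosis
    probe_id = c("r1", "r1", "r2", "r1", "d1", "h1", "h1"),
    call = c("AB", "AB", "AB", "BB", "AB", "BB", "AB"),
    zygosity = c("het", "het", "het", "hom", "het", "hemizygous", "het"),
    caller = "primary", flagged_for_review = FALSE, filter_trail = "t"))
  dx <- match_inheritance(cand, ann, man, sex, sprintf("P%d", 1:6))
  expect_equal(dx$status,
               c("no_diagnosis", "genetic_diagnosis", "genetic_diagnosis",
                 "genetic_diagnosis", "genetic_diagnosis", "no_diagnosis"))
  expect_equal(dx$genes[2], "GAR")
})

test_that("the cascade is invariant to sample ordering", {
  sc <- small_cohort(seed = 71, noise_sd = 0.03)
  cg <- call_genotypes(sc$cohort$run1)
  qc <- apply_qc(cg, sc$manifest)
  res <- screen_snv(qc, sc$annotation, sc$manifest, cg$models,
                    sc$cohort$run1, sc$cohort$patients)
  # re-run with the genotype matrix rows shuffled
  perm <- rev(rownames(qc$genotypes$calls))
  qc2 <- qc
  qc2$genotypes <- pidscreen:::subset_genotypes(qc$genotypes, samples = perm)
  res2 <- screen_snv(qc2, sc$annotation, sc$manifest, cg$models,
                     sc$cohort$run1, sc$cohort$patients)
  k1 <- paste(res$candidates$sample_id, res$candidates$probe_id)
  k2 <- paste(res2$candidates$sample_id, res2$candidates$probe_id)
  expect_setequal(k1, k2)
  expect_equal(res$diagnoses[order(res$diagnoses$sample_id), ],
               res2$diagnoses[order(res2$diagnoses$sample_id), ],
               ignore_attr = TRUE)
})

test_that("non-recurrence filters are per-sample local", {
  sc <- small_cohort(seed = 81, noise_sd = 0.03)
  cg <- call_genotypes(sc$cohort$run1)
  qc <- apply_qc(cg, sc$manifest)
  c0 <- select_disease_causing(qc$genotypes, sc$annotation)
  c1 <- frequency_filter(c0, sc$annotation)
  # removing an unrelated sample changes nothing for the others
  drop_s <- setdiff(rownames(qc$genotypes$calls), unique(c1$sample_id))[1]
  keep <- setdiff(rownames(qc$genotypes$calls), drop_s)
  gm2 <- pidscreen:::subset_genotypes(qc$genotypes, samples = keep)
  c1b <- frequency_filter(select_disease_causing(gm2, sc$annotation),
                          sc$annotation)
  expect_setequal(paste(c1$sample_id, c1$probe_id),
                  paste(c1b$sample_id, c1b$probe_id))
})
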