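# Synthetic tracks built directly (for segmentation arithmetic) plus
# simulated cohorts with planted events (for end-to-end recovery).

# A hand-built single-sample track: one chromosome, evenly spaced probes.
flat_track <- function(n = 200, spacing = 1e5, lrr = rep(0, n),
                       baf = NULL, chrom = "1", sample = "S1") {
  if (is.null(baf)) baf <- rep(c(0, 0.5, 1), length.out = n)
  structure(list(
    lrr = matrix(lrr, 1, n, dimnames = list(sample, sprintf("p%04d", 1:n))),
    baf = matrix(baf, 1, n, dimnames = list(sample, sprintf("p%04d", 1:n))),
    chromosome = rep(chrom, n),
    position = seq(0, by = spacing, length.out = n),
    probe_ids = sprintf("p%04d", 1:n)), class = "baf_lrr_track")
}

test_that("a flat LRR track yields no called events", {
  set.seed(1)
  tr <- flat_track(lrr = rnorm(200, 0, 0.08))
  seg <- segment_lrr(tr)
  expect_equal(nrow(seg), 0L)
})

test_that("threshold arithmetic classifies the event from the mean log2", {
  set.seed(2)
  base <- rnorm(200, 0, 0.05)
  # 40 probes at -2: a homozygous (double) loss
  x <- base; x[81:120] <- x[81:120] - 2
  seg <- segment_lrr(flat_track(lrr = x))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$event, "double_loss")
  expect_equal(seg$n_probes, 40L)
  # 12 probes at -0.45: crosses -0.3 but not -1.1
  x <- base; x[81:92] <- x[81:92] - 0.45
  seg <- segment_lrr(flat_track(lrr = x))
  expect_equal(seg$event, "single_loss")
  # 12 probes at +0.9: beyond the +0.7 double-gain threshold
  x <- base; x[81:92] <- x[81:92] + 0.9
  seg <- segment_lrr(flat_track(lrr = x))
  expect_equal(seg$event, "double_gain")
})

test_that("the minimum-probe rule suppresses 3-probe events", {
  set.seed(3)
  x <- rnorm(200, 0, 0.05)
  x[100:102] <- x[100:102] - 2
  seg <- segment_lrr(flat_track(lrr = x))
  expect_equal(nrow(seg), 0L)
  # the same event with 4 probes is called
  x[103] <- x[103] - 2
  seg <- segment_lrr(flat_track(lrr = x))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 4L)
})

test_that("segments never span probe gaps beyond the spacing limit", {
  set.seed(4)
  # two clusters of probes 2 Mb apart, both shifted low: must be two events
  pos <- c(seq(0, by = 1e5, length.out = 100),
           seq(12e6, by = 1e5, length.out = 100))
  x <- rnorm(200, -1.5, 0.05)
  tr <- flat_track(lrr = x)
  tr$position <- pos
  seg <- segment_lrr(tr)
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$end <= c(100e5, Inf)))
  # and segmentation is deterministic
  expect_identical(seg, segment_lrr(tr))
})

test_that("LRR/BAF tracks anchor diploid samples at 0 and AB at 0.5", {
  sc <- small_cohort(seed = 91, noise_sd = 0, intensity_noise_sd = 0)
  cg <- call_genotypes(sc$cohort$run1)
  track <- compute_lrr_baf(sc$cohort$run1, cg$models, sc$manifest,
                           sex = sc$cohort$sex)
  auto <- sc$manifest$chromosome[match(track$probe_ids,
                                       sc$manifest$probe_id)] != "X"
  expect_true(all(abs(track$lrr[, auto]) < 1e-9))
  het <- sc$cohort$truth == "AB"
  het_baf <- track$baf[, auto][het[, auto] & !is.na(track$baf[, auto])]
  expect_true(all(abs(het_baf - 0.5) < 1e-6))
})

test_that("planted CNVs, aneuploidy and LCSH are recovered with class", {
  man <- simulate_manifest(n_custom = 60, n_backbone = 4000, n_genes = 6,
                           x_gene_fraction = 0, chrom_length_bp = 20e6,
                           seed = 14)
  bb1 <- man[man$probe_class == "backbone" & man$chromosome == "1", ]
  spacing <- diff(bb1$position[1:2])
  cnv <- data.frame(
    sample_id = c("P001", "P002", "P003", "P004", "P005"),
    chromosome = c("1", "2", "8", "7", "5"),
    start = c(2e6, 2e6, 0, 0, 2e6),
    end = c(2e6 + 40 * spacing, 2e6 + 10 * spacing, 20e6, 20e6,
            2e6 + 3 * spacing),
    copy_number = c(0, 1, 3, 1, 0))
  lcsh <- data.frame(sample_id = "P006", chromosome = "4",
                     start = 4e6, end = 14e6)
  cfg <- simulation_config(n_patients = 8, n_controls = 12,
                           run2_patients = 0, run2_controls = 0,
                           noise_sd = 0.03, probe_failure_rate = 0,
                           sample_failure_rate = 0, cnv_events = cnv,
                           lcsh_events = lcsh, seed = 14)
  coh <- simulate_cohort(cfg, man)
  cg <- call_genotypes(coh$run1)
  res <- screen_cnv(coh$run1, cg$models, man, sex = coh$sex)

  recovered <- function(df, s, chrom, start, end, events) {
    hit <- df[df$sample_id == s & df$chromosome == chrom &
                df$event %in% events, , drop = FALSE]
    if (nrow(hit) == 0) return(FALSE)
    ro <- pidscreen:::reciprocal_overlap(start, end, hit$start, hit$end)
    any(ro >= 0.5)
  }
  expect_true(recovered(res$segments, "P001", "1", cnv$start[1], cnv$end[1],
                        "double_loss"))
  expect_true(recovered(res$segments, "P002", "2", cnv$start[2], cnv$end[2],
                        "single_loss"))
  expect_true(recovered(res$lcsh$segments, "P006", "4", 4e6, 14e6, "lcsh"))
  an <- res$aneuploidy
  expect_true(any(an$sample_id == "P003" & an$chromosome == "8" &
                    an$event == "trisomy" & !an$discordant))
  expect_true(any(an$sample_id == "P004" & an$chromosome == "7" &
                    an$event == "monosomy" & !an$discordant))
  # the 3-probe deletion stays uncalled
  expect_false(any(res$segments$sample_id == "P005" &
                     res$segments$chromosome == "5"))
  # called events respect the probe-count and spacing invariants
  expect_true(all(res$segments$n_probes >= 4))
  # LCSH and deletion calls are disjoint per sample/interval
  del <- res$segments[grepl("loss", res$segments$event), ]
  for (i in seq_len(nrow(del))) {
    l <- res$lcsh$segments
    same <- l$sample_id == del$sample_id[i] &
      l$chromosome == del$chromosome[i] &
      l$start < del$end[i] & l$end > del$start[i]
    expect_false(any(same))
  }
  # no whole-chromosome events on a diploid genome
  expect_false(any(an$sample_id %in% coh$controls))
})

test_that("CNV filters: gene overlap, strict benign overlap, recurrence", {
  man <- probe_manifest(data.frame(
    probe_id = sprintf("c%02d", 1:4),
    chromosome = c("1", "1", "2", "2"),
    position = c(1e6, 2e6, 1e6, 2e6),
    ref_allele = "A", alt_allele = "B",
    gene = c("G1", "G1", "G2", "G2"),
    probe_class = "custom_pid_snv"))
  benign <- benign_cnv_track(data.frame(
    chromosome = "1", start = 0, end = 1.2e6, zygosity = "het"))
  seg <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    chromosome = c("1", "1", "1", "3", "2", "2"),
    start = c(1199999, 1199999, 1.3e6, 1e6, 1e6, 1e6),
    end = c(2.5e6, 2.5e6, 1.45e6, 2e6, 2e6, 2e6),
    n_probes = 10L,
    mean_log2 = c(-0.45, -1.5, -0.45, -0.45, -0.45, -0.45),
    event = c("single_loss", "double_loss", "single_loss", "single_loss",
              "single_loss", "single_loss"),
    p_value = 1e-9)
  out <- filter_cnvs(seg, man, benign)
  # S1: heterozygous loss with 1 bp of benign overlap -> dropped
  expect_false("S1" %in% out$sample_id)
  # S2: homozygous loss overlapping benign track -> exempt, retained
  expect_true("S2" %in% out$sample_id)
  # S3: same interval, no benign overlap -> retained
  expect_true("S3" %in% out$sample_id)
  # S4: no PID-gene overlap -> dropped
  expect_false("S4" %in% out$sample_id)
  # S5/S6: identical event in two samples -> recurrence-dropped in both
  expect_false(any(c("S5", "S6") %in% out$sample_id))
})

test_that("LCSH runs tolerate isolated heterozygous probes", {
  hom <- rep(TRUE, 120)
  hom[c(40, 90)] <- FALSE
  runs <- pidscreen:::lcsh_runs(hom, 1 / 50)
  expect_equal(runs[[1]], c(1, 120))
  # too many errors early on break the run
  hom2 <- rep(TRUE, 120)
  hom2[c(10, 12)] <- FALSE
  runs2 <- pidscreen:::lcsh_runs(hom2, 1 / 50)
  expect_equal(runs2[[1]], c(1, 11))
})
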