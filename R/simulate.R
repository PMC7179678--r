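# Synthetic array-data generator.
#
# Emulates a two-run customized genotyping-array experiment over a PID
# patient + control cohort: per-probe three-cluster intensity geometry,
# Hardy-Weinberg backbone genotypes, rare pathogenic genotypes planted into
# patients, probe/sample failures, copy-number events (intensity scaled by
# copy/2, heterozygote channel balance shifted), LCSH regions (forced
# homozygosity at normal intensity), and a second re-noised technical run.
# Every planted event is recorded exactly once in a ledger so downstream
# stages can be validated against known truth.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults reproduce the
#' cohort structure of a two-run screening experiment: 95 patients and 56
#' controls on the first run, 41 patients and 55 controls re-assayed on the
#' second.
#'
#' @param n_patients,n_controls cohort sizes for the first run.
#' @param run2_patients,run2_controls how many patients/controls (taken from
#'   the start of each group) are re-assayed on the second run.
#' @param n_custom_probes,n_backbone_probes probe counts when simulating a
#'   manifest with [simulate_manifest()].
#' @param rare_variant_rate planted pathogenic genotypes per patient.
#' @param cluster_separation angular distance between the heterozygous
#'   cluster and each homozygous cluster on the normalized angle axis, so
#'   the canonical centers sit at `0.5 - s`, `0.5`, `0.5 + s`.
#' @param noise_sd intra-cluster angular spread (Gaussian, on the \[0,1\]
#'   angle axis) of the heterozygote cluster; homozygote clusters are tighter
#'   by the allelic-noise scaling `0.2 + 0.8*sqrt(4f(1-f))`, reflecting that
#'   the off channel sits near background at homozygous genotypes.
#' @param intensity_noise_sd log-scale spread of per-point total intensity
#'   around the per-probe baseline.
#' @param probe_failure_rate,sample_failure_rate per-run fractions of probes
#'   and samples given inflated noise (emulating assay failures).
#' @param failed_samples_run1,failed_samples_run2 explicit sample ids to fail
#'   in a given run, in addition to randomly drawn failures.
#' @param cnv_events data.frame with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `copy_number` (0, 1, 3 or 4; 2 is diploid and not an
#'   event). Whole-chromosome intervals emulate aneuploidy.
#' @param lcsh_events data.frame with columns `sample_id`, `chromosome`,
#'   `start`, `end`.
#' @param seed master integer seed; all stage substreams derive from it, so
#'   a fixed seed gives byte-identical outputs.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 95, n_controls = 56,
                              run2_patients = 41, run2_controls = 55,
                              n_custom_probes = 800, n_backbone_probes = 4000,
                              rare_variant_rate = 1,
                              cluster_separation = 0.45,
                              noise_sd = 0.05,
                              intensity_noise_sd = 0.08,
                              probe_failure_rate = 0.05,
                              sample_failure_rate = 0.02,
                              failed_samples_run1 = character(0),
                              failed_samples_run2 = character(0),
                              cnv_events = NULL, lcsh_events = NULL,
                              seed = 1L) {
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              run2_patients = min(run2_patients, n_patients),
              run2_controls = min(run2_controls, n_controls),
              n_custom_probes = n_custom_probes,
              n_backbone_probes = n_backbone_probes,
              rare_variant_rate = rare_variant_rate,
              cluster_separation = cluster_separation,
              noise_sd = noise_sd,
              intensity_noise_sd = intensity_noise_sd,
              probe_failure_rate = probe_failure_rate,
              sample_failure_rate = sample_failure_rate,
              failed_samples_run1 = failed_samples_run1,
              failed_samples_run2 = failed_samples_run2,
              cnv_events = cnv_events, lcsh_events = lcsh_events,
              seed = as.integer(seed))
  rates <- c(rare = min(rare_variant_rate, 1),
             probe_fail = probe_failure_rate,
             sample_fail = sample_failure_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("failure rates must lie in [0, 1]", call. = FALSE)
  }
  if (cluster_separation <= 0 || cluster_separation > 0.5) {
    stop("cluster_separation must lie in (0, 0.5]", call. = FALSE)
  }
  if (noise_sd < 0 || intensity_noise_sd < 0) {
    stop("noise spreads must be non-negative", call. = FALSE)
  }
  for (ev in list(cfg$cnv_events)) {
    if (!is.null(ev)) {
      stopifnot_cols(ev, c("sample_id", "chromosome", "start", "end",
                           "copy_number"), "cnv_events")
      if (any(!ev$copy_number %in% c(0, 1, 3, 4))) {
        stop("cnv_events copy_number must be 0, 1, 3 or 4", call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$lcsh_events)) {
    stopifnot_cols(cfg$lcsh_events, c("sample_id", "chromosome", "start", "end"),
                   "lcsh_events")
  }
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose top-level keys are arguments of
#'   [simulation_config()]; `cnv_events` and `lcsh_events` are lists of
#'   per-event mappings.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("cnv_events", "lcsh_events")) {
    if (!is.null(y[[field]])) {
      y[[field]] <- do.call(rbind, lapply(y[[field]], as.data.frame))
    }
  }
  do.call(simulation_config, y)
}

#' Simulate a probe manifest
#'
#' Lays out a compact genome: backbone SNPs evenly spaced over chromosomes
#' 1..22 and X, and custom PID-variant probes clustered into genes. A
#' configurable fraction of custom probes are INDEL probes (token alleles
#' `I`/`D`), and a fraction of genes are X-linked.
#'
#' @param n_custom,n_backbone probe counts.
#' @param n_genes number of PID genes to spread the custom probes over.
#' @param indel_fraction fraction of custom probes typed as INDEL
#'   (the remainder are SNV probes).
#' @param x_gene_fraction fraction of genes placed on chromosome X.
#' @param chrom_length_bp simulated chromosome length (same for all
#'   chromosomes).
#' @param seed integer seed.
#' @return A `probe_manifest`.
#' @export
simulate_manifest <- function(n_custom = 800, n_backbone = 4000,
                              n_genes = 40, indel_fraction = 0.2,
                              x_gene_fraction = 0.1,
                              chrom_length_bp = 50e6, seed = 1L) {
  with_substream(seed, "manifest", {
    chroms <- c(as.character(1:22), "X")
    nb_per <- diff(round(seq(0, n_backbone, length.out = length(chroms) + 1)))
    backbone <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      n <- nb_per[i]
      if (n == 0) return(NULL)
      data.frame(probe_id = sprintf("bb_%s_%04d", chroms[i], seq_len(n)),
                 chromosome = chroms[i],
                 position = round(seq(1e5, chrom_length_bp - 1e5,
                                      length.out = n)),
                 ref_allele = "A", alt_allele = "B",
                 gene = "", probe_class = "backbone")
    }))
    n_x_genes <- max(if (x_gene_fraction > 0) 1 else 0,
                     round(n_genes * x_gene_fraction))
    gene_chrom <- c(sample(as.character(1:22), n_genes - n_x_genes,
                           replace = TRUE),
                    rep("X", n_x_genes))
    gene_start <- round(runif(n_genes, 2e5, chrom_length_bp - 2e6))
    per_gene <- diff(round(seq(0, n_custom, length.out = n_genes + 1)))
    custom <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      n <- per_gene[g]
      if (n == 0) return(NULL)
      data.frame(probe_id = sprintf("pid_G%03d_%03d", g, seq_len(n)),
                 chromosome = gene_chrom[g],
                 position = gene_start[g] + sort(sample.int(1e6, n)),
                 ref_allele = "A", alt_allele = "B",
                 gene = sprintf("GENE%03d", g), probe_class = "custom_pid_snv")
    }))
    idx_indel <- sample.int(nrow(custom), round(nrow(custom) * indel_fraction))
    custom$probe_class[idx_indel] <- "custom_pid_indel"
    custom$ref_allele[idx_indel] <- "I"
    custom$alt_allele[idx_indel] <- "D"
    probe_manifest(rbind(custom, backbone))
  })
}

#' Simulate a variant annotation table
#'
#' Annotates the custom probes: most are disease-causing with a rare
#' population frequency; gene-level inheritance patterns are assigned
#' (X-linked genes get `XL`, autosomal genes `AD` or `AR`); a fraction are
#' benign or common, so the pathogenicity and frequency filters have
#' something to remove. Backbone probes stay unannotated.
#'
#' @param manifest a `probe_manifest`.
#' @param benign_fraction fraction of custom probes annotated benign.
#' @param common_fraction fraction of disease-causing probes given a
#'   population frequency at or above the screening cutoff.
#' @param seed integer seed.
#' @return A `variant_annotation`.
#' @export
simulate_annotation <- function(manifest, benign_fraction = 0.1,
                                common_fraction = 0.05, seed = 1L) {
  with_substream(seed, "annotation", {
    cust <- manifest[manifest$probe_class != "backbone", , drop = FALSE]
    genes <- unique(cust$gene)
    gene_chrom <- cust$chromosome[match(genes, cust$gene)]
    inh <- ifelse(gene_chrom == "X", "XL",
                  sample(c("AD", "AR"), length(genes), replace = TRUE))
    names(inh) <- genes
    n <- nrow(cust)
    pathogenicity <- rep("disease_causing", n)
    pathogenicity[seq_len(n) %in% sample.int(n, round(n * benign_fraction))] <-
      sample(c("benign", "likely_benign"), round(n * benign_fraction),
             replace = TRUE)
    freq <- 10^runif(n, -5, -3)
    dc <- which(pathogenicity == "disease_causing")
    common <- sample(dc, round(length(dc) * common_fraction))
    freq[common] <- runif(length(common), 0.005, 0.2)
    freq[pathogenicity != "disease_causing"] <-
      runif(sum(pathogenicity != "disease_causing"), 0.01, 0.4)
    variant_annotation(
      data.frame(probe_id = cust$probe_id,
                 pathogenicity = pathogenicity,
                 pop_frequency = freq,
                 inheritance = unname(inh[cust$gene])),
      manifest)
  })
}

# Map an allelic B fraction in [0,1] to the normalized angle axis through the
# canonical cluster centers.
allelic_fraction_to_angle <- function(f, sep) {
  (0.5 - sep) + f * 2 * sep
}

#' Simulate a two-run array cohort with known truth
#'
#' Generates truth genotypes for the whole cohort (HWE backbone genotypes,
#' rare custom probes that are homozygous-reference except for planted
#' pathogenic carriers), plants the configured CNV and LCSH events and
#' probe/sample failures, and renders two intensity runs over the same truth
#' (the second run re-noised, over the configured sample overlap). All
#' planted events are inventoried exactly once in the returned ledger;
#' CNV events covering fewer than 4 probes are flagged `sub_detectable`.
#'
#' @param config a [simulation_config()].
#' @param manifest a `probe_manifest`.
#' @param annotation a `variant_annotation`; pathogenic planting draws from
#'   its disease-causing probes. If `NULL`, one is simulated from the
#'   manifest.
#' @return A `simulated_cohort` list: `run1`, `run2` (intensity runs),
#'   `truth` (genotype truth matrix, samples x probes, values AA/AB/BB/
#'   missing), `sex` (named vector), `ledger` (planted-event data.frame),
#'   `annotation`, `manifest`, `config`.
#' @export
simulate_cohort <- function(config, manifest, annotation = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(manifest, "probe_manifest"))
  if (is.null(annotation)) {
    annotation <- simulate_annotation(manifest, seed = config$seed)
  }
  seed <- config$seed
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  controls <- sprintf("C%03d", seq_len(config$n_controls))
  samples <- c(patients, controls)
  probes <- manifest$probe_id
  n_s <- length(samples)
  n_p <- length(probes)

  sex <- with_substream(seed, "sex", {
    setNames(sample(c("male", "female"), n_s, replace = TRUE), samples)
  })

  ## --- truth genotypes ------------------------------------------------
  is_backbone <- manifest$probe_class == "backbone"
  is_x <- manifest$chromosome == "X"
  truth <- with_substream(seed, "genotypes", {
    p_b <- ifelse(is_backbone, runif(n_p, 0.05, 0.5), 0)
    g <- matrix(NA_character_, n_s, n_p, dimnames = list(samples, probes))
    male <- sex == "male"
    for (j in seq_len(n_p)) {
      p <- p_b[j]
      if (p == 0) {
        g[, j] <- "AA"
      } else if (is_x[j]) {
        gm <- ifelse(runif(n_s) < p, "BB", "AA")          # hemizygous males
        gf_draw <- runif(n_s)
        gf <- ifelse(gf_draw < p^2, "BB",
                     ifelse(gf_draw < p^2 + 2 * p * (1 - p), "AB", "AA"))
        g[, j] <- ifelse(male, gm, gf)
      } else {
        d <- runif(n_s)
        g[, j] <- ifelse(d < p^2, "BB",
                         ifelse(d < p^2 + 2 * p * (1 - p), "AB", "AA"))
      }
    }
    g
  })

  ledger <- list()

  ## --- planted pathogenic SNVs ----------------------------------------
  planted <- with_substream(seed, "plant_snv", {
    dc <- annotation[annotation$pathogenicity == "disease_causing" &
                       annotation$pop_frequency < 0.005, , drop = FALSE]
    out <- NULL
    if (nrow(dc) > 0 && config$rare_variant_rate > 0) {
      rows <- lapply(patients, function(s) {
        k <- if (config$rare_variant_rate < 1) {
          rbinom(1, 1, config$rare_variant_rate)
        } else {
          round(config$rare_variant_rate)
        }
        if (k == 0) return(NULL)
        pick <- dc[sample.int(nrow(dc), min(k, nrow(dc))), , drop = FALSE]
        data.frame(sample_id = s, probe_id = pick$probe_id,
                   inheritance = pick$inheritance)
      })
      out <- do.call(rbind, rows)
    }
    out
  })
  if (!is.null(planted) && nrow(planted) > 0) {
    m_idx <- match(planted$probe_id, manifest$probe_id)
    planted$gene <- manifest$gene[m_idx]
    planted$chromosome <- manifest$chromosome[m_idx]
    planted$position <- manifest$position[m_idx]
    planted$genotype <- ifelse(
      planted$inheritance == "AD", "AB",
      ifelse(planted$inheritance == "AR", "BB",
             "BB"))  # XL: hemizygous male or homozygous female, both read BB
    for (i in seq_len(nrow(planted))) {
      truth[planted$sample_id[i], planted$probe_id[i]] <- planted$genotype[i]
    }
    ledger$snv <- data.frame(
      type = "snv", sample_id = planted$sample_id,
      chromosome = planted$chromosome, start = planted$position,
      end = planted$position + 1, probe_id = planted$probe_id,
      gene = planted$gene, genotype = planted$genotype,
      inheritance = planted$inheritance, copy_number = NA_real_,
      n_probes = 1L, sub_detectable = FALSE, run = "both")
  }

  ## --- planted LCSH regions -------------------------------------------
  copy_number <- matrix(2, n_s, n_p, dimnames = list(samples, probes))
  lcsh_mask <- matrix(FALSE, n_s, n_p, dimnames = list(samples, probes))
  if (!is.null(config$lcsh_events) && nrow(config$lcsh_events) > 0) {
    ev <- config$lcsh_events
    ev_rows <- with_substream(seed, "plant_lcsh", {
      rows <- vector("list", nrow(ev))
      for (i in seq_len(nrow(ev))) {
        in_ev <- manifest$chromosome == ev$chromosome[i] &
          manifest$position >= ev$start[i] & manifest$position < ev$end[i]
        s <- ev$sample_id[i]
        idx <- which(in_ev)
        if (length(idx) > 0) {
          # force homozygosity, preserving each probe's allele frequency bias
          hom_b <- truth[s, idx] == "BB" |
            (truth[s, idx] == "AB" & runif(length(idx)) < 0.5)
          truth[s, idx] <- ifelse(hom_b, "BB", "AA")
          lcsh_mask[s, idx] <- TRUE
        }
        rows[[i]] <- data.frame(
          type = "lcsh", sample_id = s, chromosome = ev$chromosome[i],
          start = ev$start[i], end = ev$end[i], probe_id = NA_character_,
          gene = NA_character_, genotype = NA_character_,
          inheritance = NA_character_, copy_number = 2,
          n_probes = length(idx), sub_detectable = FALSE, run = "both")
      }
      rows
    })
    ledger$lcsh <- do.call(rbind, ev_rows)
  }

  ## --- planted CNV events ---------------------------------------------
  if (!is.null(config$cnv_events) && nrow(config$cnv_events) > 0) {
    ev <- config$cnv_events
    ev_rows <- with_substream(seed, "plant_cnv", {
      rows <- vector("list", nrow(ev))
      for (i in seq_len(nrow(ev))) {
        in_ev <- manifest$chromosome == ev$chromosome[i] &
          manifest$position >= ev$start[i] & manifest$position < ev$end[i]
        s <- ev$sample_id[i]
        cn <- ev$copy_number[i]
        idx <- which(in_ev)
        copy_number[s, idx] <- cn
        if (cn == 0) {
          truth[s, idx] <- "missing"
        } else if (cn == 1) {
          het <- idx[truth[s, idx] == "AB"]
          keep_b <- runif(length(het)) < 0.5
          truth[s, het] <- ifelse(keep_b, "BB", "AA")
        }
        rows[[i]] <- data.frame(
          type = "cnv", sample_id = s, chromosome = ev$chromosome[i],
          start = ev$start[i], end = ev$end[i], probe_id = NA_character_,
          gene = NA_character_, genotype = NA_character_,
          inheritance = NA_character_, copy_number = cn,
          n_probes = length(idx), sub_detectable = length(idx) < 4,
          run = "both")
      }
      rows
    })
    ledger$cnv <- do.call(rbind, ev_rows)
  }

  ## --- render the two runs --------------------------------------------
  run2_samples <- c(patients[seq_len(config$run2_patients)],
                    controls[seq_len(config$run2_controls)])
  render <- function(run_id, run_samples, explicit_failed) {
    fail <- with_substream(seed, paste0("fail_", run_id), {
      fp <- probes[runif(n_p) < config$probe_failure_rate]
      fs <- run_samples[runif(length(run_samples)) < config$sample_failure_rate]
      list(probes = fp, samples = union(fs, explicit_failed))
    })
    run <- with_substream(seed, paste0("render_", run_id), {
      render_intensities(truth[run_samples, , drop = FALSE],
                         copy_number[run_samples, , drop = FALSE],
                         manifest, sex[run_samples], config,
                         failed_probes = fail$probes,
                         failed_samples = fail$samples,
                         run_id = run_id)
    })
    list(run = run, fail = fail)
  }
  r1 <- render("run1", samples, config$failed_samples_run1)
  r2 <- if (length(run2_samples) > 0) {
    render("run2", run2_samples, config$failed_samples_run2)
  } else {
    list(run = NULL, fail = list(probes = character(0),
                                 samples = character(0)))
  }

  fail_rows <- function(fail, run_id) {
    rows <- NULL
    if (length(fail$probes) > 0) {
      m_idx <- match(fail$probes, manifest$probe_id)
      rows <- data.frame(
        type = "probe_failure", sample_id = NA_character_,
        chromosome = manifest$chromosome[m_idx],
        start = manifest$position[m_idx],
        end = manifest$position[m_idx] + 1, probe_id = fail$probes,
        gene = manifest$gene[m_idx], genotype = NA_character_,
        inheritance = NA_character_, copy_number = NA_real_,
        n_probes = 1L, sub_detectable = FALSE, run = run_id)
    }
    if (length(fail$samples) > 0) {
      rows <- rbind(rows, data.frame(
        type = "sample_failure", sample_id = fail$samples,
        chromosome = NA_character_, start = NA_real_, end = NA_real_,
        probe_id = NA_character_, gene = NA_character_,
        genotype = NA_character_, inheritance = NA_character_,
        copy_number = NA_real_, n_probes = NA_integer_,
        sub_detectable = FALSE, run = run_id))
    }
    rows
  }
  ledger$failures <- rbind(fail_rows(r1$fail, "run1"), fail_rows(r2$fail, "run2"))
  ledger_df <- do.call(rbind, ledger)
  rownames(ledger_df) <- NULL

  structure(list(run1 = r1$run, run2 = r2$run, truth = truth, sex = sex,
                 ledger = ledger_df, annotation = annotation,
                 manifest = manifest, config = config,
                 patients = patients, controls = controls),
            class = "simulated_cohort")
}

# Render raw two-channel intensities for one run from truth genotypes and
# per-entry copy number.
render_intensities <- function(truth, copy_number, manifest, sex, config,
                               failed_probes, failed_samples, run_id) {
  samples <- rownames(truth)
  probes <- colnames(truth)
  n_s <- length(samples)
  n_p <- length(probes)
  sep <- config$cluster_separation

  baseline <- exp(rnorm(n_p, log(2000), 0.1))
  male <- sex == "male"
  is_x <- manifest$chromosome[match(probes, manifest$probe_id)] == "X"

  # effective copies: males carry one X
  cn <- copy_number
  if (any(is_x) && any(male)) {
    cn[male, is_x] <- pmin(cn[male, is_x], 1)
  }

  # allelic B fraction per entry given genotype and copy number
  n_b <- matrix(NA_real_, n_s, n_p)
  n_b[truth == "AA"] <- 0
  n_b[truth == "AB"] <- 0.5
  n_b[truth == "BB"] <- 1
  frac <- n_b
  tri <- cn >= 3 & truth == "AB"
  if (any(tri)) {
    # the duplicated allele is drawn, giving the AAB/ABB balance
    dup_b <- matrix(runif(n_s * n_p) < 0.5, n_s, n_p)
    frac[tri] <- ifelse(dup_b[tri], 2 / cn[tri], 1 / cn[tri])
  }
  hemi <- cn == 1 & truth == "AB"   # should not occur: planting resolves hets
  frac[hemi] <- round(frac[hemi])

  angle <- allelic_fraction_to_angle(frac, sep)
  # allelic-ratio noise is widest for heterozygotes (both channels carry
  # signal) and tight at homozygotes, where the off channel is near
  # background; noise_sd is the heterozygote-cluster angular spread
  sd_scale <- 0.2 + 0.8 * sqrt(pmax(4 * frac * (1 - frac), 0))
  sd_scale[is.na(sd_scale)] <- 1
  noise <- matrix(rnorm(n_s * n_p), n_s, n_p) * config$noise_sd * sd_scale
  angle <- angle + noise

  # failures: garbage angles
  fp <- probes %in% failed_probes
  fs <- samples %in% failed_samples
  n_fail_p <- sum(fp)
  if (n_fail_p > 0) {
    angle[, fp] <- matrix(runif(n_s * n_fail_p), n_s, n_fail_p)
  }
  n_fail_s <- sum(fs)
  if (n_fail_s > 0) {
    angle[fs, ] <- angle[fs, , drop = FALSE] +
      matrix(rnorm(n_fail_s * n_p, 0, 0.35), n_fail_s, n_p)
  }
  # deleted genome: no allelic signal at all
  zero <- cn == 0
  angle[zero] <- runif(sum(zero))
  angle <- pmin(pmax(angle, 0), 1)

  dose <- pmax(cn / 2, 0.07)  # background hybridization floor at copy 0
  total <- matrix(baseline, n_s, n_p, byrow = TRUE) * dose *
    exp(matrix(rnorm(n_s * n_p, 0, config$intensity_noise_sd), n_s, n_p))

  # partition total by tan(phi): y/x = tan(phi) => x = total/(1+tan(phi))
  phi <- angle * pi / 2
  tanphi <- tan(phi)
  x <- ifelse(is.infinite(tanphi), 0, total / (1 + tanphi))
  y <- total - x
  dimnames(x) <- dimnames(y) <- list(samples, probes)
  intensity_run(run_id, x, y)
}

#' Construct an intensity run
#'
#' @param run_id label for the run.
#' @param x,y non-negative channel-intensity matrices (samples x probes):
#'   `x` is the A-allele channel, `y` the B-allele channel.
#' @return An `intensity_run` object.
#' @export
intensity_run <- function(run_id, x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            !is.null(rownames(x)), !is.null(colnames(x)))
  if (any(x < 0) || any(y < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  structure(list(run_id = run_id, x = x, y = y,
                 sample_ids = rownames(x), probe_ids = colnames(x)),
            class = "intensity_run")
}

#' @export
print.intensity_run <- function(x, ...) {
  cat(sprintf("Intensity run '%s': %d samples x %d probes\n",
              x$run_id, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Truth matrix as long-format truth genotypes
#'
#' Flattens the simulator's truth matrix into the long (sample, probe,
#' genotype) record form used by the concordance evaluator, emulating
#' genotypes called from deep sequencing of the same samples.
#'
#' @param cohort a `simulated_cohort`.
#' @param samples optional subset of sample ids.
#' @return A `truth_genotypes` data.frame.
#' @export
truth_as_genotypes <- function(cohort, samples = NULL) {
  tr <- cohort$truth
  if (!is.null(samples)) tr <- tr[samples, , drop = FALSE]
  truth_genotypes(data.frame(
    sample_id = rep(rownames(tr), times = ncol(tr)),
    probe_id = rep(colnames(tr), each = nrow(tr)),
    genotype = as.vector(tr)))
}
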