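# Shared fixtures: tiny hand-built tables plus small simulated cohorts.

tiny_manifest_df <- function() {
  data.frame(
    probe_id = c("p1", "p2", "p3", "px1", "px2"),
    chromosome = c("1", "1", "2", "X", "X"),
    position = c(100, 50, 0, 500, 900),
    ref_allele = c("A", "C", "G", "A", "T"),
    alt_allele = c("G", "T", "A", "C", "G"),
    gene = c("GENE1", "GENE1", "", "GENEX", "GENEX"),
    probe_class = c("custom_pid_snv", "custom_pid_snv", "backbone",
                    "custom_pid_snv", "custom_pid_indel"))
}

tiny_manifest <- function() probe_manifest(tiny_manifest_df())

tiny_annotation <- function(manifest = tiny_manifest()) {
  variant_annotation(data.frame(
    probe_id = c("p1", "p2", "px1", "px2"),
    pathogenicity = c("disease_causing", "benign", "disease_causing",
                      "disease_causing"),
    pop_frequency = c(1e-4, 0.3, 2e-4, NA),
    inheritance = c("AD", "none", "XL", "XL")), manifest)
}

# A genotype matrix from a compact character matrix; scores default to 0.9.
gm_from_calls <- function(calls, caller = NULL) {
  score <- matrix(0.9, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  score[calls == "nocall"] <- NA_real_
  genotype_matrix(calls, score, caller)
}

# Small noisy cohort used by several calling/QC tests.
small_cohort <- function(seed = 42, noise_sd = 0.04, n_patients = 12,
                         n_controls = 10, n_custom = 80, n_backbone = 300,
                         ...) {
  man <- simulate_manifest(n_custom = n_custom, n_backbone = n_backbone,
                           n_genes = 8, seed = seed)
  ann <- simulate_annotation(man, seed = seed)
  cfg <- simulation_config(n_patients = n_patients, n_controls = n_controls,
                           run2_patients = 6, run2_controls = 6,
                           noise_sd = noise_sd, probe_failure_rate = 0,
                           sample_failure_rate = 0, seed = seed, ...)
  list(manifest = man, annotation = ann, config = cfg,
       cohort = simulate_cohort(cfg, man, ann))
}

# Independent direct-enumeration oracle for the exact HWE test: conditional
# probability of each heterozygote count from the closed-form expression
# with log-factorials.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (min(n_a, n_b) == 0) return(1)
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
      lfactorial((n_b - h) / 2) + h * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}
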