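# Array QC cascade: call-rate filters before and after rare-variant
# recalling, exact Hardy-Weinberg exclusion, and sex inference from
# X-chromosome heterozygosity.

#' QC thresholds
#'
#' The screening QC cascade: probe and sample call-rate thresholds of 97.5%
#' applied to primary calls, Hardy-Weinberg exclusion at P < 1e-4, then a
#' stricter 98% probe and sample call-rate filter after rare-variant
#' recalling.
#'
#' @param snp_call_rate_primary,sample_call_rate_primary call-rate
#'   thresholds on primary calls.
#' @param hwe_p_cut exact-test p-value below which a probe is excluded.
#' @param snp_call_rate_post_zcall,sample_call_rate_post_zcall stricter
#'   thresholds applied after recalling.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(snp_call_rate_primary = 0.975,
                          sample_call_rate_primary = 0.975,
                          hwe_p_cut = 1e-4,
                          snp_call_rate_post_zcall = 0.98,
                          sample_call_rate_post_zcall = 0.98) {
  rates <- c(snp_call_rate_primary, sample_call_rate_primary,
             snp_call_rate_post_zcall, sample_call_rate_post_zcall)
  if (any(rates <= 0 | rates > 1)) {
    stop("call-rate thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (hwe_p_cut <= 0 || hwe_p_cut >= 1) {
    stop("hwe_p_cut must lie in (0, 1)", call. = FALSE)
  }
  structure(list(snp_call_rate_primary = snp_call_rate_primary,
                 sample_call_rate_primary = sample_call_rate_primary,
                 hwe_p_cut = hwe_p_cut,
                 snp_call_rate_post_zcall = snp_call_rate_post_zcall,
                 sample_call_rate_post_zcall = sample_call_rate_post_zcall),
            class = "qc_thresholds")
}

#' Call rate per probe or per sample
#'
#' Fraction of non-missing genotype calls, per probe (over samples) or per
#' sample (over probes).
#'
#' @param calls a `genotype_matrix` or a call matrix.
#' @param margin `"probe"` or `"sample"`.
#' @return Named numeric vector of call rates.
#' @export
call_rate <- function(calls, margin = c("probe", "sample")) {
  margin <- match.arg(margin)
  m <- if (inherits(calls, "genotype_matrix")) calls$calls else calls
  called <- m != NOCALL
  if (margin == "probe") colMeans(called) else rowMeans(called)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration (the standard recurrence-based formulation used by common
#' genetics toolkits). Monomorphic probes are untestable and return 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("counts must be non-negative",
                                         call. = FALSE)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  # probability of each het count via the recurrence
  # P(h-2)/P(h) = h*(h-1) / ((na-h)/2+1)/((nb-h)/2+1) ... built upward from
  # the mid configuration for numerical stability
  probs <- numeric(length(het_vals))
  mid_idx <- which.min(abs(het_vals - rare * (2 * n - rare) / (2 * n)))
  probs[mid_idx] <- 1
  if (mid_idx < length(het_vals)) {
    for (i in (mid_idx + 1):length(het_vals)) {
      h <- het_vals[i]
      hom_a <- (n_a - h) / 2
      hom_b <- (n_b - h) / 2
      # going up from h-2 to h
      probs[i] <- probs[i - 1] * 4 * (hom_a + 1) * (hom_b + 1) / (h * (h - 1))
    }
  }
  if (mid_idx > 1) {
    for (i in (mid_idx - 1):1) {
      h <- het_vals[i]
      hom_a <- (n_a - h) / 2
      hom_b <- (n_b - h) / 2
      # going down from h+2 to h
      probs[i] <- probs[i + 1] * (h + 2) * (h + 1) / (4 * hom_a * hom_b)
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, het_vals)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Infer sample sex from X heterozygosity
#'
#' X-chromosome heterozygosity is near zero in males (hemizygous X) and
#' matches Hardy-Weinberg expectations in females. Samples with fewer than
#' `min_x_probes` called X probes are `ambiguous`.
#'
#' @param calls a `genotype_matrix` or call matrix.
#' @param manifest the `probe_manifest`.
#' @param male_max,female_min X-het-rate thresholds for male / female.
#' @param min_x_probes minimum called X probes required.
#' @return Named character vector: `male`, `female` or `ambiguous`.
#' @export
infer_sex <- function(calls, manifest, male_max = 0.05, female_min = 0.20,
                      min_x_probes = 50) {
  m <- if (inherits(calls, "genotype_matrix")) calls$calls else calls
  x_probes <- intersect(colnames(m),
                        manifest$probe_id[manifest$chromosome == "X"])
  mx <- m[, x_probes, drop = FALSE]
  n_called <- rowSums(mx != NOCALL)
  n_het <- rowSums(mx == "AB")
  rate <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  sex <- rep("ambiguous", nrow(m))
  ok <- n_called >= min_x_probes
  sex[ok & rate < male_max] <- "male"
  sex[ok & rate > female_min] <- "female"
  setNames(sex, rownames(m))
}

#' Apply the QC cascade to a called run
#'
#' Filters are applied in the fixed order: primary probe call rate, primary
#' sample call rate, Hardy-Weinberg exclusion (autosomes over all retained
#' samples; chromosome X over inferred females; Y untested), then the
#' post-recalling 98% probe and sample call-rate filters on the recalled
#' matrix. Each excluded item records the first rule it failed.
#'
#' @param calls the result of [call_genotypes()] (needs both the `primary`
#'   and `recalled` matrices), or a list with those two elements.
#' @param manifest the `probe_manifest`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (the filtered post-recalling
#'   `genotype_matrix`) and `report` (a `qc_report`: exclusions with
#'   reasons, inferred sex, pass/fail counts).
#' @export
apply_qc <- function(calls, manifest, thresholds = qc_thresholds()) {
  primary <- calls$primary
  recalled <- calls$recalled
  stopifnot(inherits(primary, "genotype_matrix"),
            inherits(recalled, "genotype_matrix"))
  probes <- colnames(primary$calls)
  samples <- rownames(primary$calls)
  excl_probes <- character(0); excl_probe_reason <- character(0)
  excl_samples <- character(0); excl_sample_reason <- character(0)

  keep_p <- probes
  keep_s <- samples

  # 1. primary probe call rate
  cr <- call_rate(subset_genotypes(primary, keep_s, keep_p), "probe")
  fail <- names(cr)[cr < thresholds$snp_call_rate_primary]
  excl_probes <- c(excl_probes, fail)
  excl_probe_reason <- c(excl_probe_reason, rep("low_call_rate", length(fail)))
  keep_p <- setdiff(keep_p, fail)

  # 2. primary sample call rate
  cr <- call_rate(subset_genotypes(primary, keep_s, keep_p), "sample")
  fail <- names(cr)[cr < thresholds$sample_call_rate_primary]
  excl_samples <- c(excl_samples, fail)
  excl_sample_reason <- c(excl_sample_reason,
                          rep("low_call_rate", length(fail)))
  keep_s <- setdiff(keep_s, fail)
  if (length(keep_s) == 0) stop("QC excluded every sample", call. = FALSE)

  # 3. Hardy-Weinberg exclusion
  sex <- infer_sex(subset_genotypes(primary, keep_s, keep_p), manifest)
  chrom <- manifest$chromosome[match(keep_p, manifest$probe_id)]
  females <- names(sex)[sex == "female"]
  hwe_p <- vapply(seq_along(keep_p), function(j) {
    p <- keep_p[j]
    if (is.na(chrom[j]) || chrom[j] == "Y") return(NA_real_)
    use_s <- if (chrom[j] == "X") females else keep_s
    if (length(use_s) == 0) return(NA_real_)
    g <- primary$calls[use_s, p]
    hwe_exact_p(sum(g == "AA"), sum(g == "AB"), sum(g == "BB"))
  }, numeric(1))
  fail <- keep_p[!is.na(hwe_p) & hwe_p < thresholds$hwe_p_cut]
  excl_probes <- c(excl_probes, fail)
  excl_probe_reason <- c(excl_probe_reason, rep("hwe", length(fail)))
  keep_p <- setdiff(keep_p, fail)

  # 4-5. post-recalling stricter filters on the recalled matrix
  cr <- call_rate(subset_genotypes(recalled, keep_s, keep_p), "probe")
  fail <- names(cr)[cr < thresholds$snp_call_rate_post_zcall]
  excl_probes <- c(excl_probes, fail)
  excl_probe_reason <- c(excl_probe_reason,
                         rep("post_zcall_rate", length(fail)))
  keep_p <- setdiff(keep_p, fail)

  cr <- call_rate(subset_genotypes(recalled, keep_s, keep_p), "sample")
  fail <- names(cr)[cr < thresholds$sample_call_rate_post_zcall]
  excl_samples <- c(excl_samples, fail)
  excl_sample_reason <- c(excl_sample_reason,
                          rep("post_zcall_rate", length(fail)))
  keep_s <- setdiff(keep_s, fail)
  if (length(keep_s) == 0) stop("QC excluded every sample", call. = FALSE)

  report <- structure(list(
    excluded_probes = data.frame(probe_id = excl_probes,
                                 reason = excl_probe_reason),
    excluded_samples = data.frame(sample_id = excl_samples,
                                  reason = excl_sample_reason),
    sex = sex,
    n_probes_in = length(probes), n_probes_retained = length(keep_p),
    n_samples_in = length(samples), n_samples_retained = length(keep_s),
    thresholds = thresholds), class = "qc_report")
  list(genotypes = subset_genotypes(recalled, keep_s, keep_p),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d probes retained, %d/%d samples retained\n",
              x$n_probes_retained, x$n_probes_in,
              x$n_samples_retained, x$n_samples_in))
  if (nrow(x$excluded_probes) > 0) {
    print(table(x$excluded_probes$reason))
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  obj <- list(
    n_probes_in = report$n_probes_in,
    n_probes_retained = report$n_probes_retained,
    n_samples_in = report$n_samples_in,
    n_samples_retained = report$n_samples_retained,
    excluded_probes = report$excluded_probes,
    excluded_samples = report$excluded_samples,
    sex = as.list(report$sex))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
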