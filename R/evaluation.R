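# Validation statistics and screening economics: array-vs-truth genotype
# concordance, variant-level sensitivity, patient-level diagnostic yield,
# inter-run reproducibility, and the screen-then-sequence cost model.
#
# Reporting precision follows array-validation convention: one decimal for
# concordance, confirmation and reproducibility percentages, integers for
# sensitivity and yield, all rounded half away from zero.

#' Genotype concordance against sequencing truth
#'
#' Compares post-QC array calls with truth genotypes over the overlapping
#' samples, restricted to custom SNV probes (INDEL probes are typed with
#' the same chemistry but flagged out of the sequencing comparison).
#' A (sample, probe) pair is compared when the array made a call and the
#' truth genotype is not missing. Non-reference array calls are also
#' tallied separately, since those are the screen's positive findings; the
#' non-reference mismatch rate is reported against both defensible
#' denominators (non-reference calls and compared probes).
#'
#' @param calls the post-QC `genotype_matrix`.
#' @param truth a `truth_genotypes` data.frame.
#' @param manifest the `probe_manifest`.
#' @param scope_classes probe classes entering the comparison.
#' @param excluded_probes probes excluded up front (known malfunctioning
#'   probes from a previous validation).
#' @return A `concordance_report` list: `n_compared`, `n_matching`,
#'   `percent_concordance` (1 decimal), `n_nonref_calls`,
#'   `n_nonref_mismatches`, `nonref_mismatch_percent_of_nonref`,
#'   `nonref_mismatch_percent_of_compared`, `discordant_probes`,
#'   `excluded_probes`.
#' @export
concordance <- function(calls, truth, manifest,
                        scope_classes = "custom_pid_snv",
                        excluded_probes = character(0)) {
  scope <- manifest$probe_id[manifest$probe_class %in% scope_classes]
  probes <- setdiff(intersect(colnames(calls$calls), scope), excluded_probes)
  samples <- intersect(rownames(calls$calls), unique(truth$sample_id))
  if (length(samples) == 0) {
    stop("no overlapping samples between calls and truth", call. = FALSE)
  }
  tr <- truth[truth$sample_id %in% samples & truth$probe_id %in% probes, ,
              drop = FALSE]
  arr <- calls$calls[cbind(match(tr$sample_id, rownames(calls$calls)),
                           match(tr$probe_id, colnames(calls$calls)))]
  use <- arr != NOCALL & tr$genotype != "missing"
  arr <- arr[use]
  tru <- tr$genotype[use]
  probe_of <- tr$probe_id[use]
  match_vec <- arr == tru
  nonref <- arr %in% c("AB", "BB")
  n_compared <- length(arr)
  n_matching <- sum(match_vec)
  n_nonref <- sum(nonref)
  n_nonref_mm <- sum(nonref & !match_vec)
  structure(list(
    n_compared = n_compared, n_matching = n_matching,
    percent_concordance = round_half_up(100 * n_matching /
                                          max(n_compared, 1), 1),
    n_nonref_calls = n_nonref, n_nonref_mismatches = n_nonref_mm,
    nonref_mismatch_percent_of_nonref =
      round_half_up(100 * n_nonref_mm / max(n_nonref, 1), 2),
    nonref_mismatch_percent_of_compared =
      round_half_up(100 * n_nonref_mm / max(n_compared, 1), 2),
    discordant_probes = sort(unique(probe_of[!match_vec])),
    excluded_probes = excluded_probes), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d (%.1f%%); non-reference mismatches %d of %d non-ref calls\n",
              x$n_matching, x$n_compared, x$percent_concordance,
              x$n_nonref_mismatches, x$n_nonref_calls))
  invisible(x)
}

VARIANT_CATEGORIES <- c("replicated_known", "missed_probe_failed",
                        "missed_no_probe", "new_confirmed", "new_refuted",
                        "new_unconfirmable")

#' Variant-level sensitivity and confirmation statistics
#'
#' Summarizes assessed variants by category and derives the screening
#' sensitivities. Categories: `replicated_known` (known variant, probe on
#' the array, replicated by the screen), `missed_probe_failed` (known,
#' probe present, not replicated), `missed_no_probe` (known but no probe on
#' the array: excluded from the sensitivity denominator),
#' `new_confirmed` / `new_refuted` (variants newly found by the screen that
#' confirmation testing verified or rejected), `new_unconfirmable` (newly
#' found, confirmation impossible, e.g. no DNA left: excluded).
#'
#' Known-variant sensitivity is `replicated / (replicated + probe_failed)`;
#' overall sensitivity adds the confirmation-tested new variants to both
#' sides: `(replicated + new_confirmed) / (replicated + probe_failed +
#' new_confirmed + new_refuted)`. The confirmation rate is
#' `new_confirmed / (new_confirmed + new_refuted)`.
#'
#' @param categories character vector with one category per assessed
#'   variant.
#' @return A `yield_report` list of counts and percentages (sensitivities
#'   as integers, confirmation rate at 1 decimal); undefined ratios are
#'   `NA`.
#' @export
sensitivity_report <- function(categories) {
  bad <- setdiff(unique(categories), VARIANT_CATEGORIES)
  if (length(bad) > 0) {
    stop(sprintf("unknown variant category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  n <- vapply(VARIANT_CATEGORIES, function(cc) sum(categories == cc),
              integer(1))
  denom_known <- n[["replicated_known"]] + n[["missed_probe_failed"]]
  denom_overall <- denom_known + n[["new_confirmed"]] + n[["new_refuted"]]
  n_tested_new <- n[["new_confirmed"]] + n[["new_refuted"]]
  structure(list(
    counts = n,
    sensitivity_known = if (denom_known > 0) {
      round_half_up(100 * n[["replicated_known"]] / denom_known)
    } else NA_real_,
    sensitivity_overall = if (denom_overall > 0) {
      round_half_up(100 * (n[["replicated_known"]] + n[["new_confirmed"]]) /
                      denom_overall)
    } else NA_real_,
    confirmation_percent = if (n_tested_new > 0) {
      round_half_up(100 * n[["new_confirmed"]] / n_tested_new, 1)
    } else NA_real_), class = "yield_report")
}

#' Patient-level diagnostic yield
#'
#' @param diagnoses data.frame with per-patient `status`
#'   (`genetic_diagnosis` / `no_diagnosis`), as produced by
#'   [match_inheritance()], or a logical vector (TRUE = diagnosed).
#' @return list: `n_diagnosed`, `n_total`, `yield_percent` (integer
#'   percent).
#' @export
diagnostic_yield <- function(diagnoses) {
  diagnosed <- if (is.data.frame(diagnoses)) {
    diagnoses$status == "genetic_diagnosis"
  } else {
    as.logical(diagnoses)
  }
  n <- length(diagnosed)
  d <- sum(diagnosed)
  list(n_diagnosed = d, n_total = n,
       yield_percent = round_half_up(100 * d / max(n, 1)))
}

#' Inter-run reproducibility
#'
#' Two complementary views over the samples assayed in both runs: at the
#' patient level, the fraction of patients diagnosed in run 1 whose causal
#' finding (same gene) replicates in run 2; at the genotype level, the
#' discordance rate over entries called in both runs at shared post-QC
#' custom probes.
#'
#' @param calls1,calls2 post-QC `genotype_matrix` objects for the two runs.
#' @param manifest the `probe_manifest`.
#' @param diagnoses1,diagnoses2 optional per-patient diagnosis data.frames
#'   (from [match_inheritance()]) for the patient-level comparison.
#' @param scope_classes probe classes entering the genotype comparison.
#' @return list: `n_overlap_samples`, `n_shared_probes`, `n_compared`,
#'   `n_discordant`, `discordance_percent` (2 decimals),
#'   `n_diagnosed_run1`, `n_replicated`, `patient_percent` (1 decimal, NA
#'   when no diagnoses supplied).
#' @export
reproducibility <- function(calls1, calls2, manifest,
                            diagnoses1 = NULL, diagnoses2 = NULL,
                            scope_classes = c("custom_pid_snv",
                                              "custom_pid_indel")) {
  samples <- intersect(rownames(calls1$calls), rownames(calls2$calls))
  if (length(samples) == 0) {
    stop("no overlapping samples between the two runs", call. = FALSE)
  }
  scope <- manifest$probe_id[manifest$probe_class %in% scope_classes]
  probes <- intersect(intersect(colnames(calls1$calls),
                                colnames(calls2$calls)), scope)
  g1 <- calls1$calls[samples, probes, drop = FALSE]
  g2 <- calls2$calls[samples, probes, drop = FALSE]
  both <- g1 != NOCALL & g2 != NOCALL
  n_compared <- sum(both)
  n_discordant <- sum(g1[both] != g2[both])

  patient_percent <- NA_real_
  n_diag1 <- NA_integer_
  n_repl <- NA_integer_
  if (!is.null(diagnoses1) && !is.null(diagnoses2)) {
    d1 <- diagnoses1[diagnoses1$status == "genetic_diagnosis" &
                       diagnoses1$sample_id %in% samples, , drop = FALSE]
    n_diag1 <- nrow(d1)
    if (n_diag1 > 0) {
      g2map <- setNames(diagnoses2$genes, diagnoses2$sample_id)
      repl <- vapply(seq_len(n_diag1), function(i) {
        s <- d1$sample_id[i]
        genes1 <- strsplit(d1$genes[i], ";")[[1]]
        genes2 <- strsplit(g2map[s] %||% "", ";")[[1]]
        length(intersect(genes1, genes2)) > 0
      }, logical(1))
      n_repl <- sum(repl)
      patient_percent <- round_half_up(100 * n_repl / n_diag1, 1)
    }
  }
  list(n_overlap_samples = length(samples), n_shared_probes = length(probes),
       n_compared = n_compared, n_discordant = n_discordant,
       discordance_percent = round_half_up(100 * n_discordant /
                                             max(n_compared, 1), 2),
       n_diagnosed_run1 = n_diag1, n_replicated = n_repl,
       patient_percent = patient_percent)
}

#' Write a per-patient screen report as JSON
#'
#' Bundles the per-patient outcome (diagnosis status, diagnostic genes,
#' retained candidate variants) with cohort-level summary statistics.
#'
#' @param screen result of [screen_snv()].
#' @param path output path.
#' @param cnv_findings optional result of [screen_cnv()]; filtered CNV
#'   events and aneuploidy calls are included when given.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path, cnv_findings = NULL) {
  yield <- diagnostic_yield(screen$diagnoses)
  obj <- list(
    patients = screen$diagnoses,
    candidates = as.data.frame(screen$candidates),
    attrition = as.list(screen$attrition),
    n_diagnosed = yield$n_diagnosed,
    n_patients = yield$n_total,
    yield_percent = yield$yield_percent)
  if (!is.null(cnv_findings)) {
    obj$cnv_events <- as.data.frame(cnv_findings$filtered)
    obj$aneuploidy <- cnv_findings$aneuploidy
    obj$lcsh_burden <- cnv_findings$lcsh$burden
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Screening cost model
#'
#' @param array_cost_per_sample,ngs_cost_per_sample per-sample costs (any
#'   fixed currency; defaults in Euro).
#' @param cohort_size number of patients screened.
#' @param screen_yield_fraction fraction of patients diagnosed by the array
#'   screen (they skip sequencing).
#' @return A `cost_model` list.
#' @export
cost_model <- function(array_cost_per_sample = 40,
                       ngs_cost_per_sample = 1000,
                       cohort_size = 100, screen_yield_fraction = 0.4) {
  if (array_cost_per_sample <= 0 || ngs_cost_per_sample <= 0) {
    stop("costs must be positive", call. = FALSE)
  }
  if (screen_yield_fraction < 0 || screen_yield_fraction > 1) {
    stop("screen_yield_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(array_cost_per_sample = array_cost_per_sample,
                 ngs_cost_per_sample = ngs_cost_per_sample,
                 cohort_size = cohort_size,
                 screen_yield_fraction = screen_yield_fraction),
            class = "cost_model")
}

#' Compare screen-then-sequence against sequence-everyone costs
#'
#' The screening arm pays the array for everyone plus sequencing for the
#' patients the screen leaves undiagnosed; the comparator sequences
#' everyone directly.
#'
#' @param model a [cost_model()].
#' @return list: `initial_array_cost`, `screen_then_sequence_total`,
#'   `sequence_all_total`, `saving`.
#' @export
cost_compare <- function(model) {
  n <- model$cohort_size
  initial <- n * model$array_cost_per_sample
  screen_total <- initial +
    n * (1 - model$screen_yield_fraction) * model$ngs_cost_per_sample
  seq_all <- n * model$ngs_cost_per_sample
  list(initial_array_cost = initial,
       screen_then_sequence_total = screen_total,
       sequence_all_total = seq_all,
       saving = seq_all - screen_total)
}
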