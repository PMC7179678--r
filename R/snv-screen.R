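# The SNV filter cascade: post-QC genotypes -> per-patient candidate
# diagnostic variants. Filter order is fixed: pathogenicity class ->
# population frequency -> cohort recurrence -> male X-heterozygote removal
# -> cluster-quality (signal-intensity) review -> inheritance matching.

new_candidates <- function(df) {
  df <- df[order(df$sample_id, df$probe_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("candidate_set", "data.frame")
  df
}

#' Select non-reference calls at disease-causing probes
#'
#' Seeds the cascade: every non-reference post-QC call (het or homozygous
#' alternate) at a probe annotated `disease_causing`. Non-reference calls at
#' unannotated or benign probes are dropped and counted.
#'
#' @param calls the post-QC `genotype_matrix`.
#' @param annotation a `variant_annotation`.
#' @return A `candidate_set` data.frame (`sample_id`, `probe_id`, `call`,
#'   `zygosity`, `caller`, `flagged_for_review`, `filter_trail`), with
#'   attributes `n_nonref` and `n_dropped_not_disease_causing`.
#' @export
select_disease_causing <- function(calls, annotation) {
  m <- calls$calls
  idx <- which(m == "AB" | m == "BB", arr.ind = TRUE)
  cand <- data.frame(
    sample_id = rownames(m)[idx[, 1]],
    probe_id = colnames(m)[idx[, 2]],
    call = m[idx],
    zygosity = ifelse(m[idx] == "AB", "het", "hom"),
    caller = calls$caller[idx],
    flagged_for_review = FALSE,
    filter_trail = "disease_causing")
  dc <- annotation$probe_id[annotation$pathogenicity == "disease_causing"]
  keep <- cand$probe_id %in% dc
  out <- new_candidates(cand[keep, , drop = FALSE])
  attr(out, "n_nonref") <- nrow(cand)
  attr(out, "n_dropped_not_disease_causing") <- sum(!keep)
  out
}

append_trail <- function(cands, tag) {
  if (nrow(cands) > 0) {
    cands$filter_trail <- paste(cands$filter_trail, tag, sep = ";")
  }
  cands
}

#' Population-frequency filter
#'
#' Keeps candidates whose annotated population frequency is strictly below
#' the cutoff. Probes without a frequency annotation are treated as
#' unobserved in the population (frequency 0) and retained; their count is
#' reported in the `n_missing_frequency` attribute.
#'
#' @param cands a `candidate_set`.
#' @param annotation a `variant_annotation`.
#' @param cutoff exclusive frequency threshold (default 0.5%).
#' @return The filtered `candidate_set`.
#' @export
frequency_filter <- function(cands, annotation, cutoff = 0.005) {
  freq <- annotation$pop_frequency[match(cands$probe_id, annotation$probe_id)]
  n_missing <- sum(is.na(freq))
  freq[is.na(freq)] <- 0
  out <- new_candidates(append_trail(cands[freq < cutoff, , drop = FALSE],
                                     "frequency"))
  attr(out, "n_missing_frequency") <- n_missing
  out
}

#' Cohort recurrence filter
#'
#' Drops variants carried (non-reference) by two or more samples in the run:
#' rare pathogenic variants should be singletons in a modest cohort, so
#' recurrence indicates a faulty probe.
#'
#' @param cands a `candidate_set`.
#' @param calls the post-QC `genotype_matrix` the candidates came from
#'   (carrier counts are over the whole run, not just surviving candidates).
#' @return The filtered `candidate_set`.
#' @export
recurrence_filter <- function(cands, calls) {
  m <- calls$calls
  carriers <- colSums(m == "AB" | m == "BB")
  keep <- carriers[cands$probe_id] < 2
  new_candidates(append_trail(cands[keep, , drop = FALSE], "singleton"))
}

#' Male X-heterozygote filter
#'
#' Heterozygous calls on chromosome X in males are artifacts (males are
#' hemizygous) and are removed; male X homozygous-alternate calls are
#' relabelled `hemizygous`. Candidates in samples of ambiguous sex are
#' retained but flagged for review.
#'
#' @param cands a `candidate_set`.
#' @param sex named per-sample vector from [infer_sex()].
#' @param manifest the `probe_manifest`.
#' @return The filtered `candidate_set`.
#' @export
male_x_het_filter <- function(cands, sex, manifest) {
  chrom <- manifest$chromosome[match(cands$probe_id, manifest$probe_id)]
  s <- sex[cands$sample_id]
  on_x <- chrom == "X"
  drop <- on_x & s == "male" & cands$zygosity == "het"
  cands$zygosity[on_x & s == "male" & cands$zygosity == "hom"] <- "hemizygous"
  cands$flagged_for_review <- cands$flagged_for_review |
    (on_x & s == "ambiguous")
  new_candidates(append_trail(cands[!drop, , drop = FALSE], "male_x_het"))
}

#' Cluster-quality check
#'
#' Automated stand-in for the manual SNP-graph review: a candidate is
#' excluded when its point lies more than `k` spreads from its called
#' cluster center on the angle axis, or when its total intensity falls below
#' the probe's `intensity_quantile` quantile (a dropout). Points between
#' `k - 1` and `k` spreads are retained but flagged for review. Recalled
#' (zCall-rescued) candidates sit outside the primary clusters by
#' construction and already passed the channel-threshold criterion, so they
#' are exempt from the distance rule but always flagged for review.
#'
#' @param cands a `candidate_set`.
#' @param models the `cluster_models` for the run.
#' @param run the `intensity_run`.
#' @param k spread multiplier for the distance rule.
#' @param intensity_quantile lower intensity quantile treated as dropout.
#' @return The filtered `candidate_set`.
#' @export
cluster_quality_check <- function(cands, models, run, k = 3,
                                  intensity_quantile = 0.05) {
  if (nrow(cands) == 0) {
    return(new_candidates(append_trail(cands, "cluster_quality")))
  }
  pt <- polar_transform(run$x, run$y)
  ij <- cbind(match(cands$sample_id, rownames(run$x)),
              match(cands$probe_id, colnames(run$x)))
  angle <- pt$angle[ij]
  total <- pt$total[ij]
  kk <- match(cands$call, GENOTYPE_LEVELS)
  centers <- models$centers[cbind(kk, ij[, 2])]
  spreads <- models$spread[cbind(kk, ij[, 2])]
  d_rel <- abs(angle - centers) / spreads
  q_lo <- vapply(seq_len(ncol(run$x)), function(j) {
    tot <- pt$total[, j]
    quantile(tot[tot > 0], intensity_quantile, names = FALSE)
  }, numeric(1))
  low_intensity <- total < q_lo[ij[, 2]] * (1 - 1e-9)
  recalled <- cands$caller == "recalled"
  drop <- (!recalled & d_rel > k) | low_intensity
  flag <- (!recalled & d_rel > (k - 1) & d_rel <= k) | recalled
  cands$flagged_for_review <- cands$flagged_for_review | flag
  new_candidates(append_trail(cands[!drop, , drop = FALSE], "cluster_quality"))
}

#' Match candidates against gene inheritance patterns
#'
#' Turns each patient's surviving candidates into a diagnosis status. A
#' patient is diagnosed when some gene's candidates match its inheritance
#' pattern: autosomal dominant needs one variant (het or hom); autosomal
#' recessive needs a homozygote or two distinct heterozygous variants in the
#' gene (assumed in trans, the compound-heterozygote assumption); X-linked
#' needs a hemizygous male or homozygous female call.
#'
#' @param cands a `candidate_set` (post-cascade).
#' @param annotation a `variant_annotation` (for inheritance per probe).
#' @param manifest the `probe_manifest` (for gene per probe).
#' @param sex named per-sample sex vector.
#' @param patients character vector of all patient ids to report on (those
#'   without candidates get `no_diagnosis`).
#' @return data.frame: `sample_id`, `status` (`genetic_diagnosis` /
#'   `no_diagnosis`), `genes` (semicolon list of diagnostic genes, "" if
#'   none).
#' @export
match_inheritance <- function(cands, annotation, manifest, sex, patients) {
  cands$gene <- manifest$gene[match(cands$probe_id, manifest$probe_id)]
  cands$inheritance <-
    annotation$inheritance[match(cands$probe_id, annotation$probe_id)]
  status <- setNames(rep("no_diagnosis", length(patients)), patients)
  genes <- setNames(rep("", length(patients)), patients)
  cc <- cands[cands$sample_id %in% patients & cands$gene != "", , drop = FALSE]
  if (nrow(cc) > 0) {
    by_pg <- split(cc, list(cc$sample_id, cc$gene), drop = TRUE)
    for (grp in by_pg) {
      s <- grp$sample_id[1]
      inh <- grp$inheritance[1]
      hit <- switch(
        inh,
        AD = nrow(grp) >= 1,
        AR = any(grp$zygosity == "hom") ||
          length(unique(grp$probe_id[grp$zygosity == "het"])) >= 2,
        XL = any(grp$zygosity == "hemizygous") ||
          any(grp$zygosity == "hom" & sex[s] == "female"),
        FALSE)
      if (isTRUE(hit)) {
        status[s] <- "genetic_diagnosis"
        genes[s] <- if (genes[s] == "") grp$gene[1] else
          paste(genes[s], grp$gene[1], sep = ";")
      }
    }
  }
  data.frame(sample_id = patients, status = unname(status[patients]),
             genes = unname(genes[patients]))
}

#' Run the full SNV screening cascade
#'
#' Applies, in order: disease-causing selection, population-frequency
#' filter, cohort-recurrence filter, male X-heterozygote filter and the
#' cluster-quality check, then matches inheritance patterns to produce
#' per-patient diagnosis statuses.
#'
#' @param qc result of [apply_qc()] (uses `$genotypes`).
#' @param annotation a `variant_annotation`.
#' @param manifest the `probe_manifest`.
#' @param models,run the run's `cluster_models` and `intensity_run` (for the
#'   cluster-quality check).
#' @param patients character vector of patient sample ids (controls are
#'   never diagnosed but do count for recurrence).
#' @param freq_cutoff,k,intensity_quantile tuning parameters of the
#'   individual filters.
#' @return list: `candidates` (post-cascade `candidate_set`), `diagnoses`
#'   (per-patient data.frame), `attrition` (named counts surviving each
#'   filter), `sex`.
#' @export
screen_snv <- function(qc, annotation, manifest, models, run, patients,
                       freq_cutoff = 0.005, k = 3,
                       intensity_quantile = 0.05) {
  calls <- qc$genotypes
  sex <- qc$report$sex
  c0 <- select_disease_causing(calls, annotation)
  c1 <- frequency_filter(c0, annotation, freq_cutoff)
  c2 <- recurrence_filter(c1, calls)
  c3 <- male_x_het_filter(c2, sex, manifest)
  c4 <- cluster_quality_check(c3, models, run, k, intensity_quantile)
  diagnoses <- match_inheritance(c4, annotation, manifest, sex, patients)
  attrition <- c(nonref_calls = attr(c0, "n_nonref"),
                 disease_causing = nrow(c0), frequency = nrow(c1),
                 singleton = nrow(c2), male_x_het = nrow(c3),
                 cluster_quality = nrow(c4))
  list(candidates = c4, diagnoses = diagnoses, attrition = attrition,
       sex = sex)
}

#' Write cascade attrition counts as JSON
#'
#' @param screen result of [screen_snv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(screen, path) {
  jsonlite::write_json(as.list(screen$attrition), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
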