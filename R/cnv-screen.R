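# CNV screening: log-R-ratio / B-allele-frequency computation, change-point
# segmentation, event classification, whole-chromosome aneuploidy, LCSH
# detection, and the CNV filter cascade (PID-gene overlap, benign-track
# overlap for heterozygous events, cohort recurrence).

CNV_EVENTS <- c("single_loss", "double_loss", "single_gain", "double_gain")

#' CNV calling parameters
#'
#' @param significance_p per-segment acceptance p-value for calling an
#'   event.
#' @param min_probes minimum probes per called segment.
#' @param max_probe_spacing_bp adjacent probes farther apart than this can
#'   never share a segment.
#' @param log2_single_loss,log2_double_loss,log2_single_gain,log2_double_gain
#'   mean-log2 thresholds for the four event classes; the double thresholds
#'   must be more extreme than the single ones.
#' @param het_known_overlap maximum tolerated overlap fraction between a
#'   heterozygous (single-copy) event and the benign-CNV track (0 = any
#'   overlap excludes).
#' @param min_lcsh_bp,min_lcsh_probes minimum span and probe count for an
#'   LCSH call.
#' @param lcsh_error_rate tolerated heterozygous probes per LCSH run probe
#'   (1/50 = one error probe per 50).
#' @param lcsh_lrr_tolerance LCSH requires |mean LRR| below this (normal
#'   copy number distinguishes LCSH from deletion).
#' @param aneuploidy_tolerance fraction of the ideal whole-chromosome LRR
#'   shift (log2(3/2) for trisomy, log2(1/2) for monosomy) that the
#'   chromosome median must reach.
#' @param reciprocal_overlap fraction defining "the same CNV" across samples
#'   for the recurrence filter.
#' @param consanguinity_min_bp per-sample total LCSH span above which the
#'   sample is flagged as consanguineous.
#' @return A `cnv_params` list.
#' @export
cnv_params <- function(significance_p = 5e-6, min_probes = 4,
                       max_probe_spacing_bp = 1e6,
                       log2_single_loss = -0.3, log2_double_loss = -1.1,
                       log2_single_gain = 0.2, log2_double_gain = 0.7,
                       het_known_overlap = 0,
                       min_lcsh_bp = 5e6, min_lcsh_probes = 50,
                       lcsh_error_rate = 1 / 50, lcsh_lrr_tolerance = 0.15,
                       aneuploidy_tolerance = 0.5,
                       reciprocal_overlap = 0.5,
                       consanguinity_min_bp = 50e6) {
  if (min_probes < 2) stop("min_probes must be at least 2", call. = FALSE)
  if (log2_double_loss >= log2_single_loss ||
      log2_double_gain <= log2_single_gain) {
    stop("double-copy thresholds must be more extreme than single-copy ones",
         call. = FALSE)
  }
  structure(list(significance_p = significance_p, min_probes = min_probes,
                 max_probe_spacing_bp = max_probe_spacing_bp,
                 log2_single_loss = log2_single_loss,
                 log2_double_loss = log2_double_loss,
                 log2_single_gain = log2_single_gain,
                 log2_double_gain = log2_double_gain,
                 het_known_overlap = het_known_overlap,
                 min_lcsh_bp = min_lcsh_bp,
                 min_lcsh_probes = min_lcsh_probes,
                 lcsh_error_rate = lcsh_error_rate,
                 lcsh_lrr_tolerance = lcsh_lrr_tolerance,
                 aneuploidy_tolerance = aneuploidy_tolerance,
                 reciprocal_overlap = reciprocal_overlap,
                 consanguinity_min_bp = consanguinity_min_bp),
            class = "cnv_params")
}

# Piecewise-linear BAF from the angle through the fitted cluster centers:
# AA center -> 0, AB center -> 0.5, BB center -> 1.
interpolate_baf <- function(angle, centers) {
  baf <- numeric(length(angle))
  lo <- angle <= centers[1]
  hi <- angle >= centers[3]
  mid_l <- !lo & angle <= centers[2]
  mid_r <- !hi & angle > centers[2]
  baf[lo] <- 0
  baf[hi] <- 1
  baf[mid_l] <- 0.5 * (angle[mid_l] - centers[1]) / (centers[2] - centers[1])
  baf[mid_r] <- 0.5 + 0.5 * (angle[mid_r] - centers[2]) /
    (centers[3] - centers[2])
  baf[is.na(angle)] <- NA_real_
  baf
}

#' Compute the log-R-ratio / B-allele-frequency track
#'
#' LRR is `log2(total / expected)` with the diploid expectation taken as the
#' cohort median total intensity at the probe, so a copy-number-`c` region
#' sits near `log2(c/2)`. BAF interpolates the angle piecewise-linearly
#' between the fitted AA, AB and BB cluster centers (anchored at 0, 0.5, 1)
#' and is defined only at polymorphic probes (at least two occupied
#' clusters). Unmeasured points are missing, not zero.
#'
#' @param run an `intensity_run`.
#' @param models the run's `cluster_models`.
#' @param manifest the `probe_manifest` (provides probe order and
#'   coordinates; probes absent from the run are skipped).
#' @param sex optional named per-sample sex vector (see [infer_sex()]). The
#'   X-chromosome expectation is taken from females only and male X LRR is
#'   recentred by +1 (one X copy is their normal baseline); without sex
#'   information the X LRR is left unmeasured, since a mixed-sex cohort
#'   median is not a diploid expectation there.
#' @return A `baf_lrr_track`: `lrr` and `baf` matrices (samples x probes in
#'   manifest order), plus `chromosome` and `position` vectors.
#' @export
compute_lrr_baf <- function(run, models, manifest, sex = NULL) {
  probes <- manifest$probe_id[manifest$probe_id %in% run$probe_ids]
  pt <- polar_transform(run$x[, probes, drop = FALSE],
                        run$y[, probes, drop = FALSE])
  total <- pt$total
  total[total == 0] <- NA_real_
  expected <- apply(total, 2, median, na.rm = TRUE)
  on_x <- manifest$chromosome[match(probes, manifest$probe_id)] == "X"
  males <- character(0)
  if (any(on_x)) {
    if (is.null(sex)) {
      total[, on_x] <- NA_real_
    } else {
      females <- intersect(rownames(total), names(sex)[sex == "female"])
      males <- intersect(rownames(total), names(sex)[sex == "male"])
      total[setdiff(rownames(total), c(females, males)), on_x] <- NA_real_
      if (length(females) >= 3) {
        expected[on_x] <- apply(total[females, on_x, drop = FALSE], 2,
                                median, na.rm = TRUE)
      } else {
        total[, on_x] <- NA_real_
      }
    }
  }
  lrr <- log2(sweep(total, 2, expected, "/"))
  if (any(on_x) && length(males) > 0) {
    lrr[males, on_x] <- lrr[males, on_x] + 1
  }
  baf <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  for (j in seq_along(probes)) {
    p <- probes[j]
    if (!models$callable[p]) next
    if (sum(models$n[, p] > 0) < 2) next   # monomorphic: BAF undefined
    baf[, j] <- interpolate_baf(pt$angle[, j], models$centers[, p])
  }
  m_idx <- match(probes, manifest$probe_id)
  structure(list(lrr = lrr, baf = baf,
                 chromosome = manifest$chromosome[m_idx],
                 position = manifest$position[m_idx],
                 probe_ids = probes),
            class = "baf_lrr_track")
}

# Recursive CUSUM-style binary segmentation of one series; returns sorted
# breakpoints (index of last element of each left part).
binseg <- function(x, s, z_crit, lo = 1, hi = length(x)) {
  n <- hi - lo + 1
  if (n < 2) return(integer(0))
  xs <- x[lo:hi]
  cs <- cumsum(xs)
  k <- seq_len(n - 1)
  mean_l <- cs[k] / k
  mean_r <- (cs[n] - cs[k]) / (n - k)
  stat <- abs(mean_l - mean_r) / (s * sqrt(1 / k + 1 / (n - k)))
  k_best <- which.max(stat)
  if (!is.finite(stat[k_best]) || stat[k_best] < z_crit) return(integer(0))
  cut <- lo + k_best - 1
  c(binseg(x, s, z_crit, lo, cut), cut, binseg(x, s, z_crit, cut + 1, hi))
}

# Robust per-sample noise estimate: scaled MAD of successive LRR
# differences (insensitive to step changes at true events).
sample_lrr_noise <- function(lrr_vec) {
  d <- diff(lrr_vec[!is.na(lrr_vec)])
  max(mad(d) / sqrt(2), 1e-3)
}

classify_event <- function(mean_log2, params) {
  if (mean_log2 <= params$log2_double_loss) return("double_loss")
  if (mean_log2 <= params$log2_single_loss) return("single_loss")
  if (mean_log2 >= params$log2_double_gain) return("double_gain")
  if (mean_log2 >= params$log2_single_gain) return("single_gain")
  NA_character_
}

#' Segment the LRR track and call copy-number events
#'
#' Per sample and chromosome, probes with measured LRR are split into
#' blocks wherever adjacent probes are farther apart than
#' `max_probe_spacing_bp`, each block is segmented by binary change-point
#' search, and a segment becomes a called event when it has at least
#' `min_probes` probes, its mean log2 ratio crosses a class threshold, and
#' the two-sided Gaussian p-value of its mean against the sample's robust
#' noise null is below `significance_p`. The event class comes from the
#' most extreme threshold crossed. Chromosome Y is never segmented.
#'
#' @param track a `baf_lrr_track`.
#' @param params a [cnv_params()].
#' @return A `cnv_segments` data.frame: `sample_id`, `chromosome`, `start`,
#'   `end` (0-based half-open, probe-spanned), `n_probes`, `mean_log2`,
#'   `event`, `p_value`.
#' @export
segment_lrr <- function(track, params = cnv_params()) {
  out <- list()
  z_crit <- qnorm(1 - params$significance_p / 2)
  samples <- rownames(track$lrr)
  for (s in samples) {
    lrr_s <- track$lrr[s, ]
    noise <- sample_lrr_noise(lrr_s)
    for (chrom in setdiff(unique(track$chromosome), "Y")) {
      on_c <- which(track$chromosome == chrom & !is.na(lrr_s))
      if (length(on_c) < params$min_probes) next
      pos <- track$position[on_c]
      x <- lrr_s[on_c]
      # hard block boundaries at large probe gaps
      gap_break <- which(diff(pos) > params$max_probe_spacing_bp)
      block_start <- c(1, gap_break + 1)
      block_end <- c(gap_break, length(x))
      for (b in seq_along(block_start)) {
        idx <- block_start[b]:block_end[b]
        cuts <- binseg(x[idx], noise, z_crit)
        bounds <- c(0, cuts, length(idx))
        for (seg in seq_len(length(bounds) - 1)) {
          sel <- idx[(bounds[seg] + 1):bounds[seg + 1]]
          n <- length(sel)
          if (n < params$min_probes) next
          m <- mean(x[sel])
          ev <- classify_event(m, params)
          if (is.na(ev)) next
          p_val <- 2 * pnorm(-abs(m) * sqrt(n) / noise)
          if (p_val >= params$significance_p) next
          out[[length(out) + 1]] <- data.frame(
            sample_id = s, chromosome = chrom,
            start = pos[sel[1]], end = pos[sel[n]] + 1,
            n_probes = n, mean_log2 = m, event = ev, p_value = p_val)
        }
      }
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(sample_id = character(0), chromosome = character(0),
               start = numeric(0), end = numeric(0), n_probes = integer(0),
               mean_log2 = numeric(0), event = character(0),
               p_value = numeric(0))
  class(res) <- c("cnv_segments", "data.frame")
  res
}

#' Detect whole-chromosome aneuploidy
#'
#' A chromosome is trisomic when its median LRR reaches
#' `aneuploidy_tolerance * log2(3/2)` and the heterozygote BAF band is split
#' towards the 1/3 and 2/3 allelic fractions; monosomic when the median LRR
#' reaches `aneuploidy_tolerance * log2(1/2)` and the heterozygote band is
#' absent. When the LRR shift and the BAF pattern disagree the event is
#' still emitted, flagged `discordant`. Only autosomes are assessed (the X
#' LRR is sex-confounded and Y is excluded throughout).
#'
#' @param track a `baf_lrr_track`.
#' @param params a [cnv_params()].
#' @return data.frame: `sample_id`, `chromosome`, `event` (`trisomy` /
#'   `monosomy`), `median_lrr`, `het_fraction`, `split_fraction`,
#'   `discordant`.
#' @export
detect_aneuploidy <- function(track, params = cnv_params()) {
  out <- list()
  tri_cut <- params$aneuploidy_tolerance * log2(3 / 2)
  mono_cut <- params$aneuploidy_tolerance * log2(1 / 2)
  autosomes <- intersect(unique(track$chromosome), as.character(1:22))
  for (s in rownames(track$lrr)) {
    for (chrom in autosomes) {
      on_c <- track$chromosome == chrom
      lrr <- track$lrr[s, on_c]
      baf <- track$baf[s, on_c]
      med <- median(lrr, na.rm = TRUE)
      if (is.na(med)) next
      informative <- baf[!is.na(baf)]
      # off-homozygote points: the heterozygote band region
      band <- informative[informative > 0.1 & informative < 0.9]
      het_fraction <- length(band) / max(length(informative), 1)
      near_half <- sum(abs(band - 0.5) < 0.1)
      near_thirds <- sum(abs(band - 1 / 3) < 0.1 | abs(band - 2 / 3) < 0.1)
      split_fraction <- if (length(band) > 0) near_thirds / length(band) else 0
      ev <- NA_character_
      discordant <- FALSE
      if (med >= tri_cut) {
        ev <- "trisomy"
        discordant <- !(length(band) >= 5 && near_thirds > near_half)
      } else if (med <= mono_cut) {
        ev <- "monosomy"
        discordant <- het_fraction > 0.05
      }
      if (!is.na(ev)) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = s, chromosome = chrom, event = ev, median_lrr = med,
          het_fraction = het_fraction, split_fraction = split_fraction,
          discordant = discordant)
      }
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(sample_id = character(0), chromosome = character(0),
               event = character(0), median_lrr = numeric(0),
               het_fraction = numeric(0), split_fraction = numeric(0),
               discordant = logical(0))
}

#' Detect long contiguous stretches of homozygosity (LCSH)
#'
#' Per sample and chromosome, maximal runs of informative probes with
#' homozygous BAF (`|baf - 0.5| > 0.4`), tolerating `lcsh_error_rate`
#' heterozygous probes per run probe (at least one), become LCSH segments
#' when they span at least `min_lcsh_bp`, contain at least
#' `min_lcsh_probes` probes, and have normal copy number
#' (`|mean LRR| < lcsh_lrr_tolerance`), which distinguishes LCSH from
#' deletions. The per-sample total LCSH span is reported as a consanguinity
#' indicator.
#'
#' @param track a `baf_lrr_track`.
#' @param params a [cnv_params()].
#' @return list: `segments` (`cnv_segments`-shaped data.frame with event
#'   `lcsh`) and `burden` (per-sample data.frame: total LCSH bp and a
#'   consanguinity flag at `consanguinity_min_bp`).
#' @export
detect_lcsh <- function(track, params = cnv_params()) {
  out <- list()
  samples <- rownames(track$lrr)
  for (s in samples) {
    for (chrom in setdiff(unique(track$chromosome), c("X", "Y"))) {
      on_c <- which(track$chromosome == chrom & !is.na(track$baf[s, ]))
      if (length(on_c) < params$min_lcsh_probes) next
      hom <- abs(track$baf[s, on_c] - 0.5) > 0.4
      runs <- lcsh_runs(hom, params$lcsh_error_rate)
      for (r in runs) {
        sel <- on_c[r[1]:r[2]]
        n <- length(sel)
        span_start <- track$position[sel[1]]
        span_end <- track$position[sel[n]] + 1
        if (n < params$min_lcsh_probes) next
        if (span_end - span_start < params$min_lcsh_bp) next
        m <- mean(track$lrr[s, sel], na.rm = TRUE)
        if (!is.finite(m) || abs(m) >= params$lcsh_lrr_tolerance) next
        out[[length(out) + 1]] <- data.frame(
          sample_id = s, chromosome = chrom, start = span_start,
          end = span_end, n_probes = n, mean_log2 = m, event = "lcsh",
          p_value = NA_real_)
      }
    }
  }
  segments <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(sample_id = character(0), chromosome = character(0),
               start = numeric(0), end = numeric(0), n_probes = integer(0),
               mean_log2 = numeric(0), event = character(0),
               p_value = numeric(0))
  class(segments) <- c("cnv_segments", "data.frame")
  burden_bp <- vapply(samples, function(s) {
    sum(segments$end[segments$sample_id == s] -
          segments$start[segments$sample_id == s])
  }, numeric(1))
  burden <- data.frame(sample_id = samples, lcsh_bp = unname(burden_bp),
                       consanguinity_flag =
                         unname(burden_bp >= params$consanguinity_min_bp))
  list(segments = segments, burden = burden)
}

# Maximal homozygous runs in a logical vector, tolerating error probes at
# the given per-probe rate (minimum one); runs are trimmed to homozygous
# endpoints. Returns list of c(start, end) index pairs.
lcsh_runs <- function(hom, error_rate) {
  runs <- list()
  n <- length(hom)
  i <- 1
  while (i <= n) {
    if (!hom[i]) { i <- i + 1; next }
    start <- i
    errors <- 0
    last_hom <- i
    j <- i + 1
    while (j <= n) {
      if (hom[j]) {
        last_hom <- j
      } else {
        # one tolerated error plus one per 1/error_rate probes of run length
        allowed <- 1 + floor((j - start + 1) * error_rate)
        if (errors + 1 > allowed) break
        errors <- errors + 1
      }
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- c(start, last_hom)
    i <- last_hom + 1
  }
  runs
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(inter / (e1 - s1), inter / (e2 - s2))
}

#' Filter copy-number events
#'
#' The CNV screening filters, applied to called copy-number segments (LCSH
#' and aneuploidy findings are handled separately): keep events overlapping
#' a PID gene (any custom-probe gene footprint in the manifest); drop
#' heterozygous (single-copy) events with more than `het_known_overlap`
#' overlap fraction against the benign-CNV track (0 means any overlap
#' excludes) while homozygous/double events are exempt; drop events whose
#' reciprocal-overlap match (>= `reciprocal_overlap`, same direction)
#' occurs in two or more samples.
#'
#' @param segments a `cnv_segments` data.frame from [segment_lrr()].
#' @param manifest the `probe_manifest`.
#' @param benign a `benign_cnv_track` (or NULL to skip that filter).
#' @param params a [cnv_params()].
#' @return The filtered `cnv_segments`, with a `filter_trail` column.
#' @export
filter_cnvs <- function(segments, manifest, benign = NULL,
                        params = cnv_params()) {
  seg <- segments[segments$event %in% CNV_EVENTS, , drop = FALSE]
  finish <- function(seg) {
    rownames(seg) <- NULL
    class(seg) <- c("cnv_segments", "data.frame")
    seg
  }
  if (nrow(seg) == 0) {
    seg$filter_trail <- character(0)
    return(finish(seg))
  }

  # PID-gene footprint overlap
  cust <- manifest[manifest$gene != "", , drop = FALSE]
  genes <- unique(cust$gene)
  gene_span <- do.call(rbind, lapply(genes, function(g) {
    gg <- cust[cust$gene == g, ]
    data.frame(gene = g, chromosome = gg$chromosome[1],
               start = min(gg$position), end = max(gg$position) + 1)
  }))
  in_gene <- vapply(seq_len(nrow(seg)), function(i) {
    any(gene_span$chromosome == seg$chromosome[i] &
          gene_span$start < seg$end[i] & gene_span$end > seg$start[i])
  }, logical(1))
  seg <- seg[in_gene, , drop = FALSE]
  seg$filter_trail <- rep("pid_gene", nrow(seg))
  if (nrow(seg) == 0) return(finish(seg))

  # benign-track overlap: heterozygous (single-copy) events only
  if (!is.null(benign) && nrow(benign) > 0) {
    het_ev <- seg$event %in% c("single_loss", "single_gain")
    overlap_frac <- vapply(seq_len(nrow(seg)), function(i) {
      b <- benign[benign$chromosome == seg$chromosome[i], , drop = FALSE]
      if (nrow(b) == 0) return(0)
      inter <- pmax(0, pmin(b$end, seg$end[i]) - pmax(b$start, seg$start[i]))
      sum(inter) / (seg$end[i] - seg$start[i])
    }, numeric(1))
    drop <- het_ev & overlap_frac > params$het_known_overlap
    seg <- seg[!drop, , drop = FALSE]
    if (nrow(seg) == 0) return(finish(seg))
    seg$filter_trail <- paste(seg$filter_trail, "benign_overlap", sep = ";")
  }

  # cohort recurrence by reciprocal overlap, same direction
  direction <- ifelse(grepl("loss", seg$event), "loss", "gain")
  n_matching_samples <- vapply(seq_len(nrow(seg)), function(i) {
    same <- seg$chromosome == seg$chromosome[i] & direction == direction[i]
    ro <- reciprocal_overlap(seg$start[i], seg$end[i],
                             seg$start[same], seg$end[same])
    length(unique(seg$sample_id[same][ro >= params$reciprocal_overlap]))
  }, integer(1))
  seg <- seg[n_matching_samples < 2, , drop = FALSE]
  if (nrow(seg) > 0) {
    seg$filter_trail <- paste(seg$filter_trail, "singleton", sep = ";")
  }
  finish(seg)
}

#' Run the full CNV screening stage
#'
#' Computes the LRR/BAF track, segments it, detects whole-chromosome
#' aneuploidy and LCSH, and applies the CNV filters.
#'
#' @param run an `intensity_run` (restrict to post-QC samples upstream).
#' @param models the run's `cluster_models`.
#' @param manifest the `probe_manifest`.
#' @param benign optional `benign_cnv_track`.
#' @param params a [cnv_params()].
#' @param sex optional named per-sample sex vector, enabling X-chromosome
#'   LRR (see [compute_lrr_baf()]).
#' @return list: `track`, `segments` (all called events), `filtered`
#'   (post-filter events), `aneuploidy`, `lcsh` (segments + burden).
#' @export
screen_cnv <- function(run, models, manifest, benign = NULL,
                       params = cnv_params(), sex = NULL) {
  track <- compute_lrr_baf(run, models, manifest, sex = sex)
  segments <- segment_lrr(track, params)
  aneuploidy <- detect_aneuploidy(track, params)
  lcsh <- detect_lcsh(track, params)
  filtered <- filter_cnvs(segments, manifest, benign, params)
  list(track = track, segments = segments, filtered = filtered,
       aneuploidy = aneuploidy, lcsh = lcsh)
}
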