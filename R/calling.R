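# Genotype calling from two-channel intensities.
#
# Primary calling emulates cluster-based array callers: per probe, a
# three-component 1-D Gaussian mixture is fitted on the normalized angle
# axis (EM, canonical initialization, ordering constraint), and each sample
# is assigned to its nearest cluster with a confidence score that falls off
# towards the decision boundary. A zCall-style recalling stage then rescues
# rare-variant no-calls using channel thresholds derived from the
# homozygote cluster statistics.

#' Polar transform of two-channel intensities
#'
#' Maps raw channel signals to the normalized angle
#' `(2/pi) * atan2(y, x)` in \[0,1\] (0 = pure A signal, 1 = pure B) and the
#' total intensity `x + y`. Points with no signal on either channel are
#' unmeasured: angle `NA`.
#'
#' @param x,y non-negative channel intensities (A and B channel), vectors or
#'   matrices of equal shape.
#' @return list with `angle` and `total`, same shape as the input.
#' @export
polar_transform <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  total <- x + y
  angle <- (2 / pi) * atan2(y, x)
  angle[total == 0] <- NA_real_
  list(angle = angle, total = total)
}

DEFAULT_CENTERS <- c(0.05, 0.5, 0.95)
DEFAULT_SPREAD <- 0.05
MIN_SPREAD <- 0.005

# Fit the three-cluster angle model for one probe.
# Returns centers, spreads, occupancy counts and imputed flags, ordered
# AA < AB < BB on the angle axis. A component only moves off its canonical
# anchor once it has enough effective members (population callers form
# clusters from multiple carriers; one or two rare points must not drag a
# cluster onto themselves, which is exactly the regime the recalling stage
# exists for).
fit_cluster_probe <- function(angle, centers_init = DEFAULT_CENTERS,
                              n_iter = 20, min_members = 3) {
  a <- angle[!is.na(angle)]
  mu <- centers_init
  sigma <- rep(DEFAULT_SPREAD, 3)
  w <- rep(1 / 3, 3)
  n <- length(a)
  for (it in seq_len(n_iter)) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(a, mu[k], sigma[k]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs == 0] <- 1
    resp <- dens / rs
    nk <- colSums(resp)
    for (k in 1:3) {
      if (nk[k] >= min_members) {
        mu[k] <- sum(resp[, k] * a) / nk[k]
        sigma[k] <- sqrt(sum(resp[, k] * (a - mu[k])^2) / nk[k])
      } else {
        mu[k] <- centers_init[k]
        sigma[k] <- DEFAULT_SPREAD
      }
    }
    sigma <- pmax(sigma, MIN_SPREAD)
    w <- pmax(nk / n, 1e-8)
    w <- w / sum(w)
    # ordering constraint AA < AB < BB: re-sort, tie-break by canonical order
    ord <- order(mu)
    mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]
  }
  # hard occupancy; thin clusters stay at (or return to) canonical anchors
  assign_k <- max.col(-abs(outer(a, mu, "-")), ties.method = "first")
  occ <- tabulate(assign_k, 3)
  imputed <- occ < min_members
  mu[imputed] <- centers_init[imputed]
  sigma[imputed] <- DEFAULT_SPREAD
  ord <- order(mu)
  list(centers = mu[ord], spread = sigma[ord], n = occ[ord],
       imputed = imputed[ord])
}

#' Fit per-probe cluster models for an intensity run
#'
#' For each probe with at least `min_samples` measurable points, fits the
#' three-cluster angle model; clusters with no carriers (e.g. no BB
#' homozygotes at a rare variant) are imputed at the canonical centers with
#' the default spread. Per-cluster channel statistics needed by the
#' recalling stage are recorded alongside.
#'
#' @param run an `intensity_run`.
#' @param centers_init canonical initialization centers on the angle axis.
#' @param min_samples minimum measurable samples for a probe to be callable.
#' @return A `cluster_models` object: matrices (3 x probes) of `centers`,
#'   `spread`, `n`, `imputed`; per-probe callability; per-probe homozygote
#'   channel statistics.
#' @export
fit_clusters <- function(run, centers_init = DEFAULT_CENTERS,
                         min_samples = 10) {
  pt <- polar_transform(run$x, run$y)
  probes <- run$probe_ids
  P <- length(probes)
  centers <- spread <- nmat <- matrix(NA_real_, 3, P,
                                      dimnames = list(GENOTYPE_LEVELS, probes))
  imputed <- matrix(NA, 3, P, dimnames = list(GENOTYPE_LEVELS, probes))
  callable <- setNames(rep(FALSE, P), probes)
  hom_stats <- matrix(NA_real_, 4, P,
                      dimnames = list(c("aa_y_mean", "aa_y_sd",
                                        "bb_x_mean", "bb_x_sd"), probes))
  for (j in seq_len(P)) {
    aj <- pt$angle[, j]
    ok <- !is.na(aj)
    if (sum(ok) < min_samples) next
    fit <- fit_cluster_probe(aj, centers_init)
    centers[, j] <- fit$centers
    spread[, j] <- fit$spread
    nmat[, j] <- fit$n
    imputed[, j] <- fit$imputed
    callable[j] <- TRUE
    # channel noise statistics of the homozygote clusters (for recalling):
    # y-noise among AA carriers, x-noise among BB carriers
    k <- assign_nearest(aj[ok], fit$centers)
    xs <- run$x[ok, j]; ys <- run$y[ok, j]
    if (fit$n[1] > 1) {
      hom_stats["aa_y_mean", j] <- mean(ys[k == 1])
      hom_stats["aa_y_sd", j] <- sd(ys[k == 1])
    }
    if (fit$n[3] > 1) {
      hom_stats["bb_x_mean", j] <- mean(xs[k == 3])
      hom_stats["bb_x_sd", j] <- sd(xs[k == 3])
    }
  }
  structure(list(centers = centers, spread = spread, n = nmat,
                 imputed = imputed, callable = callable,
                 hom_stats = hom_stats, probe_ids = probes),
            class = "cluster_models")
}

assign_nearest <- function(angle, centers) {
  max.col(-abs(outer(angle, centers, "-")), ties.method = "first")
}

# Confidence score for points assigned to cluster k: 1 at the cluster
# center, 0 at the midpoint boundary with the adjacent cluster.
boundary_score <- function(angle, k, centers) {
  c_k <- centers[k]
  d <- abs(angle - c_k)
  # boundary on the side the point lies on; edge clusters use the inner
  # boundary for points falling outside the cluster frame
  left <- angle < c_k
  adj <- ifelse(k == 1, 2, ifelse(k == 3, 2, ifelse(left, 1, 3)))
  b <- abs(centers[adj] - c_k) / 2
  pmax(0, 1 - d / b)
}

#' Primary genotype calling against a cluster model
#'
#' Assigns each point to the nearest cluster on the angle axis. The score is
#' 1 at the cluster center and falls linearly to 0 at the decision boundary
#' (midpoint between adjacent cluster centers); calls scoring below
#' `nocall_threshold` are no-calls, as are unmeasured points.
#'
#' @param centers length-3 cluster centers (AA, AB, BB) for one probe.
#' @param angle numeric vector of normalized angles (NA = unmeasured).
#' @param nocall_threshold minimum score for a call.
#' @return list with `call` (character) and `score` (numeric, NA at
#'   no-calls).
#' @export
primary_call <- function(centers, angle, nocall_threshold = 0.15) {
  call <- rep(NOCALL, length(angle))
  score <- rep(NA_real_, length(angle))
  ok <- !is.na(angle)
  if (any(ok)) {
    k <- assign_nearest(angle[ok], centers)
    s <- boundary_score(angle[ok], k, centers)
    cl <- GENOTYPE_LEVELS[k]
    cl[s < nocall_threshold] <- NOCALL
    s[s < nocall_threshold] <- NA_real_
    call[ok] <- cl
    score[ok] <- s
  }
  list(call = call, score = score)
}

#' zCall-style rare-variant recalling
#'
#' For probes in the rare regime (all clusters but the major one together
#' hold fewer than `rare_occupancy` samples), no-calls are revisited with
#' channel thresholds derived from homozygote cluster statistics: a point is
#' real on a channel when its signal exceeds the opposite homozygote
#' cluster's mean on that channel plus `z` spreads. Beyond both thresholds
#' the point is recalled heterozygous; beyond exactly one, the matching
#' homozygote. When a homozygote cluster is absent its channel statistics
#' are mirrored from the other homozygote cluster (symmetric chemistry);
#' degenerate (zero) spreads are floored at 1% of the channel mean.
#' Recalled entries are marked `caller = "recalled"`; confident primary
#' calls are never touched.
#'
#' @param calls a `genotype_matrix` from primary calling.
#' @param models the `cluster_models` for the run.
#' @param run the `intensity_run`.
#' @param z spread multiplier for the channel thresholds.
#' @param rare_occupancy a probe is rare when its non-major clusters hold
#'   fewer than this many samples.
#' @param recalled_score score recorded for recalled entries (they carry
#'   reduced confidence by construction).
#' @return The updated `genotype_matrix`.
#' @export
zcall_recall <- function(calls, models, run, z = 7, rare_occupancy = 5,
                         recalled_score = 0.5) {
  out_calls <- calls$calls
  out_score <- calls$score
  out_caller <- calls$caller
  for (j in seq_along(models$probe_ids)) {
    p <- models$probe_ids[j]
    if (!models$callable[p]) next
    occ <- models$n[, p]
    if (sum(occ) - max(occ) >= rare_occupancy) next
    nc <- which(out_calls[, p] == NOCALL & (run$x[, p] + run$y[, p]) > 0)
    if (length(nc) == 0) next
    hs <- models$hom_stats[, p]
    aa_y <- c(hs[["aa_y_mean"]], hs[["aa_y_sd"]])
    bb_x <- c(hs[["bb_x_mean"]], hs[["bb_x_sd"]])
    if (any(is.na(aa_y)) && !any(is.na(bb_x))) aa_y <- bb_x  # mirror
    if (any(is.na(bb_x)) && !any(is.na(aa_y))) bb_x <- aa_y
    if (any(is.na(aa_y)) || any(is.na(bb_x))) next
    floor_y <- 0.01 * aa_y[1] + 1e-9
    floor_x <- 0.01 * bb_x[1] + 1e-9
    ty <- aa_y[1] + z * max(aa_y[2], floor_y)
    tx <- bb_x[1] + z * max(bb_x[2], floor_x)
    xs <- run$x[nc, p]; ys <- run$y[nc, p]
    new_call <- ifelse(xs > tx & ys > ty, "AB",
                       ifelse(xs > tx, "AA",
                              ifelse(ys > ty, "BB", NOCALL)))
    hit <- new_call != NOCALL
    if (any(hit)) {
      out_calls[nc[hit], p] <- new_call[hit]
      out_score[nc[hit], p] <- recalled_score
      out_caller[nc[hit], p] <- "recalled"
    }
  }
  genotype_matrix(out_calls, out_score, out_caller)
}

#' Call genotypes for an intensity run
#'
#' The full calling stage: polar transform, per-probe cluster fitting,
#' primary calling, and (optionally) zCall-style recalling of rare-variant
#' no-calls.
#'
#' @param run an `intensity_run`.
#' @param nocall_threshold primary-call score cutoff.
#' @param zcall apply the recalling stage.
#' @param z,rare_occupancy recalling parameters, see [zcall_recall()].
#' @param centers_init canonical cluster initialization.
#' @return list with `primary` (genotype_matrix before recalling),
#'   `recalled` (after recalling; identical to `primary` when
#'   `zcall = FALSE`), and `models` (the fitted `cluster_models`).
#' @export
call_genotypes <- function(run, nocall_threshold = 0.15, zcall = TRUE,
                           z = 7, rare_occupancy = 5,
                           centers_init = DEFAULT_CENTERS) {
  models <- fit_clusters(run, centers_init)
  pt <- polar_transform(run$x, run$y)
  calls <- matrix(NOCALL, nrow(run$x), ncol(run$x), dimnames = dimnames(run$x))
  score <- matrix(NA_real_, nrow(run$x), ncol(run$x),
                  dimnames = dimnames(run$x))
  for (j in seq_along(run$probe_ids)) {
    p <- run$probe_ids[j]
    if (!models$callable[p]) next
    pc <- primary_call(models$centers[, p], pt$angle[, j], nocall_threshold)
    calls[, j] <- pc$call
    score[, j] <- pc$score
  }
  primary <- genotype_matrix(calls, score)
  recalled <- if (zcall) {
    zcall_recall(primary, models, run, z = z, rare_occupancy = rare_occupancy)
  } else {
    primary
  }
  list(primary = primary, recalled = recalled, models = models)
}
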