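# Probe manifest, variant annotation, truth genotypes and benign-CNV track:
# the domain tables every downstream stage consumes.
#
# Coordinate convention: all positions held in memory are 0-based half-open.
# The single conversion to 1-based coordinates happens in write_vcf(); SEG and
# BED output stay 0-based half-open.

PROBE_CLASSES <- c("custom_pid_snv", "custom_pid_indel", "backbone")

#' Construct and validate a probe manifest
#'
#' A probe manifest describes the array content: genome-wide "backbone" SNPs
#' used for QC, CNV and LCSH detection, plus custom probes targeting known
#' PID disease variants (SNVs and INDELs). The manifest is sorted by
#' (chromosome, position) on construction.
#'
#' @param df data.frame with columns `probe_id`, `chromosome` (1-22, X, Y),
#'   `position` (0-based), `ref_allele`, `alt_allele` (nucleotide, or the
#'   tokens "I"/"D" for INDEL probes), `gene` (symbol or ""), and
#'   `probe_class` (one of `custom_pid_snv`, `custom_pid_indel`, `backbone`).
#' @return A `probe_manifest`: the validated, sorted data.frame.
#' @seealso [read_manifest()], [manifest_class_counts()]
#' @export
probe_manifest <- function(df) {
  stopifnot_cols(df, c("probe_id", "chromosome", "position", "ref_allele",
                       "alt_allele", "gene", "probe_class"), "probe manifest")
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- as.character(df$chromosome)
  df$gene <- ifelse(is.na(df$gene), "", as.character(df$gene))
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicated probe_id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  bad_chrom <- unique(df$chromosome[!is_valid_chrom(df$chromosome)])
  if (length(bad_chrom) > 0) {
    stop(sprintf("unknown chromosome label(s): %s",
                 paste(bad_chrom, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(df$position)) || any(df$position < 0)) {
    stop("probe positions must be non-negative", call. = FALSE)
  }
  bad_class <- unique(df$probe_class[!df$probe_class %in% PROBE_CLASSES])
  if (length(bad_class) > 0) {
    stop(sprintf("unknown probe_class value(s): %s",
                 paste(bad_class, collapse = ", ")), call. = FALSE)
  }
  df <- df[chrom_order(df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Read a probe manifest from CSV
#'
#' @param path CSV file with the seven manifest columns (see
#'   [probe_manifest()]).
#' @return A validated, sorted `probe_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(probe_id = "character",
                                chromosome = "character",
                                gene = "character"))
  probe_manifest(df)
}

#' Write a probe manifest to CSV
#'
#' Inverse of [read_manifest()]: writing then reading reproduces the manifest
#' on all fields.
#'
#' @param manifest a `probe_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count manifest probes by class
#'
#' @param manifest a `probe_manifest`.
#' @return Named integer vector over the probe classes, plus a `custom` total
#'   (SNV + INDEL custom content).
#' @export
manifest_class_counts <- function(manifest) {
  counts <- vapply(PROBE_CLASSES,
                   function(cl) sum(manifest$probe_class == cl), integer(1))
  c(counts, custom = sum(counts[c("custom_pid_snv", "custom_pid_indel")]))
}

#' @export
print.probe_manifest <- function(x, ...) {
  counts <- manifest_class_counts(x)
  cat(sprintf(
    "Probe manifest: %d probes (%d custom SNV, %d custom INDEL, %d backbone)\n",
    nrow(x), counts[["custom_pid_snv"]], counts[["custom_pid_indel"]],
    counts[["backbone"]]))
  invisible(x)
}

#' Construct and validate a variant annotation table
#'
#' Per-probe annotations emulating the curated databases used for variant
#' interpretation: a pathogenicity class (disease-variant database style), a
#' population allele frequency (population-database style) and a Mendelian
#' inheritance pattern (Mendelian-inheritance-catalogue style).
#'
#' @param df data.frame with columns `probe_id`, `pathogenicity`
#'   (`disease_causing`, `likely_benign`, `benign`), `pop_frequency` in
#'   \[0,1\] (NA allowed: treated as unobserved, i.e. frequency 0), and
#'   `inheritance` (`AD`, `AR`, `XL`, `none`).
#' @param manifest the `probe_manifest` the annotations refer to.
#' @return A `variant_annotation` data.frame.
#' @export
variant_annotation <- function(df, manifest) {
  stopifnot_cols(df, c("probe_id", "pathogenicity", "pop_frequency",
                       "inheritance"), "variant annotation")
  df$probe_id <- as.character(df$probe_id)
  unknown <- setdiff(df$probe_id, manifest$probe_id)
  if (length(unknown) > 0) {
    stop(sprintf("annotation refers to probe(s) absent from manifest: %s",
                 paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  bad_path <- !df$pathogenicity %in% c("disease_causing", "likely_benign", "benign")
  if (any(bad_path)) {
    stop("pathogenicity must be disease_causing, likely_benign or benign",
         call. = FALSE)
  }
  f <- df$pop_frequency
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("pop_frequency must lie in [0, 1]", call. = FALSE)
  }
  if (any(!df$inheritance %in% c("AD", "AR", "XL", "none"))) {
    stop("inheritance must be AD, AR, XL or none", call. = FALSE)
  }
  class(df) <- c("variant_annotation", "data.frame")
  df
}

#' Read a variant annotation table from CSV
#'
#' @param path CSV with columns `probe_id`, `pathogenicity`, `pop_frequency`,
#'   `inheritance`.
#' @param manifest the `probe_manifest` the annotations refer to.
#' @return A validated `variant_annotation`.
#' @export
read_annotation <- function(path, manifest) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(probe_id = "character"))
  variant_annotation(df, manifest)
}

#' Read truth genotypes from CSV
#'
#' Truth genotypes play the role of deep whole-genome sequencing calls for
#' control samples: the reference against which array concordance is
#' measured. Genotypes are on the manifest allele frame (`AA`, `AB`, `BB`,
#' `missing`).
#'
#' @param path CSV with columns `sample_id`, `probe_id`, `genotype`.
#' @return A `truth_genotypes` data.frame, at most one record per
#'   (sample, probe).
#' @export
read_truth_genotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sample_id = "character",
                                probe_id = "character"))
  truth_genotypes(df)
}

#' @rdname read_truth_genotypes
#' @param df data.frame to validate in place of a file.
#' @export
truth_genotypes <- function(df) {
  stopifnot_cols(df, c("sample_id", "probe_id", "genotype"), "truth genotypes")
  if (any(!df$genotype %in% c(GENOTYPE_LEVELS, "missing"))) {
    stop("truth genotypes must be AA, AB, BB or missing", call. = FALSE)
  }
  key <- paste(df$sample_id, df$probe_id)
  if (anyDuplicated(key)) {
    stop("more than one truth record for the same (sample, probe)", call. = FALSE)
  }
  class(df) <- c("truth_genotypes", "data.frame")
  df
}

#' Read a benign-CNV track from CSV
#'
#' Known (population-polymorphic) copy-number intervals used to filter
#' heterozygous CNV calls. Intervals are 0-based half-open and may overlap.
#'
#' @param path CSV with columns `chromosome`, `start`, `end`, `zygosity`
#'   (`het` or `hom`).
#' @return A `benign_cnv_track` data.frame.
#' @export
read_benign_cnv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(chromosome = "character"))
  benign_cnv_track(df)
}

#' @rdname read_benign_cnv
#' @param df data.frame to validate in place of a file.
#' @export
benign_cnv_track <- function(df) {
  stopifnot_cols(df, c("chromosome", "start", "end", "zygosity"),
                 "benign CNV track")
  if (any(df$start >= df$end)) {
    stop("benign CNV intervals must satisfy start < end", call. = FALSE)
  }
  if (any(!is_valid_chrom(df$chromosome))) {
    stop("benign CNV track contains unknown chromosome labels", call. = FALSE)
  }
  class(df) <- c("benign_cnv_track", "data.frame")
  df
}
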