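# The genotype-matrix container and the VCF/SEG/BED writers.

#' Construct a genotype matrix
#'
#' Holds called genotypes for one array run as samples-by-probes matrices:
#' the call (`AA`, `AB`, `BB` or `nocall`), a call-confidence score in
#' \[0,1\] (present iff called), and which caller produced the entry
#' (`primary` cluster calling or the rare-variant `recalled` stage).
#'
#' @param calls character matrix (samples x probes) with dimnames, values in
#'   `AA`, `AB`, `BB`, `nocall`.
#' @param score numeric matrix, same shape; `NA` exactly where `calls` is
#'   `nocall`.
#' @param caller character matrix, same shape; `primary` or `recalled` where
#'   called, `NA` where `nocall`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, score, caller = NULL) {
  stopifnot(is.matrix(calls), is.matrix(score),
            all(dim(calls) == dim(score)),
            !is.null(rownames(calls)), !is.null(colnames(calls)))
  if (is.null(caller)) {
    caller <- matrix("primary", nrow(calls), ncol(calls),
                     dimnames = dimnames(calls))
    caller[calls == NOCALL] <- NA_character_
  }
  bad <- !calls %in% c(GENOTYPE_LEVELS, NOCALL)
  if (any(bad)) stop("calls must be AA, AB, BB or nocall", call. = FALSE)
  nc <- calls == NOCALL
  if (any(nc & !is.na(score)) || any(!nc & is.na(score))) {
    stop("score must be present exactly where a call was made", call. = FALSE)
  }
  structure(list(calls = calls, score = score, caller = caller),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cr <- mean(x$calls != NOCALL)
  cat(sprintf("Genotype matrix: %d samples x %d probes, call rate %.3f, %d recalled\n",
              nrow(x$calls), ncol(x$calls), cr,
              sum(x$caller == "recalled", na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Subset a genotype matrix by sample and/or probe ids.
subset_genotypes <- function(gm, samples = NULL, probes = NULL) {
  samples <- samples %||% rownames(gm$calls)
  probes <- probes %||% colnames(gm$calls)
  genotype_matrix(gm$calls[samples, probes, drop = FALSE],
                  gm$score[samples, probes, drop = FALSE],
                  gm$caller[samples, probes, drop = FALSE])
}

#' Write called genotypes as VCF 4.2
#'
#' Emits one record per called probe with genotypes encoded `0/0`, `0/1`,
#' `1/1` or `./.` and the call score in the `GS` FORMAT field. Internal
#' 0-based positions are converted to the 1-based VCF convention here, at the
#' single conversion point. INDEL probes carry their `I`/`D` allele tokens in
#' the REF/ALT columns. The header is static, so identical inputs produce
#' byte-identical files.
#'
#' @param calls a `genotype_matrix`.
#' @param manifest the `probe_manifest`; every called probe must be present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, manifest, path) {
  probes <- colnames(calls$calls)
  missing_probes <- setdiff(probes, manifest$probe_id)
  if (length(missing_probes) > 0) {
    stop(sprintf("probe(s) absent from manifest: %s",
                 paste(head(missing_probes, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- manifest[match(probes, manifest$probe_id), , drop = FALSE]
  ord <- chrom_order(m$chromosome, m$position)
  m <- m[ord, , drop = FALSE]
  probes <- probes[ord]
  samples <- rownames(calls$calls)

  gt_code <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pidscreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GS,Number=1,Type=Float,Description="Call confidence score in [0,1]">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(probes), function(j) {
    p <- probes[j]
    g <- calls$calls[, p]
    s <- calls$score[, p]
    gt <- ifelse(g == NOCALL, "./.", gt_code[g])
    gs <- ifelse(is.na(s), ".", sprintf("%.4f", s))
    paste(c(m$chromosome[j], m$position[j] + 1L, p,
            m$ref_allele[j], m$alt_allele[j], ".", "PASS", ".", "GT:GS",
            paste(gt, gs, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write CNV/LCSH segments as SEG
#'
#' Tab-separated SEG with 0-based half-open coordinates: sample, chromosome,
#' start, end, number of probes, mean log2 ratio, event class.
#'
#' @param segments a `cnv_segments` data.frame (see [segment_lrr()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(
    sample = segments$sample_id, chrom = segments$chromosome,
    loc.start = segments$start, loc.end = segments$end,
    num.mark = segments$n_probes,
    seg.mean = sprintf("%.4f", segments$mean_log2),
    event = segments$event)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(df, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write events as BED
#'
#' BED3+ with 0-based half-open coordinates and the event class plus sample
#' in the name column.
#'
#' @inheritParams write_seg
#' @export
write_bed <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s", segments$chromosome,
                   segments$start, segments$end,
                   segments$sample_id, segments$event)
  writeLines(lines, path)
  invisible(path)
}
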