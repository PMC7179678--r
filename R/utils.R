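# Shared internal helpers: chromosome ordering, rounding, seed substreams.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

GENOTYPE_LEVELS <- c("AA", "AB", "BB")
NOCALL <- "nocall"

#' Round half away from zero
#'
#' Percent statistics are reported at the precision conventional in array
#' validation studies (one decimal for concordance and reproducibility,
#' integer for sensitivity and yield), rounding halves away from zero rather
#' than to even as [base::round()] does.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round_half_up(94.87179, 1)  # 94.9
#' round_half_up(0.5)          # 1
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Order index over (chromosome, position) using the canonical 1..22, X, Y order.
chrom_order <- function(chromosome, position) {
  order(match(chromosome, CHROM_LEVELS), position)
}

is_valid_chrom <- function(chromosome) {
  chromosome %in% CHROM_LEVELS
}

# Deterministic 32-bit substream seed from a master seed and a stream label,
# so independent simulation stages do not share an RNG stream.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate expr with a temporary RNG state seeded from (seed, label).
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}
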