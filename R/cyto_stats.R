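# Cytogenetic summaries: chromosome counts per cell, nucleoli per
# nucleus, and the nucleoli-chromosome correlation.

#' Summarise per-cell chromosome counts
#'
#' @param counts Integer vector of chromosome counts, one per metaphase
#'   cell (values in 1-300).
#' @param modal_interval Optional length-2 vector `c(lo, hi)`; the share
#'   of cells whose count falls inside the closed interval is reported
#'   as `modal_class_share` (e.g. the hyper-diploid 48-80 class).
#' @return List with `range`, `mean`, `se` (sample SD / sqrt(n); 0 with
#'   a warning for n = 1), `histogram` (bins of width 10 starting at 1:
#'   1-10, 11-20, ...), and `modal_class_share` (or `NA`).
#' @export
chromosome_summary <- function(counts, modal_interval = NULL) {
  if (!length(counts)) stop("no chromosome counts supplied")
  counts <- as.integer(counts)
  if (any(counts < 1L) || any(counts > 300L))
    stop("chromosome counts must lie in [1, 300]")
  n <- length(counts)
  se <- if (n == 1L) {
    warning("single observation: SE reported as 0")
    0
  } else stats::sd(counts) / sqrt(n)
  top <- 10L * ceiling(max(counts) / 10L)
  breaks <- seq(0L, top, by = 10L)
  h <- table(cut(counts, breaks = breaks + 0.5,
                 labels = paste(breaks[-length(breaks)] + 1L,
                                breaks[-1L], sep = "-"),
                 include.lowest = TRUE))
  share <- NA_real_
  if (!is.null(modal_interval)) {
    stopifnot(length(modal_interval) == 2L)
    share <- mean(counts >= modal_interval[1] & counts <= modal_interval[2])
  }
  list(range = range(counts), mean = mean(counts), se = se,
       histogram = h, modal_class_share = share)
}

#' Summarise nucleoli counts per nucleus
#'
#' @param macro,micro Integer vectors (same length): per-nucleus counts
#'   of macro (>= 2 um) and micro (< 2 um) nucleoli.
#' @return List with `macro_mean`, `macro_se`, `micro_mean`, `micro_se`,
#'   `total_range` (range of macro + micro per nucleus) and `n`.
#'   SE is sample SD / sqrt(n), reported as 0 with a warning when n = 1.
#' @export
nucleoli_summary <- function(macro, micro = rep(0L, length(macro))) {
  if (!length(macro)) stop("no nuclei supplied")
  if (length(micro) != length(macro))
    stop("macro and micro must have the same length")
  if (any(macro < 0) || any(micro < 0)) stop("counts must be non-negative")
  n <- length(macro)
  if (n == 1L) warning("single nucleus: SE reported as 0")
  se <- function(x) if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  list(macro_mean = mean(macro), macro_se = se(macro),
       micro_mean = mean(micro), micro_se = se(micro),
       total_range = range(macro + micro), n = n)
}

#' Pearson product-moment correlation with t-test p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; an error is raised
#'   when either has zero variance.
#' @return List with `r`, `t`, `df`, `p` (two-sided, from the t
#'   distribution with n - 2 degrees of freedom).
#' @examples
#' pearson_r(1:5, 2 * (1:5))$r  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, df = n - 2L,
       p = 2 * stats::pt(-abs(tt), df = n - 2L))
}

#' Correlation of mean nucleoli and mean chromosome numbers across lines
#'
#' Computes the Pearson correlation between per-line mean nucleoli per
#' nucleus and per-line mean chromosomes per cell. Because "mean number
#' of nucleoli" is ambiguous between macro-only and macro + micro
#' totals, both conventions are supported.
#'
#' @param cyto Data frame with one row per cell line and columns
#'   `macro_mean`, `micro_mean`, `chr_mean`.
#' @param nucleoli `"total"` (macro + micro, default) or `"macro"`.
#' @return As [pearson_r()].
#' @export
nucleoli_chromosome_correlation <- function(cyto,
                                            nucleoli = c("total",
                                                         "macro")) {
  nucleoli <- match.arg(nucleoli)
  stopifnot(all(c("macro_mean", "micro_mean", "chr_mean") %in% names(cyto)))
  x <- if (nucleoli == "total") cyto$macro_mean + cyto$micro_mean
       else cyto$macro_mean
  pearson_r(x, cyto$chr_mean)
}

#' Read per-cell chromosome and per-nucleus nucleoli tables
#'
#' `read_chromosome_counts()` expects a TSV with header columns
#' `line_id`, `cell_id`, `chromosome_count`; `read_nucleoli_counts()`
#' expects `line_id`, `nucleus_id`, `macro`, `micro`.
#'
#' @param path Path to the TSV file.
#' @return The table as a data frame.
#' @export
read_chromosome_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "cell_id", "chromosome_count") %in% names(tab)))
  tab
}

#' @rdname read_chromosome_counts
#' @export
read_nucleoli_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "nucleus_id", "macro", "micro") %in% names(tab)))
  tab
}
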