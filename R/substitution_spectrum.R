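# Per-clone substitution calling and per-line spectrum statistics.

# canonical order of the 12 directed substitution types
SUB_TYPES <- c("A>G", "T>C", "G>A", "C>T",
               "A>T", "A>C", "T>A", "T>G", "G>T", "C>G", "G>C", "C>A")
TS_TYPES <- c("A>G", "T>C", "G>A", "C>T")
MET_TYPES <- c("G>A", "C>T")   # deamination footprint of 5-methylcytosine
AM_TYPES <- c("T>A", "T>C", "T>G")  # replacement of reference T

#' Classify a directed base substitution
#'
#' A change is a transition when both bases are purines or both are
#' pyrimidines; methylation-associated when it is `C>T` or `G>A` (the
#' sequence footprint expected from deamination of 5-methylcytosine, with
#' no reverse-strand symmetrisation); amination-associated when the
#' reference base `T` is replaced by any other base. All arguments are
#' vectorised.
#'
#' @param ref_base,alt_base Single characters in `A`, `C`, `G`, `T`;
#'   `ref_base != alt_base`.
#' @return Data frame with logical columns `is_transition`,
#'   `is_methylation`, `is_amination`.
#' @examples
#' classify_substitution("C", "T")  # transition + methylation-associated
#' classify_substitution("T", "C")  # transition + amination-associated
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  if (any(!ref_base %in% DNA_BASES) || any(!alt_base %in% DNA_BASES))
    stop("bases must be one of A, C, G, T")
  if (any(ref_base == alt_base))
    stop("ref_base and alt_base must differ")
  type <- paste0(ref_base, ">", alt_base)
  data.frame(
    is_transition = type %in% TS_TYPES,
    is_methylation = type %in% MET_TYPES,
    is_amination = type %in% AM_TYPES
  )
}

#' Call substitutions of a clone against the aligned reference
#'
#' One call per alignment column where both sequences carry an
#' unambiguous base (`A`/`C`/`G`/`T`) and the bases differ. Columns with a
#' gap or an ambiguity code in either sequence are skipped entirely, so
#' only unambiguous substitution directions are reported. Positions are in
#' ungapped (1-based) reference coordinates.
#'
#' @param aligned_clone,aligned_ref Equal-length aligned strings.
#' @param clone_id Identifier recorded with each call.
#' @return Data frame with columns `clone_id`, `pos`, `ref`, `alt`,
#'   `type`, `is_transition`, `is_methylation`, `is_amination`.
#' @export
call_substitutions <- function(aligned_clone, aligned_ref,
                               clone_id = "clone") {
  if (nchar(aligned_clone) != nchar(aligned_ref))
    stop("aligned sequences must have equal length")
  cc <- seq_chars(toupper(aligned_clone))
  rc <- seq_chars(toupper(aligned_ref))
  ref_pos <- cumsum(rc != "-")
  keep <- rc %in% DNA_BASES & cc %in% DNA_BASES & rc != cc
  out <- data.frame(
    clone_id = rep(clone_id, sum(keep)),
    pos = ref_pos[keep],
    ref = rc[keep],
    alt = cc[keep]
  )
  if (nrow(out)) {
    out$type <- paste0(out$ref, ">", out$alt)
    out <- cbind(out, classify_substitution(out$ref, out$alt))
  } else {
    out$type <- character(0)
    out$is_transition <- logical(0)
    out$is_methylation <- logical(0)
    out$is_amination <- logical(0)
  }
  rownames(out) <- NULL
  out
}

#' Call substitutions for every clone of a clone set
#'
#' Applies [call_substitutions()] clone by clone against the reference.
#' Clones produced by [align_clone_set()] or [generate_clone_set()] are
#' already on reference coordinates, so the reference sequence itself is
#' the aligned counterpart.
#'
#' @param clones A [clone_set()].
#' @param ref A [reference_gene()] or reference string of matching length.
#' @return Data frame of substitution calls for all clones.
#' @export
call_substitutions_set <- function(clones, ref) {
  stopifnot(inherits(clones, "clone_set"))
  ref_seq <- if (inherits(ref, "reference_gene")) ref$seq else toupper(ref)
  res <- lapply(names(clones$clones), function(id) {
    call_substitutions(clones$clones[[id]], ref_seq, clone_id = id)
  })
  do.call(rbind, res)
}

# histogram bins over per-clone substitution counts
CLONE_BINS <- c("0", "1-2", "3-4", "5-6", "7-10", ">10")

bin_clone_counts <- function(counts) {
  cut(counts, breaks = c(-0.5, 0.5, 2.5, 4.5, 6.5, 10.5, Inf),
      labels = CLONE_BINS)
}

#' Histogram of substitutions per clone
#'
#' Bins the per-clone substitution counts into the classes
#' 0, 1-2, 3-4, 5-6, 7-10 and >10. Clones with no substitution calls are
#' counted in the `0` bin.
#'
#' @param subs Substitution calls (from [call_substitutions_set()]).
#' @param clones The [clone_set()] the calls came from.
#' @return List with `counts` (named integer vector over the six bins,
#'   summing to the number of clones) and `pct` (percent of clones).
#' @export
per_clone_histogram <- function(subs, clones) {
  stopifnot(inherits(clones, "clone_set"))
  per_clone <- table(factor(subs$clone_id, levels = names(clones$clones)))
  binned <- table(bin_clone_counts(as.integer(per_clone)))
  counts <- as.integer(binned)
  names(counts) <- CLONE_BINS
  list(counts = counts, pct = 100 * counts / clones$n)
}

# Core spectrum computation from a named count vector over SUB_TYPES.
spectrum_core <- function(type_counts, n_clones, line_id = NA_character_,
                          per_clone_counts = NULL, gc_pct = NA_real_) {
  if (n_clones < 1L) stop("clone set must contain at least one clone")
  counts <- integer(length(SUB_TYPES))
  names(counts) <- SUB_TYPES
  counts[names(type_counts)] <- as.integer(type_counts)
  total <- sum(counts)
  ts <- sum(counts[TS_TYPES])
  tv <- total - ts
  met <- sum(counts[MET_TYPES])
  am <- sum(counts[AM_TYPES])
  pct <- if (total > 0) 100 * counts / total else counts * 0
  bins <- NULL
  if (!is.null(per_clone_counts)) {
    b <- table(bin_clone_counts(per_clone_counts))
    bins <- as.integer(b)
    names(bins) <- CLONE_BINS
  }
  structure(list(
    line_id = line_id,
    n_clones = as.integer(n_clones),
    counts = counts,
    total = total,
    ts = ts,
    tv = tv,
    ts_tv = if (tv == 0) Inf else ts / tv,
    pct = pct,
    met_count = met,
    am_count = am,
    met_pct = if (total > 0) 100 * met / total else 0,
    am_pct = if (total > 0) 100 * am / total else 0,
    met_am_ratio = if (am == 0) Inf else met / am,
    per_gene_all = total / n_clones,
    per_gene_met = met / n_clones,
    per_gene_am = am / n_clones,
    gc_pct = gc_pct,
    per_clone_bins = bins
  ), class = "spectrum_summary")
}

#' Summarise the substitution spectrum of a clone set
#'
#' Computes, for one cell line, the directed-type counts over the 12
#' substitution types, the transition/transversion ratio, the shares of
#' methylation- and amination-associated changes, mean substitutions per
#' gene copy (all / methylation / amination), the mean G+C content of the
#' (ungapped) clone sequences, and the per-clone count histogram. All
#' values are stored unrounded; rounding to printed precision happens
#' only in the print method.
#'
#' @param clones The [clone_set()].
#' @param subs Substitution calls produced from `clones`
#'   (see [call_substitutions_set()]).
#' @return Object of class `spectrum_summary`.
#' @export
summarize_spectrum <- function(clones, subs) {
  stopifnot(inherits(clones, "clone_set"))
  if (clones$n == 0L) stop("clone set must contain at least one clone")
  type_counts <- table(factor(subs$type, levels = SUB_TYPES))
  per_clone <- as.integer(table(factor(subs$clone_id,
                                       levels = names(clones$clones))))
  gc <- vapply(clones$clones, function(s) {
    ch <- seq_chars(s)
    ch <- ch[ch %in% DNA_BASES]
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
  spectrum_core(type_counts, clones$n, line_id = clones$line_id,
                per_clone_counts = per_clone, gc_pct = mean(gc))
}

#' Build a spectrum summary directly from directed-type counts
#'
#' Takes a published or otherwise pre-tallied table of directed
#' substitution-type counts for a line (e.g. `c("A>G" = 10, "T>C" = 19,
#' ...)`) and computes the same summary statistics as
#' [summarize_spectrum()]. Arrow notation (`"A->G"`, `"A→G"`, `"A/G"`) is
#' accepted in names. G+C content and the per-clone histogram are not
#' derivable from counts alone and are reported as `NA`/absent.
#'
#' @param counts Named numeric vector of directed-type counts.
#' @param n_clones Number of clones the counts were tallied over.
#' @param line_id Optional identifier.
#' @return Object of class `spectrum_summary`.
#' @export
spectrum_from_counts <- function(counts, n_clones, line_id = NA_character_) {
  nm <- gsub("→|->|/", ">", names(counts))
  nm <- gsub("\\s", "", nm)
  if (any(!nm %in% SUB_TYPES))
    stop("unknown substitution type(s): ",
         paste(nm[!nm %in% SUB_TYPES], collapse = ", "))
  names(counts) <- nm
  spectrum_core(counts, n_clones, line_id = line_id)
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Substitution spectrum", if (!is.na(x$line_id)) x$line_id else "",
      "(n =", x$n_clones, "clones)\n")
  cat("  total:", x$total,
      " ts/tv:", if (is.infinite(x$ts_tv)) "Inf" else
        format(round_half_up(x$ts_tv, 2)), "\n")
  cat("  Met%:", round_half_up(x$met_pct, 2),
      " Am%:", round_half_up(x$am_pct, 2),
      " Met/Am:", if (is.infinite(x$met_am_ratio)) "Inf" else
        round_half_up(x$met_am_ratio, 2), "\n")
  cat("  per gene copy: all", round_half_up(x$per_gene_all, 2),
      "| methylation", round_half_up(x$per_gene_met, 2),
      "| amination", round_half_up(x$per_gene_am, 2), "\n")
  if (!is.na(x$gc_pct))
    cat("  mean G+C%:", round_half_up(x$gc_pct, 2), "\n")
  invisible(x)
}

#' Write substitution calls and a spectrum summary as TSV
#'
#' @param subs Substitution calls data frame.
#' @param summary A `spectrum_summary`.
#' @param out_prefix Path prefix; writes `<prefix>_substitutions.tsv` and
#'   `<prefix>_spectrum.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_spectrum <- function(subs, summary, out_prefix) {
  p1 <- paste0(out_prefix, "_substitutions.tsv")
  p2 <- paste0(out_prefix, "_spectrum.tsv")
  utils::write.table(subs, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  row <- data.frame(
    line_id = summary$line_id, n_clones = summary$n_clones,
    t(summary$counts), total = summary$total,
    ts_tv = summary$ts_tv, met_pct = summary$met_pct,
    am_pct = summary$am_pct, met_am_ratio = summary$met_am_ratio,
    per_gene_all = summary$per_gene_all,
    per_gene_met = summary$per_gene_met,
    per_gene_am = summary$per_gene_am, gc_pct = summary$gc_pct,
    check.names = FALSE
  )
  utils::write.table(row, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
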