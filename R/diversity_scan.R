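# Nucleotide diversity, sliding windows, site classification, distances,
# and region hotspot tables.

# pairwise difference / valid-site counts for all unordered pairs
pair_diff_stats <- function(mat) {
  n <- nrow(mat)
  valid <- matrix(mat %in% DNA_BASES, nrow = n)
  pairs <- utils::combn(n, 2)
  diffs <- integer(ncol(pairs))
  valids <- integer(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    vv <- valid[i, ] & valid[j, ]
    valids[p] <- sum(vv)
    diffs[p] <- sum(mat[i, vv] != mat[j, vv])
  }
  list(i = pairs[1, ], j = pairs[2, ], diff = diffs, valid = valids)
}

#' Nucleotide diversity of an alignment
#'
#' Per-site nucleotide diversity: the average, over all unordered
#' sequence pairs, of the proportion of differing sites among the sites
#' validly compared for that pair. Columns where either member of a pair
#' carries a gap or an ambiguity code are excluded pairwise (pairwise
#' deletion).
#'
#' @param seqs Character vector of at least two equal-length aligned
#'   sequences.
#' @return Per-site diversity (a proportion in `[0, 1]`).
#' @examples
#' nucleotide_diversity(c("ACGT", "ACGT"))      # 0
#' nucleotide_diversity(c(a = "AAAA", b = "AAAT"))  # 0.25
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  st <- pair_diff_stats(seq_matrix(seqs))
  ok <- st$valid > 0
  mean(st$diff[ok] / st$valid[ok])
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows of `window_len` sites advance by `step` sites starting at
#' column 1; a trailing window that would extend past the alignment is
#' discarded rather than shrunk. Each window's diversity is computed on
#' its columns alone. The profile also carries the global diversity and
#' the per-site classification of [classify_sites()].
#'
#' @param seqs Aligned sequences (>= 2, equal length >= `window_len`).
#' @param window_len Window length in sites (default 100).
#' @param step Step size in sites (default 25).
#' @param line_id Optional identifier carried in the profile.
#' @return Object of class `diversity_profile`: list with `windows`
#'   (data frame `start`, `mid`, `end`, `pi`), `global_pi`,
#'   `site_classes`, `site_counts`, `window_len`, `step`, `line_id`.
#' @export
sliding_window_pi <- function(seqs, window_len = 100L, step = 25L,
                              line_id = NA_character_) {
  if (window_len < 2L) stop("window_len must be at least 2")
  if (step < 1L) stop("step must be positive")
  mat <- seq_matrix(seqs)
  L <- ncol(mat)
  if (L < window_len)
    stop("alignment length (", L, ") shorter than window_len (",
         window_len, ")")
  starts <- 1L + step * (0:((L - window_len) %/% step))
  pi_w <- vapply(starts, function(s) {
    sub <- mat[, s:(s + window_len - 1L), drop = FALSE]
    st <- pair_diff_stats(sub)
    ok <- st$valid > 0
    if (!any(ok)) return(NA_real_)
    mean(st$diff[ok] / st$valid[ok])
  }, numeric(1))
  cls <- classify_sites(seqs)
  structure(list(
    line_id = line_id,
    window_len = as.integer(window_len),
    step = as.integer(step),
    windows = data.frame(start = starts,
                         mid = starts + (window_len - 1) / 2,
                         end = starts + window_len - 1L,
                         pi = pi_w),
    global_pi = nucleotide_diversity(seqs),
    site_classes = cls$classes,
    site_counts = cls$counts
  ), class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("Diversity profile", if (!is.na(x$line_id)) x$line_id else "", "\n")
  cat("  global pi:", signif(x$global_pi, 4), "over",
      length(x$site_classes), "sites\n")
  cat("  ", nrow(x$windows), " windows of ", x$window_len,
      " sites, step ", x$step, "\n", sep = "")
  cat("  sites:", paste(names(x$site_counts), x$site_counts,
                        collapse = ", "), "\n")
  invisible(x)
}

#' Classify alignment sites
#'
#' A site is *variable* when at least two distinct unambiguous bases
#' occur; *parsimony-informative* when at least two bases each occur in
#' at least two sequences; otherwise a variable site is a *singleton*
#' (every minority base occurs in exactly one sequence). Sites with fewer
#' than two valid bases are invariant.
#'
#' @param seqs Aligned sequences (>= 2).
#' @return List with `classes` (per-site character vector with values
#'   `"invariant"`, `"singleton"`, `"parsimony_informative"`) and
#'   `counts` (named totals, including `variable = singleton +
#'   parsimony_informative`).
#' @export
classify_sites <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  mat <- seq_matrix(seqs)
  classes <- apply(mat, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    tab <- table(col)
    if (length(tab) < 2L) return("invariant")
    if (sum(tab >= 2L) >= 2L) return("parsimony_informative")
    "singleton"
  })
  counts <- c(
    invariant = sum(classes == "invariant"),
    singleton = sum(classes == "singleton"),
    parsimony_informative = sum(classes == "parsimony_informative")
  )
  counts <- c(counts,
              variable = unname(counts["singleton"] +
                                  counts["parsimony_informative"]))
  list(classes = unname(classes), counts = counts)
}

#' Pairwise p-distances and mean number of differences
#'
#' For every unordered pair: `D` is the proportion of differing sites
#' among validly compared sites (p-distance) and `K` the raw count of
#' differences. `mean_D` and `mean_K` average these over all pairs.
#'
#' @param seqs Aligned sequences (>= 2).
#' @return List with `D` (symmetric p-distance matrix, zero diagonal),
#'   `K` (symmetric count matrix), `mean_D`, `mean_K`.
#' @export
pairwise_distances <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  mat <- seq_matrix(seqs)
  n <- nrow(mat)
  st <- pair_diff_stats(mat)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  K <- D
  for (p in seq_along(st$i)) {
    d <- if (st$valid[p] > 0) st$diff[p] / st$valid[p] else NA_real_
    D[st$i[p], st$j[p]] <- D[st$j[p], st$i[p]] <- d
    K[st$i[p], st$j[p]] <- K[st$j[p], st$i[p]] <- st$diff[p]
  }
  list(D = D, K = K,
       mean_D = mean(st$diff[st$valid > 0] / st$valid[st$valid > 0]),
       mean_K = mean(st$diff))
}

#' Per-region substitution hotspot table
#'
#' Assigns substitution calls to every annotated region containing their
#' position (overlapping regions each receive the call) and reports, per
#' region, the call count together with the peak sliding-window diversity
#' among windows overlapping the region and the start position of that
#' peak window.
#'
#' @param profile A [sliding_window_pi()] profile.
#' @param regions Region data frame (`name`, `start`, `end`).
#' @param subs Substitution calls (see [call_substitutions_set()]).
#' @param class_filter `"all"`, `"methylation"` or `"amination"`;
#'   restricts the counted calls to the flagged class.
#' @return Data frame with columns `region`, `start`, `end`, `n_subs`,
#'   `peak_pi`, `peak_pos`.
#' @export
region_hotspots <- function(profile, regions, subs,
                            class_filter = c("all", "methylation",
                                             "amination")) {
  class_filter <- match.arg(class_filter)
  stopifnot(inherits(profile, "diversity_profile"))
  regions <- validate_regions(regions,
                              ref_length = length(profile$site_classes))
  subs <- switch(class_filter,
                 all = subs,
                 methylation = subs[subs$is_methylation, , drop = FALSE],
                 amination = subs[subs$is_amination, , drop = FALSE])
  w <- profile$windows
  out <- lapply(seq_len(nrow(regions)), function(k) {
    r <- regions[k, ]
    n_subs <- sum(subs$pos >= r$start & subs$pos <= r$end)
    ov <- which(w$start <= r$end & w$end >= r$start)
    if (length(ov)) {
      peak <- ov[which.max(w$pi[ov])]
      peak_pi <- w$pi[peak]
      peak_pos <- w$start[peak]
    } else {
      peak_pi <- NA_real_
      peak_pos <- NA_integer_
    }
    data.frame(region = r$name, start = r$start, end = r$end,
               n_subs = n_subs, peak_pi = peak_pi, peak_pos = peak_pos)
  })
  do.call(rbind, out)
}
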