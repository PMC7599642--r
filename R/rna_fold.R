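# Nested secondary-structure prediction for short rRNA segments, loop
# census, structure comparison, and intersegment complementarity.
#
# Folding is a deterministic Nussinov-style dynamic programme. "maxpair"
# maximises the number of Watson-Crick (+GU wobble) pairs; "stacking"
# (the default) additionally awards one point per stacked neighbour
# pair, which favours contiguous helices over isolated pairs and so
# captures the helix-versus-loop trade-offs that structure comparisons
# between alleles rest on. Full Turner-rule thermodynamics is outside
# the scope of this package.

RNA_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

can_pair <- function(a, b, wobble = TRUE) {
  p <- paste0(a, b)
  if (wobble) p %in% RNA_PAIRS else p %in% RNA_PAIRS[1:4]
}

#' Convert a pair list to dot-bracket notation and back
#'
#' @param pairs Two-column matrix of 1-based pair positions (i < j).
#' @param n Sequence length.
#' @return `pairs_to_dotbracket()`: a dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (length(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  chars_seq(db)
}

#' @rdname pairs_to_dotbracket
#' @param db Dot-bracket string.
#' @return `dotbracket_to_pairs()`: a two-column matrix (`i`, `j`).
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- seq_chars(db)
  stack <- integer(0)
  out <- NULL
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      out <- rbind(out, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    } else if (ch[k] != ".") {
      stop("invalid dot-bracket character: ", ch[k])
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Fold a short RNA segment into a nested secondary structure
#'
#' Dynamic programme over nested structures with a minimum hairpin loop
#' of `min_loop` unpaired bases (pair (i, j) requires `j - i >
#' min_loop`). GU wobble pairs are allowed. The traceback is
#' deterministic: whenever pairing the left end attains the optimum it
#' is paired with its smallest admissible partner, and stacked
#' continuations are preferred on ties.
#'
#' @param seq RNA string (`ACGU`; `T` is converted to `U`), length 4-300.
#' @param min_loop Minimum unpaired span enclosed by a pair (default 3).
#' @param mode `"stacking"` (pairs + stacking bonus, default) or
#'   `"maxpair"` (pair count only).
#' @return Object of class `rna_structure`: list with `seq`, `pairs`
#'   (two-column matrix), `dot_bracket`, `score`, `mode`, `features`
#'   (a [loop_census()]).
#' @examples
#' fold_segment("GGGAAACCC", mode = "maxpair")$dot_bracket  # "(((...)))"
#' @export
fold_segment <- function(seq, min_loop = 3L, mode = c("stacking",
                                                      "maxpair")) {
  mode <- match.arg(mode)
  s <- gsub("T", "U", toupper(seq), fixed = TRUE)
  if (grepl("[^ACGU]", s)) stop("sequence must contain only A, C, G, U")
  n <- nchar(s)
  if (n < 4L || n > 300L) stop("segment length must be between 4 and 300")
  ch <- seq_chars(s)
  bonus <- if (mode == "stacking") 1L else 0L
  pairable <- outer(ch, ch, FUN = function(a, b) paste0(a, b) %in% RNA_PAIRS)

  NEG <- -1e9
  FF <- matrix(0L, n + 1L, n + 1L)   # FF[i, j+1] == F(i, j); zero if i > j
  P <- matrix(NEG, n, n)
  getF <- function(i, j) if (i > j) 0L else FF[i, j + 1L]
  for (l in seq_len(n - 1L)) {
    for (i in seq_len(n - l)) {
      j <- i + l
      if (j - i > min_loop && pairable[i, j]) {
        inner <- getF(i + 1L, j - 1L)
        stk <- if (j - 1L - (i + 1L) > min_loop && pairable[i + 1L, j - 1L])
          P[i + 1L, j - 1L] + bonus else NEG
        P[i, j] <- 1L + max(inner, stk)
      }
      best <- getF(i + 1L, j)
      ks <- if (i + min_loop + 1L <= j) seq.int(i + min_loop + 1L, j)
            else integer(0)
      ks <- ks[pairable[i, ks]]
      if (length(ks)) {
        vals <- P[i, ks] + vapply(ks, function(k) as.numeric(getF(k + 1L, j)),
                                  numeric(1))
        best <- max(best, max(vals))
      }
      FF[i, j + 1L] <- best
    }
  }

  pairs <- NULL
  trace_p <- function(i, j) {
    pairs <<- rbind(pairs, c(i, j))
    if (i + 1L > j - 1L) return(invisible())
    stk_ok <- j - 1L - (i + 1L) > min_loop && pairable[i + 1L, j - 1L] &&
      P[i + 1L, j - 1L] + bonus == P[i, j] - 1L
    if (stk_ok) trace_p(i + 1L, j - 1L) else trace_f(i + 1L, j - 1L)
  }
  trace_f <- function(i, j) {
    while (i <= j) {
      target <- getF(i, j)
      if (target == 0L) return(invisible())
      ks <- seq.int(min(i + min_loop + 1L, j), j)
      ks <- ks[ks > i + min_loop & pairable[i, ks]]
      hit <- NA_integer_
      for (k in ks) {
        if (P[i, k] + getF(k + 1L, j) == target) { hit <- k; break }
      }
      if (!is.na(hit)) {
        trace_p(i, hit)
        i <- hit + 1L
      } else {
        i <- i + 1L
      }
    }
    invisible()
  }
  trace_f(1L, n)
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("i", "j")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  st <- structure(list(
    seq = s,
    pairs = pairs,
    dot_bracket = pairs_to_dotbracket(pairs, n),
    score = getF(1L, n),
    mode = mode,
    features = NULL
  ), class = "rna_structure")
  st$features <- loop_census(st)
  st
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, "\n", sep = "")
  cat(nrow(x$pairs), "pairs, score", x$score, "(", x$mode, ")\n")
  invisible(x)
}

#' Census the loop features of a nested secondary structure
#'
#' Helices are maximal runs of stacked pairs (i, j), (i+1, j-1), ...
#' Every unpaired base is attributed to exactly one loop or to the
#' exterior: a pair with no nested pairs closes a hairpin loop; one
#' nested helix with unpaired bases on one side only is a bulge loop, on
#' both sides an interior loop; two or more nested helices close a
#' multibranch loop.
#'
#' @param x An `rna_structure`, or a two-column pair matrix.
#' @param n Sequence length (required when `x` is a pair matrix).
#' @return Object of class `structure_features`: list with `n_helices`,
#'   `hairpin_loops`, `bulge_loops`, `interior_loops` (two-column matrix
#'   `size5`, `size3`), `multi_loops`, `n_unpaired`, `exterior_unpaired`.
#' @export
loop_census <- function(x, n = NULL) {
  if (inherits(x, "rna_structure")) {
    pairs <- x$pairs
    n <- nchar(x$seq)
  } else {
    pairs <- x
    if (is.null(n)) stop("sequence length n required with a pair matrix")
  }
  pairs <- matrix(as.integer(pairs), ncol = 2, dimnames = NULL)
  np <- nrow(pairs)
  if (np) {
    if (any(pairs[, 1] >= pairs[, 2]) || any(pairs < 1) || any(pairs > n))
      stop("invalid pair coordinates")
    if (anyDuplicated(as.vector(pairs)))
      stop("a position participates in more than one pair")
    if (np > 1L) {
      for (a in 1:(np - 1)) for (b in (a + 1):np) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        p <- pairs[b, 1]; q <- pairs[b, 2]
        if ((i < p & p < j & j < q) || (p < i & i < q & q < j))
          stop("crossing pairs (pseudoknot): (", i, ",", j, ") x (",
               p, ",", q, ")")
      }
    }
  }
  partner <- integer(n)
  if (np) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  paired <- partner > 0L
  # helices: pair list sorted by i; a new helix starts unless the
  # previous pair stacks directly outside
  n_helices <- 0L
  if (np) {
    ord <- pairs[order(pairs[, 1]), , drop = FALSE]
    stacked_onto <- vapply(seq_len(np), function(k) {
      i <- ord[k, 1]; j <- ord[k, 2]
      i > 1L && j < n && partner[i - 1L] == j + 1L
    }, logical(1))
    n_helices <- sum(!stacked_onto)
  }
  hairpins <- integer(0)
  bulges <- integer(0)
  interiors <- NULL
  multis <- integer(0)
  attributed <- 0L
  if (np) {
    for (k in seq_len(np)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      # direct children: maximal pairs strictly inside (i, j)
      inside <- i + 1L
      children <- NULL
      unpaired_in <- 0L
      pos <- inside
      while (pos <= j - 1L) {
        if (partner[pos] > pos) {
          children <- rbind(children, c(pos, partner[pos]))
          pos <- partner[pos] + 1L
        } else {
          unpaired_in <- unpaired_in + 1L
          pos <- pos + 1L
        }
      }
      nc <- if (is.null(children)) 0L else nrow(children)
      if (nc == 0L) {
        hairpins <- c(hairpins, unpaired_in)
        attributed <- attributed + unpaired_in
      } else if (nc == 1L) {
        left <- children[1, 1] - i - 1L
        right <- j - children[1, 2] - 1L
        if (left == 0L && right == 0L) {
          # stacked pair: no loop
        } else if (left == 0L || right == 0L) {
          bulges <- c(bulges, left + right)
          attributed <- attributed + left + right
        } else {
          interiors <- rbind(interiors, c(left, right))
          attributed <- attributed + left + right
        }
      } else {
        multis <- c(multis, unpaired_in)
        attributed <- attributed + unpaired_in
      }
    }
  }
  if (is.null(interiors)) interiors <- matrix(integer(0), ncol = 2)
  colnames(interiors) <- c("size5", "size3")
  # exterior unpaired: not enclosed by any pair
  depth <- integer(n)
  open <- 0L
  for (pos in seq_len(n)) {
    if (paired[pos] && partner[pos] > pos) {
      depth[pos] <- open
      open <- open + 1L
    } else if (paired[pos]) {
      open <- open - 1L
      depth[pos] <- open
    } else {
      depth[pos] <- open
    }
  }
  exterior <- sum(!paired & depth == 0L)
  structure(list(
    n_helices = n_helices,
    hairpin_loops = hairpins,
    bulge_loops = bulges,
    interior_loops = interiors,
    multi_loops = multis,
    n_unpaired = n - 2L * np,
    exterior_unpaired = exterior
  ), class = "structure_features")
}

#' @export
print.structure_features <- function(x, ...) {
  cat(x$n_helices, "helices;",
      length(x$hairpin_loops), "hairpin,",
      length(x$bulge_loops), "bulge,",
      nrow(x$interior_loops), "interior,",
      length(x$multi_loops), "multibranch loops;",
      x$n_unpaired, "unpaired\n")
  invisible(x)
}

feature_signature <- function(f) {
  il <- f$interior_loops
  il <- t(apply(il, 1, sort))
  if (!nrow(f$interior_loops)) il <- matrix(integer(0), ncol = 2)
  list(
    n_helices = f$n_helices,
    hairpins = sort(f$hairpin_loops),
    bulges = sort(f$bulge_loops),
    interiors = il[order(il[, 1], il[, 2]), , drop = FALSE],
    multis = sort(f$multi_loops)
  )
}

#' Compare two secondary structures
#'
#' Base-pair distance is the size of the symmetric difference of the two
#' pair sets. Two structures have the same shape when their loop-feature
#' multisets agree: helix count, hairpin-loop sizes, bulge sizes,
#' interior-loop size pairs (orientation-insensitive) and multibranch
#' loop sizes.
#'
#' @param a,b `rna_structure` objects over sequences of the same length.
#' @return List with `base_pair_distance` (integer) and `same_shape`
#'   (logical).
#' @export
compare_structures <- function(a, b) {
  stopifnot(inherits(a, "rna_structure"), inherits(b, "rna_structure"))
  if (nchar(a$seq) != nchar(b$seq))
    stop("structures cover sequences of different lengths")
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  ka <- key(a$pairs); kb <- key(b$pairs)
  dist <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  sa <- feature_signature(a$features)
  sb <- feature_signature(b$features)
  list(base_pair_distance = dist, same_shape = isTRUE(all.equal(sa, sb)))
}

#' Maximum complementarity between two interaction sites
#'
#' Slides one site against the reverse of the other (antiparallel
#' register) over every offset, counting aligned positions that can form
#' Watson-Crick (optionally GU wobble) pairs, and returns the maximum.
#' Used for the base-paired contact between expansion segments ES3 and
#' ES6 of the small-subunit rRNA.
#'
#' @param site_a,site_b RNA strings of 4-15 nt (`T` converted to `U`).
#' @param allow_wobble Count GU pairs as complementary (default `TRUE`).
#' @return Integer: maximum number of complementary pairs over all
#'   antiparallel offsets.
#' @examples
#' interaction_pairs("GGGG", "CCCC")  # 4
#' @export
interaction_pairs <- function(site_a, site_b, allow_wobble = TRUE) {
  norm <- function(x) {
    x <- gsub("T", "U", toupper(x), fixed = TRUE)
    if (grepl("[^ACGU]", x)) stop("sites must contain only A, C, G, U")
    if (nchar(x) < 4L || nchar(x) > 15L)
      stop("interaction sites must be 4-15 nt")
    x
  }
  a <- seq_chars(norm(site_a))
  b <- rev(seq_chars(norm(site_b)))  # antiparallel
  na <- length(a); nb <- length(b)
  best <- 0L
  for (off in -(nb - 1L):(na - 1L)) {
    ia <- seq_len(na)
    ib <- ia - off
    keep <- ib >= 1L & ib <= nb
    if (!any(keep)) next
    cnt <- sum(can_pair(a[ia[keep]], b[ib[keep]], wobble = allow_wobble))
    best <- max(best, cnt)
  }
  best
}

#' Fold an annotated segment for every clone and tabulate features
#'
#' Extracts each annotated region from every (reference-projected) clone
#' sequence, folds it, and returns one row per clone and region with the
#' loop-feature counts. Clones with identical segment sequences yield
#' identical structures (the fold is deterministic), so alleles group
#' naturally by structure.
#'
#' @param clones A [clone_set()] on reference coordinates.
#' @param regions Region data frame (`name`, `start`, `end`).
#' @param mode Folding mode passed to [fold_segment()].
#' @param min_loop Minimum hairpin loop size.
#' @return List with `table` (data frame: `region`, `clone_id`,
#'   `segment`, `dot_bracket`, `n_pairs`, `n_helices`, `n_hairpins`,
#'   `n_bulges`, `n_interiors`, `score`) and `structures` (named list of
#'   `rna_structure`, one per distinct region x segment sequence).
#' @export
fold_clone_segments <- function(clones, regions, mode = "stacking",
                                min_loop = 3L) {
  stopifnot(inherits(clones, "clone_set"))
  regions <- validate_regions(regions,
                              ref_length = nchar(clones$clones[[1]]))
  cache <- list()
  rows <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    for (id in names(clones$clones)) {
      seg <- substr(clones$clones[[id]], r$start, r$end)
      seg_rna <- gsub("T", "U", gsub("-", "", seg), fixed = FALSE)
      key <- paste(r$name, seg_rna, sep = "|")
      if (is.null(cache[[key]]))
        cache[[key]] <- fold_segment(seg_rna, min_loop = min_loop,
                                     mode = mode)
      st <- cache[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        region = r$name, clone_id = id, segment = seg_rna,
        dot_bracket = st$dot_bracket, n_pairs = nrow(st$pairs),
        n_helices = st$features$n_helices,
        n_hairpins = length(st$features$hairpin_loops),
        n_bulges = length(st$features$bulge_loops),
        n_interiors = nrow(st$features$interior_loops),
        score = st$score
      )
    }
  }
  list(table = do.call(rbind, rows), structures = cache)
}
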