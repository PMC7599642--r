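# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, exhaustive enumeration) so they
# check the package implementations through a different route.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# global alignment score by plain Needleman-Wunsch (linear gap -2)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- chars(a); B <- chars(b)
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n)
  M[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(M[i, j] + if (A[i] == B[j]) match else mismatch,
                           M[i, j + 1] + gap,
                           M[i + 1, j] + gap)
  }
  M[n + 1, m + 1]
}

# nucleotide diversity by an explicit double loop over pairs and sites
pi_oracle <- function(seqs) {
  mats <- lapply(seqs, chars)
  n <- length(mats)
  acc <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    acc <- c(acc, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(acc)
}

# per-column site classification tally, written independently
site_class_oracle <- function(seqs) {
  mats <- do.call(rbind, lapply(seqs, chars))
  res <- c(invariant = 0L, singleton = 0L, parsimony_informative = 0L)
  for (k in seq_len(ncol(mats))) {
    col <- mats[, k]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    cls <- if (length(tab) < 2) "invariant"
           else if (sum(tab >= 2) >= 2) "parsimony_informative"
           else "singleton"
    res[cls] <- res[cls] + 1L
  }
  res
}

# exhaustive minimum spanning weight via Prufer-sequence enumeration
prufer_decode <- function(code, n) {
  degree <- rep(1L, n)
  for (x in code) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(code)) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, code[k])
    degree[leaf] <- 0L
    degree[code[k]] <- degree[code[k]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

mst_weight_exhaustive <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2, n <= 6)
  if (n == 2) return(d[1, 2])
  codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(codes))) {
    e <- prufer_decode(codes[r, ], n)
    best <- min(best, sum(d[e]))
  }
  best
}

# exhaustive enumeration of all nested structures (list of pair matrices)
enum_structures <- function(pairable, min_loop, i, j) {
  if (i >= j) return(list(matrix(integer(0), ncol = 2)))
  out <- enum_structures(pairable, min_loop, i + 1, j)
  ks <- seq_len(j)
  ks <- ks[ks > i + min_loop & pairable[i, ks]]
  for (k in ks) {
    left <- enum_structures(pairable, min_loop, i + 1, k - 1)
    right <- enum_structures(pairable, min_loop, k + 1, j)
    for (l in left) for (r in right) {
      out[[length(out) + 1]] <- rbind(c(i, k), l, r)
    }
  }
  out
}

structure_score <- function(pairs, mode) {
  np <- nrow(pairs)
  if (mode == "maxpair" || np == 0) return(np)
  key <- paste(pairs[, 1], pairs[, 2])
  stacked <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
  np + stacked
}

max_fold_score_exhaustive <- function(seq, min_loop = 3,
                                      mode = c("maxpair", "stacking")) {
  mode <- match.arg(mode)
  s <- chars(gsub("T", "U", toupper(seq)))
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pairable <- outer(s, s, function(a, b) paste0(a, b) %in% ok)
  structs <- enum_structures(pairable, min_loop, 1, length(s))
  max(vapply(structs, structure_score, numeric(1), mode = mode))
}

# antiparallel complementarity by an index-free sweep (different route
# from the package: pads one site and zips character pairs)
interaction_oracle <- function(a, b, wobble = TRUE) {
  ok <- c("AU", "UA", "GC", "CG")
  if (wobble) ok <- c(ok, "GU", "UG")
  A <- chars(gsub("T", "U", toupper(a)))
  B <- rev(chars(gsub("T", "U", toupper(b))))
  best <- 0
  for (off in seq(-length(B), length(A))) {
    cnt <- 0
    for (p in seq_along(A)) {
      q <- p - off
      if (q >= 1 && q <= length(B) && paste0(A[p], B[q]) %in% ok)
        cnt <- cnt + 1
    }
    best <- max(best, cnt)
  }
  best
}

# build an rna_structure object from a dot-bracket string (for
# structure-comparison tests without invoking the folder)
structure_from_db <- function(seq, db) {
  pairs <- dotbracket_to_pairs(db)
  st <- structure(list(seq = gsub("T", "U", toupper(seq)), pairs = pairs,
                       dot_bracket = db, score = nrow(pairs),
                       mode = "manual", features = NULL),
                  class = "rna_structure")
  st$features <- loop_census(st)
  st
}
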