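# Ribotype collapsing and haplotype-style networks (MST, median-joining).

#' Collapse aligned sequences into ribotypes
#'
#' Sequences identical over mutually valid (unambiguous, ungapped)
#' columns are merged, greedily against the first matching earlier
#' ribotype, so first-seen order defines ribotype identifiers.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Object of class `ribotype_set`: list with `representatives`
#'   (named character vector, ids `R1`, `R2`, ...), `frequency` (named
#'   integer vector) and `members` (list of member sequence names).
#' @examples
#' collapse_ribotypes(c(a = "AA", b = "AA", c = "AT"))
#' @export
collapse_ribotypes <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to collapse")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  mat <- seq_matrix(seqs)
  valid <- matrix(mat %in% DNA_BASES, nrow = nrow(mat))
  rep_idx <- integer(0)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (k in seq_along(rep_idx)) {
      r <- rep_idx[k]
      vv <- valid[i, ] & valid[r, ]
      if (all(mat[i, vv] == mat[r, vv])) { hit <- k; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_idx)
    }
    assign_to[i] <- hit
  }
  ids <- paste0("R", seq_along(rep_idx))
  reps <- seqs[rep_idx]
  names(reps) <- ids
  freq <- as.integer(table(factor(assign_to, levels = seq_along(rep_idx))))
  names(freq) <- ids
  members <- split(names(seqs), factor(assign_to,
                                       levels = seq_along(rep_idx)))
  names(members) <- ids
  structure(list(representatives = reps, frequency = freq,
                 members = members),
            class = "ribotype_set")
}

#' @export
print.ribotype_set <- function(x, ...) {
  cat("Ribotype set:", length(x$representatives), "ribotypes from",
      sum(x$frequency), "sequences\n")
  invisible(x)
}

#' Hamming distance matrix between ribotypes
#'
#' Entry (u, v) counts the columns where both sequences carry a valid
#' base and the bases differ (mutational steps).
#'
#' @param x A `ribotype_set` or a named character vector of equal-length
#'   sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(x) {
  seqs <- if (inherits(x, "ribotype_set")) x$representatives else x
  mat <- seq_matrix(seqs)
  n <- nrow(mat)
  valid <- matrix(mat %in% DNA_BASES, nrow = n)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vv <- valid[i, ] & valid[j, ]
    d[i, j] <- d[j, i] <- sum(mat[i, vv] != mat[j, vv])
  }
  d
}

# Kruskal MST with deterministic tie-break: weight, then the
# lexicographically smaller (id_u, id_v) pair. Returns edge data frame.
kruskal_mst <- function(d) {
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n == 1L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  u <- pmin(ids[idx[, 1]], ids[idx[, 2]])
  v <- pmax(ids[idx[, 1]], ids[idx[, 2]])
  w <- d[idx]
  ord <- order(w, u, v, method = "radix")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- vector("list", n - 1L)
  k <- 0L
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      edges[[k]] <- data.frame(from = u[e], to = v[e], weight = w[e])
      if (k == n - 1L) break
    }
  }
  do.call(rbind, edges[seq_len(k)])
}

# all-pairs minimax path distance (max edge along the best path);
# equals the largest MST edge on the path between two nodes
minimax_distance <- function(d) {
  mm <- d
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      mm[i, ] <- pmin(mm[i, ], pmax(mm[i, k], mm[k, ]))
    }
  }
  mm
}

new_network <- function(nodes, edges, method) {
  structure(list(nodes = nodes, edges = edges, method = method),
            class = "ribonet")
}

#' @export
print.ribonet <- function(x, ...) {
  cat("Haplotype network (", x$method, "): ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "median"), " median), ", nrow(x$edges),
      " edges, total weight ", sum(x$edges$weight), "\n", sep = "")
  invisible(x)
}

#' Minimum spanning tree of a ribotype distance matrix
#'
#' Kruskal's algorithm with a deterministic tie-break (equal-weight edges
#' ordered by the lexicographically smaller node-id pair), so the same
#' matrix always yields the same tree.
#'
#' @param d Symmetric distance matrix with node ids as dimnames (e.g.
#'   from [hamming_matrix()]), or a `ribotype_set`.
#' @param frequencies Optional named frequencies attached to nodes;
#'   taken from the `ribotype_set` automatically.
#' @return Object of class `ribonet` with `nodes` (`id`, `kind`,
#'   `frequency`) and `edges` (`from`, `to`, `weight`); a tree with
#'   exactly `n - 1` edges.
#' @export
minimum_spanning_tree <- function(d, frequencies = NULL) {
  if (inherits(d, "ribotype_set")) {
    frequencies <- frequencies %||% d$frequency
    d <- hamming_matrix(d)
  }
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  freq <- rep(1L, length(ids))
  names(freq) <- ids
  if (!is.null(frequencies)) freq[names(frequencies)] <- frequencies
  nodes <- data.frame(id = ids, kind = "observed",
                      frequency = as.integer(freq[ids]))
  new_network(nodes, kruskal_mst(d), method = "mst")
}

# majority-per-column median of three character vectors; columns where
# all three states differ keep the first node's state (a quasi-median)
triple_median <- function(a, b, c) {
  m <- a
  ab <- a == b
  m[!ab & b == c] <- b[!ab & b == c]
  # a==c handled by keeping a; all-distinct keeps a
  m
}

#' Median-joining network of ribotypes
#'
#' Reconstructs an intragenomic genealogy in the style of median-joining:
#' working on the variable columns only, consensus ("median") vectors of
#' node triples linked in the epsilon-relaxed minimum spanning network
#' are added whenever they reduce the total spanning-tree length, then
#' median nodes that no longer shorten the network are pruned. The final
#' graph contains every edge belonging to some minimum spanning tree
#' (within `epsilon`), so it is connected and contains an MST of the
#' observed plus median nodes. With every observed sequence one step from
#' a single central sequence the output is a star centred on it.
#'
#' @param x A `ribotype_set` or named character vector of equal-length
#'   aligned sequences.
#' @param epsilon Non-negative integer relaxation of the minimum spanning
#'   network (0 = parsimony-strict, the default).
#' @param max_iter Cap on median-addition rounds; exceeded means
#'   non-convergence and raises an error.
#' @return Object of class `ribonet`; median nodes have `kind =
#'   "median"` and frequency 0. The attribute `"sequences"` carries full
#'   sequences for all nodes (medians reconstructed by filling invariant
#'   columns).
#' @export
median_joining_network <- function(x, epsilon = 0L, max_iter = NULL) {
  if (epsilon < 0) stop("epsilon must be a non-negative integer")
  rset <- if (inherits(x, "ribotype_set")) x else collapse_ribotypes(x)
  reps <- rset$representatives
  if (length(reps) < 2L)
    stop("need at least 2 ribotypes")
  full <- seq_matrix(reps)
  # characters: variable columns only (invariant columns carry no signal)
  is_var <- apply(full, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    length(unique(col)) >= 2L
  })
  var_cols <- which(is_var)
  X <- full[, var_cols, drop = FALSE]
  ids <- names(reps)
  kind <- rep("observed", nrow(X))
  max_iter <- max_iter %||% (10L * nrow(X) + 100L)

  ham <- function(M) {
    n <- nrow(M)
    d <- matrix(0L, n, n)
    if (n >= 2L) {
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        d[i, j] <- d[j, i] <- sum(M[i, ] != M[j, ])
    }
    d
  }
  mst_len <- function(d) {
    dimnames(d) <- list(sprintf("n%04d", seq_len(nrow(d))),
                        sprintf("n%04d", seq_len(nrow(d))))
    sum(kruskal_mst(d)$weight)
  }

  n_median <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("median-joining did not converge within ", max_iter,
           " rounds (", nrow(X), " nodes); raise max_iter or epsilon")
    d <- ham(X)
    mm <- minimax_distance(d)
    linked <- d <= mm + epsilon
    diag(linked) <- FALSE
    cur_len <- mst_len(d)
    n <- nrow(X)
    # candidate medians from triples with >= 2 feasible links
    cand <- character(0)
    if (n >= 3L) {
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        nlinks <- linked[i, j] + linked[i, k] + linked[j, k]
        if (nlinks >= 2L) {
          m <- triple_median(X[i, ], X[j, ], X[k, ])
          cand <- c(cand, chars_seq(m))
        }
      }
    }
    cand <- setdiff(unique(cand), apply(X, 1, chars_seq))
    if (!length(cand)) break
    best_gain <- 0L
    best <- NULL
    for (s in sort(cand)) {  # lexicographic order fixes ties
      Xs <- rbind(X, seq_chars(s))
      gain <- cur_len - mst_len(ham(Xs))
      if (gain > best_gain) { best_gain <- gain; best <- s }
    }
    if (is.null(best)) break
    X <- rbind(X, seq_chars(best))
    n_median <- n_median + 1L
    ids <- c(ids, paste0("MV", n_median))
    kind <- c(kind, "median")
  }

  # prune medians whose removal leaves the spanning length unchanged
  repeat {
    d <- ham(X)
    cur_len <- mst_len(d)
    dropped <- FALSE
    for (i in rev(which(kind == "median"))) {
      if (mst_len(d[-i, -i, drop = FALSE]) <= cur_len) {
        X <- X[-i, , drop = FALSE]
        ids <- ids[-i]
        kind <- kind[-i]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  d <- ham(X)
  dimnames(d) <- list(ids, ids)
  mm <- minimax_distance(d)
  keep <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  edges <- data.frame(
    from = pmin(ids[keep[, 1]], ids[keep[, 2]]),
    to = pmax(ids[keep[, 1]], ids[keep[, 2]]),
    weight = d[keep]
  )
  edges <- edges[order(edges$weight, edges$from, edges$to), ]
  rownames(edges) <- NULL
  freq <- ifelse(kind == "observed", rset$frequency[ids], 0L)
  nodes <- data.frame(id = ids, kind = kind,
                      frequency = as.integer(ifelse(is.na(freq), 0L, freq)))
  net <- new_network(nodes, edges, method = "median_joining")
  # reconstruct full sequences for all nodes (medians differ from the
  # first observed sequence only at variable columns)
  seqs_full <- apply(full, 1, chars_seq)
  med_rows <- which(kind == "median")
  if (length(med_rows)) {
    template <- full[1, ]
    for (i in med_rows) {
      s <- template
      s[var_cols] <- X[i, ]
      seqs_full <- c(seqs_full, chars_seq(s))
    }
  }
  names(seqs_full) <- c(names(reps), ids[med_rows])
  attr(net, "sequences") <- seqs_full[ids]
  net
}

#' Convert a network to an igraph object
#'
#' @param net A `ribonet`.
#' @return An undirected `igraph` graph with node attributes `kind` and
#'   `frequency` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ribonet"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network as GraphML or a TSV edge list
#'
#' @param net A `ribonet`.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
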