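test_that("folding matches hand-checkable cases", {
  st <- fold_segment("GGGAAACCC", mode = "maxpair")
  expect_equal(st$dot_bracket, "(((...)))")
  expect_equal(nrow(st$pairs), 3L)
  expect_equal(fold_segment("AAAA")$dot_bracket, "....")
  # A-U separated by two bases cannot close a 3-nt loop
  expect_equal(fold_segment("ACGU", min_loop = 3)$dot_bracket, "....")
  expect_error(fold_segment("ACGX"), "only A, C, G, U")
  expect_error(fold_segment("ACG"), "length")
  # T input is treated as U
  expect_identical(fold_segment("GGGAAATTT")$dot_bracket,
                   fold_segment("GGGAAAUUU")$dot_bracket)
})

test_that("maxpair and stacking scores equal exhaustive enumeration", {
  withr::local_seed(61)
  for (k in 1:25) {
    n <- sample(6:13, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    expect_equal(fold_segment(s, mode = "maxpair")$score,
                 max_fold_score_exhaustive(s, mode = "maxpair"),
                 info = s)
    expect_equal(fold_segment(s, mode = "stacking")$score,
                 max_fold_score_exhaustive(s, mode = "stacking"),
                 info = s)
  }
  # a couple at the full oracle size
  for (s in c("GGGGAAAACCCCAA", "GCGCAAAAGCGCAU")) {
    expect_equal(fold_segment(s, mode = "maxpair")$score,
                 max_fold_score_exhaustive(s, mode = "maxpair"))
  }
})

test_that("dot-bracket and pair-list representations are interconvertible", {
  withr::local_seed(62)
  for (k in 1:10) {
    n <- sample(10:40, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    st <- fold_segment(s)
    expect_equal(dotbracket_to_pairs(st$dot_bracket),
                 st$pairs, ignore_attr = TRUE)
    expect_equal(pairs_to_dotbracket(st$pairs, n), st$dot_bracket)
  }
  expect_error(dotbracket_to_pairs("(()"), "unbalanced")
})

test_that("loop census resolves hairpins, bulges and interior loops", {
  f1 <- loop_census(dotbracket_to_pairs("(((...)))"), n = 9)
  expect_equal(f1$n_helices, 1L)
  expect_equal(f1$hairpin_loops, 3L)
  expect_equal(length(f1$bulge_loops), 0L)
  expect_equal(nrow(f1$interior_loops), 0L)

  f2 <- loop_census(dotbracket_to_pairs("((.((...))))"), n = 12)
  expect_equal(f2$n_helices, 2L)
  expect_equal(f2$hairpin_loops, 3L)
  expect_equal(f2$bulge_loops, 1L)

  f3 <- loop_census(dotbracket_to_pairs("((.((...)).))"), n = 13)
  expect_equal(f3$interior_loops, cbind(size5 = 1L, size3 = 1L),
               ignore_attr = TRUE)

  # crossing pairs are rejected
  expect_error(loop_census(rbind(c(1, 6), c(3, 9)), n = 10), "crossing")
})

test_that("every base is attributed to pairs, loops or the exterior", {
  withr::local_seed(63)
  for (k in 1:15) {
    n <- sample(12:60, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    st <- fold_segment(s)
    f <- st$features
    attributed <- sum(f$hairpin_loops) + sum(f$bulge_loops) +
      sum(f$interior_loops) + sum(f$multi_loops) + f$exterior_unpaired
    expect_equal(2 * nrow(st$pairs) + attributed, n)
    expect_equal(f$n_unpaired, n - 2 * nrow(st$pairs))
  }
})

test_that("structure comparison measures pair distance and shape identity", {
  a <- structure_from_db("GGGAAACCC", "(((...)))")
  expect_equal(compare_structures(a, a),
               list(base_pair_distance = 0L, same_shape = TRUE))
  b <- structure_from_db("GGGAAACCC", ".((...)).")
  cmp <- compare_structures(a, b)
  expect_equal(cmp$base_pair_distance, 1L)   # outermost pair lost
  c2 <- structure_from_db("GGGGAAAACCCC", "((((....))))")
  c4 <- structure_from_db("GGGGAAAACCCC", "(((.(...))))")
  # moving one pair: one pair out, one pair in
  expect_equal(compare_structures(c2, c4)$base_pair_distance, 2L)
  expect_false(compare_structures(c2, c4)$same_shape)  # bulge appears
  expect_error(compare_structures(a, structure_from_db("GGAACC",
                                                       "((..))")),
               "different length")

  withr::local_seed(64)
  for (k in 1:10) {
    n <- sample(12:30, 1)
    s1 <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                collapse = "")
    x <- fold_segment(s1); y <- fold_segment(s2)
    key <- function(p) paste(p[, 1], p[, 2])
    want <- length(setdiff(key(x$pairs), key(y$pairs))) +
      length(setdiff(key(y$pairs), key(x$pairs)))
    expect_equal(compare_structures(x, y)$base_pair_distance, want)
  }
})

test_that("intersegment complementarity is maximal over antiparallel offsets", {
  expect_equal(interaction_pairs("GGGG", "CCCC"), 4L)
  expect_equal(interaction_pairs("AAAAA", "AAAAA", allow_wobble = FALSE), 0L)
  # ES6 interaction site against the ES3 consensus: seven pairs
  expect_equal(interaction_pairs("GUUGGCCUU", "AAAACCAAU"), 7L)
  expect_equal(interaction_pairs("GUUGGCCUU", "AAAACCAAU"),
               interaction_oracle("GUUGGCCUU", "AAAACCAAU"))
  withr::local_seed(65)
  for (k in 1:10) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(5:10, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(5:10, 1),
                      replace = TRUE), collapse = "")
    for (w in c(TRUE, FALSE)) {
      expect_equal(interaction_pairs(a, b, allow_wobble = w),
                   interaction_oracle(a, b, wobble = w))
    }
  }
})

test_that("alleles with identical segments always fold identically", {
  sim <- simulate_line("1o", seed = 66)
  regions <- sim$regions[sim$regions$name %in% c("h8", "h33"), ]
  res <- fold_clone_segments(sim$clones, regions)
  by_seg <- split(res$table$dot_bracket,
                  paste(res$table$region, res$table$segment))
  for (g in by_seg) expect_length(unique(g), 1L)
})
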