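test_that("directed substitutions classify by transition / Met / Am rules", {
  # C>T: transition and methylation footprint; T>C: transition and
  # amination (reference T replaced); A>T: plain transversion
  expect_equal(classify_substitution("C", "T"),
               data.frame(is_transition = TRUE, is_methylation = TRUE,
                          is_amination = FALSE))
  expect_equal(classify_substitution("T", "C"),
               data.frame(is_transition = TRUE, is_methylation = FALSE,
                          is_amination = TRUE))
  expect_equal(classify_substitution("A", "T"),
               data.frame(is_transition = FALSE, is_methylation = FALSE,
                          is_amination = FALSE))
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A, C, G, T")
})

test_that("classification is a partition: one directed type per call, Met and Am disjoint", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  cl <- classify_substitution(grid$ref, grid$alt)
  expect_equal(nrow(cl), 12L)
  expect_equal(sum(cl$is_transition), 4L)
  expect_equal(sum(cl$is_methylation), 2L)
  expect_equal(sum(cl$is_amination), 3L)
  expect_false(any(cl$is_methylation & cl$is_amination))
})

test_that("substitution calling skips gap and ambiguous columns", {
  expect_equal(nrow(call_substitutions("ACGT", "ACGT")), 0L)
  s <- call_substitutions("ATGT", "ACGT", clone_id = "c1")
  expect_equal(s$pos, 2L)
  expect_equal(s$type, "C>T")
  expect_equal(nrow(call_substitutions("A-GT", "ACGT")), 0L)
  expect_equal(nrow(call_substitutions("ANGT", "ACGT")), 0L)
  # positions stay in ungapped reference coordinates across ref gaps
  s <- call_substitutions("AAGTT", "AC-TG")
  expect_equal(s$pos, c(2L, 4L))
  expect_error(call_substitutions("ACG", "ACGT"), "equal length")
})

test_that("spectrum summary equals an independent recount on planted data", {
  sim <- simulate_line("1s", seed = 41)
  subs <- call_substitutions_set(sim$clones, sim$ref)
  sp <- summarize_spectrum(sim$clones, subs)

  # brute-force recount straight from the sequences
  refc <- chars(sim$ref$seq)
  types <- c()
  for (id in names(sim$clones$clones)) {
    cc <- chars(sim$clones$clones[[id]])
    d <- which(cc != refc)
    types <- c(types, paste0(refc[d], ">", cc[d]))
  }
  tab <- table(types)
  expect_equal(sp$total, length(types))
  for (tp in names(tab)) expect_equal(unname(sp$counts[tp]),
                                      unname(as.integer(tab[tp])))
  expect_equal(sp$ts + sp$tv, sp$total)
  expect_equal(sp$met_count,
               sum(types %in% c("C>T", "G>A")))
  expect_equal(sp$am_count,
               sum(types %in% c("T>A", "T>C", "T>G")))
  expect_equal(sp$per_gene_all * sp$n_clones, sp$total)
  # disjointness: Met + Am + other == total
  other <- sp$total - sp$met_count - sp$am_count
  expect_gte(other, 0)
})

test_that("a clone set with zero substitutions gives a degenerate spectrum", {
  ref <- generate_reference(length = 400, seed = 5)
  params <- synthetic_params(n_clones = 6, gene_length = 400,
                             lambda_subs = 0, seed = 6)
  sim <- generate_clone_set(ref, params)
  subs <- call_substitutions_set(sim$clones, ref)
  sp <- summarize_spectrum(sim$clones, subs)
  expect_equal(sp$total, 0L)
  expect_true(is.infinite(sp$ts_tv))  # undefined sentinel
  expect_equal(sp$per_gene_all, 0)
  expect_equal(sp$per_gene_met, 0)
  expect_equal(sp$per_gene_am, 0)
})

test_that("per-clone histogram bins partition the clone counts", {
  cs <- clone_set("x", c(a = "AAAA", b = "AAAA", c = "AAAA",
                         d = "AAAA", e = "AAAA"))
  subs <- data.frame(clone_id = c("c", "d", "d", "e", "e", "e"))
  h <- per_clone_histogram(subs, cs)
  expect_equal(unname(h$counts),
               c(2L, 2L, 1L, 0L, 0L, 0L))  # 0:2, 1-2:2, 3-4:1
  expect_equal(sum(h$counts), cs$n)

  # all clones beyond 10 changes land in the open top bin
  subs2 <- data.frame(clone_id = rep(letters[1:5], each = 12))
  h2 <- per_clone_histogram(subs2, cs)
  expect_equal(unname(h2$counts[">10"]), 5L)

  # conservation on random synthetic counts
  withr::local_seed(9)
  for (k in 1:5) {
    n <- sample(5:30, 1)
    cs3 <- clone_set("r", setNames(rep("ACGT", n), paste0("c", 1:n)))
    cnt <- rpois(n, 3)
    subs3 <- data.frame(clone_id = rep(paste0("c", 1:n), cnt))
    expect_equal(sum(per_clone_histogram(subs3, cs3)$counts), n)
  }
})

test_that("planted type frequencies are recovered within sampling error", {
  # large synthetic set: estimated transition share ~ expected share
  ref <- generate_reference(length = 1809, seed = 21)
  params <- synthetic_params(n_clones = 200, lambda_subs = 8,
                             ts_bias = 4, seed = 22)
  sim <- generate_clone_set(ref, params)
  sp <- summarize_spectrum(sim$clones,
                           call_substitutions_set(sim$clones, ref))
  # expected transition probability given uniform-ish base content:
  # kappa / (kappa + 2) per site
  p_exp <- 4 / 6
  p_hat <- sp$ts / sp$total
  se <- sqrt(p_exp * (1 - p_exp) / sp$total)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})
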