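test_that("nucleotide diversity matches closed forms and the pair oracle", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT")), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "T")
  expect_equal(nucleotide_diversity(c(a, b)), 0.01)
  expect_error(nucleotide_diversity("ACGT"), "at least 2")

  withr::local_seed(31)
  for (k in 1:5) {
    seqs <- vapply(1:5, function(i) random_dna(50), character(1))
    expect_equal(nucleotide_diversity(seqs), pi_oracle(seqs))
  }
})

test_that("global pi equals the column-wise oracle on gap-free data", {
  withr::local_seed(32)
  seqs <- vapply(1:8, function(i) random_dna(60), character(1))
  # column-wise: mean over columns of pairwise-difference proportion
  mats <- do.call(rbind, lapply(seqs, chars))
  npair <- choose(8, 2)
  colprop <- apply(mats, 2, function(col) {
    tab <- table(col)
    (npair - sum(choose(tab, 2))) / npair
  })
  expect_equal(nucleotide_diversity(seqs), mean(colprop), tolerance = 1e-12)
})

test_that("adding a duplicate sequence never increases pi", {
  withr::local_seed(33)
  for (k in 1:10) {
    seqs <- vapply(1:4, function(i) random_dna(40), character(1))
    pi0 <- nucleotide_diversity(seqs)
    pi1 <- nucleotide_diversity(c(seqs, seqs[sample(4, 1)]))
    expect_lte(pi1, pi0 + 1e-12)
  }
})

test_that("sliding windows follow the start rule and local recomputation", {
  sim <- simulate_line("1o", seed = 34)
  prof <- sliding_window_pi(sim$clones$clones)
  # 1809 sites, window 100, step 25: 69 windows, last start 1701
  expect_equal(nrow(prof$windows), 69L)
  expect_equal(prof$windows$start[1], 1L)
  expect_equal(prof$windows$start[69], 1701L)
  expect_true(all(prof$windows$pi >= 0 & prof$windows$pi <= 1))
  # each window's pi equals global pi of the window slice alone
  for (w in c(1, 20, 69)) {
    s <- prof$windows$start[w]
    slice <- substring(sim$clones$clones, s, s + 99)
    expect_equal(prof$windows$pi[w], nucleotide_diversity(slice))
  }
  expect_error(sliding_window_pi(sim$clones$clones, window_len = 1),
               "at least 2")
})

test_that("an all-identical alignment is flat and a lone variant is local", {
  seqs <- rep(strrep("ACGT", 100), 5)
  prof <- sliding_window_pi(seqs)
  expect_true(all(prof$windows$pi == 0))

  ch <- chars(seqs[1])
  ch[150] <- "T"
  seqs2 <- c(paste(ch, collapse = ""), seqs[-1])
  prof2 <- sliding_window_pi(seqs2)
  covers <- prof2$windows$start <= 150 & prof2$windows$end >= 150
  expect_true(all(prof2$windows$pi[covers] > 0))
  expect_true(all(prof2$windows$pi[!covers] == 0))
})

test_that("site classification matches hand cases and the recount oracle", {
  expect_equal(classify_sites(c("A", "A", "A", "G"))$classes, "singleton")
  expect_equal(classify_sites(c("A", "A", "G", "G"))$classes,
               "parsimony_informative")
  cl <- classify_sites(c("ACGT", "ACGT", "ACGT"))
  expect_equal(unname(cl$counts["variable"]), 0L)

  withr::local_seed(35)
  for (k in 1:5) {
    seqs <- vapply(1:6, function(i) random_dna(80), character(1))
    got <- classify_sites(seqs)$counts
    want <- site_class_oracle(seqs)
    expect_equal(got[names(want)], want)
    expect_equal(unname(got["variable"]),
                 unname(want["singleton"] + want["parsimony_informative"]))
  }
})

test_that("pairwise distances follow closed forms and the exhaustive loop", {
  d0 <- pairwise_distances(c("ACGT", "ACGT"))
  expect_equal(d0$mean_D, 0)
  expect_equal(d0$mean_K, 0)

  a <- strrep("A", 1809)
  ch <- chars(a); ch[c(3, 700, 1200, 1805)] <- "G"
  d1 <- pairwise_distances(c(a, paste(ch, collapse = "")))
  expect_equal(d1$mean_K, 4)
  expect_equal(d1$mean_D, 4 / 1809, tolerance = 1e-12)

  withr::local_seed(36)
  seqs <- vapply(1:6, function(i) random_dna(70), character(1))
  ds <- pairwise_distances(seqs)
  expect_true(isSymmetric(ds$D))
  expect_true(all(diag(ds$D) == 0))
  acc_d <- acc_k <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    k <- sum(chars(seqs[i]) != chars(seqs[j]))
    acc_k <- c(acc_k, k)
    acc_d <- c(acc_d, k / 70)
    expect_equal(ds$K[i, j], k)
  }
  expect_equal(ds$mean_D, mean(acc_d))
  expect_equal(ds$mean_K, mean(acc_k))
  # K == D * site count in the gap-free case
  expect_equal(ds$K, ds$D * 70)
})

test_that("region hotspot tables count by region and recover a planted hotspot", {
  ref <- generate_reference(length = 1809, seed = 37)
  regions <- default_regions(1809)
  hot <- regions[regions$name == "h8", ]
  hot$multiplier <- 10
  params <- synthetic_params(n_clones = 30, lambda_subs = 4,
                             hotspot_regions = hot, seed = 38)
  sim <- generate_clone_set(ref, params)
  subs <- call_substitutions_set(sim$clones, ref)
  prof <- sliding_window_pi(sim$clones$clones)
  tab <- region_hotspots(prof, regions, subs)
  expect_equal(tab$region[which.max(tab$n_subs)], "h8")
  expect_equal(sum(tab$n_subs[tab$region == "h8"]),
               sum(subs$pos >= hot$start & subs$pos <= hot$end))
  # class filters restrict the counted calls
  tmet <- region_hotspots(prof, regions, subs, class_filter = "methylation")
  expect_true(all(tmet$n_subs <= tab$n_subs))
  expect_error(region_hotspots(prof, regions, subs, class_filter = "x"))
})
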