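# Synthetic clone sets, cytogenetic tables and region files with the
# statistical structure the analysis assumes: mostly-singleton
# substitutions, transition bias, methylation-context enrichment,
# hotspot windows, and star or two-level genealogies.

#' Parameters for synthetic clone-set generation
#'
#' @param n_clones Number of cloned gene copies to simulate.
#' @param gene_length Gene length in nt (default 1809).
#' @param lambda_subs Mean substitutions per clone (Poisson).
#' @param ts_bias Relative weight of the transition alternative at each
#'   site (kappa; transversions have weight 1).
#' @param met_multiplier Extra rate multiplier applied to the
#'   methylation-footprint changes C>T and G>A.
#' @param hotspot_regions Optional data frame `name`, `start`, `end`,
#'   `multiplier` (> 0): positional rate multipliers.
#' @param genealogy `"star"` (every clone derived independently from the
#'   reference) or `"two_level"` (clones derive from a small set of
#'   sub-founders which carry half the expected substitutions).
#' @param duplicate_fraction Proportion of clones that exactly copy an
#'   already-generated clone (models shared ribotypes); in `[0, 1)`.
#' @param line_id Identifier stamped on the generated clone set.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a caller can drive several generators from one seed).
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_clones, gene_length = 1809L, lambda_subs = 2,
                             ts_bias = 4, met_multiplier = 1,
                             hotspot_regions = NULL,
                             genealogy = c("star", "two_level"),
                             duplicate_fraction = 0, line_id = "sim",
                             seed = NULL) {
  genealogy <- match.arg(genealogy)
  stopifnot(n_clones >= 1L, gene_length >= 200L, lambda_subs >= 0,
            ts_bias > 0, met_multiplier > 0,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  if (!is.null(hotspot_regions)) {
    stopifnot(all(c("name", "start", "end", "multiplier") %in%
                    names(hotspot_regions)))
    if (any(hotspot_regions$multiplier <= 0))
      stop("hotspot multipliers must be positive")
    if (any(hotspot_regions$end > gene_length) ||
        any(hotspot_regions$start < 1L))
      stop("hotspot region outside the gene")
  }
  structure(list(n_clones = as.integer(n_clones),
                 gene_length = as.integer(gene_length),
                 lambda_subs = lambda_subs, ts_bias = ts_bias,
                 met_multiplier = met_multiplier,
                 hotspot_regions = hotspot_regions,
                 genealogy = genealogy,
                 duplicate_fraction = duplicate_fraction,
                 line_id = line_id, seed = seed),
            class = "synthetic_params")
}

#' Generate a random reference gene with a target G+C content
#'
#' The number of G+C positions is fixed at `round(length * gc_target /
#' 100)` and their placement randomised, so the realised G+C content is
#' always within 1% of the target. Deterministic for a fixed seed.
#'
#' @param length Gene length (>= 200 nt).
#' @param gc_target Target G+C percentage (0-100; default 49.3, typical
#'   of plant 18S rDNA).
#' @param seed Optional seed.
#' @return A [reference_gene()] with id `"synthetic_ref"`.
#' @export
generate_reference <- function(length = 1809L, gc_target = 49.3,
                               seed = NULL) {
  if (length < 200L) stop("reference length must be at least 200")
  if (gc_target < 0 || gc_target > 100)
    stop("unreachable GC target: ", gc_target)
  with_seed(seed, {
    n_gc <- round(length * gc_target / 100)
    ch <- c(sample(c("G", "C"), n_gc, replace = TRUE),
            sample(c("A", "T"), length - n_gc, replace = TRUE))
    reference_gene("synthetic_ref", chars_seq(sample(ch)))
  })
}

# transition partner of each base
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# per-(position, alternative) sampling weights implied by the parameters
event_weights <- function(ref_chars, params) {
  L <- length(ref_chars)
  hot <- rep(1, L)
  hr <- params$hotspot_regions
  if (!is.null(hr)) {
    for (k in seq_len(nrow(hr)))
      hot[hr$start[k]:hr$end[k]] <- hot[hr$start[k]:hr$end[k]] *
        hr$multiplier[k]
  }
  alts <- matrix("", L, 3L)
  w <- matrix(0, L, 3L)
  for (p in seq_len(L)) {
    b <- ref_chars[p]
    a <- setdiff(DNA_BASES, b)
    alts[p, ] <- a
    wk <- ifelse(a == TS_PARTNER[b], params$ts_bias, 1)
    met <- (b == "C" & a == "T") | (b == "G" & a == "A")
    w[p, ] <- hot[p] * wk * ifelse(met, params$met_multiplier, 1)
  }
  list(alts = alts, w = as.vector(w) / sum(w))
}

# draw k substitution events; returns data.frame(pos, alt) with site
# collisions resolved by keeping the last draw
draw_events <- function(k, ew, L) {
  if (k == 0L) return(data.frame(pos = integer(0), alt = character(0)))
  idx <- sample.int(L * 3L, k, replace = TRUE, prob = ew$w)
  pos <- ((idx - 1L) %% L) + 1L
  alt <- ew$alts[cbind(pos, ((idx - 1L) %/% L) + 1L)]
  keep <- !duplicated(pos, fromLast = TRUE)
  data.frame(pos = pos[keep], alt = alt[keep])
}

#' Generate a synthetic clone set with planted substitutions
#'
#' Per clone, the substitution count is Poisson(`lambda_subs`); event
#' positions and alternative bases are drawn with probability
#' proportional to hotspot multiplier x transition bias x methylation
#' multiplier (for C>T / G>A draws). Under the `"two_level"` genealogy,
#' sub-founders (about `sqrt(n_clones)` of them) first receive half the
#' expected substitutions and each clone then adds its own half on top
#' of a randomly chosen sub-founder. A `duplicate_fraction` of clones
#' are exact copies of earlier clones. Two draws hitting the same site
#' in one clone keep the last draw, and the returned ground truth lists
#' the resolved (observed) events, so calling substitutions on the
#' generated clones recovers the truth list exactly.
#'
#' @param ref A [reference_gene()] (its length must match
#'   `params$gene_length`).
#' @param params A [synthetic_params()] object.
#' @return List with `clones` (a [clone_set()], sequences gap-free on
#'   reference coordinates) and `truth` (data frame `clone_id`, `pos`,
#'   `ref`, `alt`, `type` of every planted event).
#' @export
generate_clone_set <- function(ref, params) {
  stopifnot(inherits(ref, "reference_gene"),
            inherits(params, "synthetic_params"))
  if (ref$length != params$gene_length)
    stop("reference length does not match params$gene_length")
  with_seed(params$seed, {
    rc <- seq_chars(ref$seq)
    L <- ref$length
    ew <- event_weights(rc, params)
    n <- params$n_clones
    n_dup <- floor(params$duplicate_fraction * n)
    n_new <- n - n_dup
    half <- params$genealogy == "two_level"
    founders <- NULL
    if (half) {
      n_f <- max(2L, ceiling(sqrt(n_new)))
      founders <- lapply(seq_len(n_f), function(i)
        draw_events(stats::rpois(1L, params$lambda_subs / 2), ew, L))
    }
    ids <- sprintf("%s_c%02d", params$line_id, seq_len(n))
    events <- vector("list", n)
    for (i in seq_len(n_new)) {
      own_lambda <- if (half) params$lambda_subs / 2 else params$lambda_subs
      ev <- draw_events(stats::rpois(1L, own_lambda), ew, L)
      if (half) {
        f <- founders[[sample.int(length(founders), 1L)]]
        ev <- rbind(f, ev)
        ev <- ev[!duplicated(ev$pos, fromLast = TRUE), , drop = FALSE]
      }
      events[[i]] <- ev
    }
    if (n_dup > 0L) {
      for (i in n_new + seq_len(n_dup))
        events[[i]] <- events[[sample.int(n_new, 1L)]]
    }
    seqs <- vapply(events, function(ev) {
      s <- rc
      if (nrow(ev)) s[ev$pos] <- ev$alt
      chars_seq(s)
    }, character(1))
    names(seqs) <- ids
    truth <- do.call(rbind, lapply(seq_len(n), function(i) {
      ev <- events[[i]]
      if (!nrow(ev)) return(NULL)
      ev <- ev[order(ev$pos), , drop = FALSE]
      data.frame(clone_id = ids[i], pos = ev$pos, ref = rc[ev$pos],
                 alt = ev$alt, type = paste0(rc[ev$pos], ">", ev$alt))
    }))
    if (is.null(truth))
      truth <- data.frame(clone_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          type = character(0))
    rownames(truth) <- NULL
    list(clones = clone_set(params$line_id, seqs), truth = truth)
  })
}

#' Generate a synthetic cytogenetic table
#'
#' Chromosome counts per cell are negative-binomial (mean `chr_mean`,
#' dispersion `chr_dispersion`), truncated into `[1, 300]`; macro and
#' micro nucleoli per nucleus are Poisson with the planted means.
#'
#' @param line_id Line identifier.
#' @param n_cells Number of metaphase cells.
#' @param chr_mean,chr_dispersion Negative-binomial mean and size for
#'   chromosome counts.
#' @param n_nuclei Number of interphase nuclei.
#' @param macro_mean,micro_mean Poisson means for macro and micro
#'   nucleoli per nucleus.
#' @param seed Optional seed.
#' @return List with `chromosomes` (data frame `line_id`, `cell_id`,
#'   `chromosome_count`) and `nucleoli` (data frame `line_id`,
#'   `nucleus_id`, `macro`, `micro`).
#' @export
generate_cyto_table <- function(line_id = "sim", n_cells = 100L,
                                chr_mean = 50, chr_dispersion = 8,
                                n_nuclei = 150L, macro_mean = 5,
                                micro_mean = 4, seed = NULL) {
  stopifnot(n_cells >= 1L, n_nuclei >= 1L)
  with_seed(seed, {
    chr <- pmin(pmax(stats::rnbinom(n_cells, mu = chr_mean,
                                    size = chr_dispersion), 1L), 300L)
    list(
      chromosomes = data.frame(line_id = line_id,
                               cell_id = sprintf("cell%03d",
                                                 seq_len(n_cells)),
                               chromosome_count = chr),
      nucleoli = data.frame(line_id = line_id,
                            nucleus_id = sprintf("nuc%03d",
                                                 seq_len(n_nuclei)),
                            macro = stats::rpois(n_nuclei, macro_mean),
                            micro = stats::rpois(n_nuclei, micro_mean))
    )
  })
}

#' Synthetic annotation of 18S variable regions
#'
#' A diagrammatic layout of the expansion segment ES3b-c and seven
#' hairpins on a gene of `gene_length` nt: coordinates are this
#' package's synthetic stand-in (scaled from a 1809-nt gene), since real
#' region coordinates must come from a structure-informed annotation
#' supplied by the user.
#'
#' @param gene_length Gene length the layout is scaled to (default 1809).
#' @return Region data frame (`name`, `start`, `end`).
#' @export
default_regions <- function(gene_length = 1809L) {
  base <- data.frame(
    name = c("h6", "ES3b-c", "h7", "h8", "h17", "h18", "h27", "h33"),
    start = c(90L, 150L, 300L, 365L, 480L, 590L, 1120L, 1380L),
    end = c(140L, 260L, 355L, 430L, 560L, 640L, 1175L, 1450L)
  )
  sc <- gene_length / 1809
  base$start <- pmax(1L, as.integer(round(base$start * sc)))
  base$end <- pmin(gene_length, as.integer(round(base$end * sc)))
  validate_regions(base, ref_length = gene_length)
}

#' Preset generator parameters emulating the three studied cell lines
#'
#' Presets reproduce the qualitative per-line structure reported for
#' cultivated ginseng 18S rDNA clone sets: a young stem line (`"9s"`,
#' n = 20, about 2 substitutions per clone, strong transition bias, a
#' single ES3 hotspot, star genealogy, one duplicated ribotype), an old
#' stem line (`"1s"`, n = 46, about 5.2 substitutions per clone, weaker
#' transition bias, methylation-context enrichment, hotspots in h7, h8
#' and h17, a two-level genealogy) and an old ovary line (`"1o"`,
#' n = 46, about 3.3 substitutions per clone, hotspot in h33).
#'
#' @param line One of `"9s"`, `"1s"`, `"1o"`.
#' @param gene_length Gene length (default 1809).
#' @param seed Optional seed stored in the params.
#' @return A [synthetic_params()] object.
#' @export
preset_params <- function(line = c("9s", "1s", "1o"),
                          gene_length = 1809L, seed = NULL) {
  line <- match.arg(line)
  reg <- default_regions(gene_length)
  hot <- function(names, mult) {
    r <- reg[reg$name %in% names, ]
    r$multiplier <- mult
    r
  }
  switch(line,
    "9s" = synthetic_params(n_clones = 20L, gene_length = gene_length,
                            lambda_subs = 2.05, ts_bias = 25,
                            met_multiplier = 0.33,
                            hotspot_regions = hot("ES3b-c", 8),
                            genealogy = "star",
                            duplicate_fraction = 0.05,
                            line_id = "9s", seed = seed),
    "1s" = synthetic_params(n_clones = 46L, gene_length = gene_length,
                            lambda_subs = 5.2, ts_bias = 4,
                            met_multiplier = 0.96,
                            hotspot_regions = hot(c("h7", "h8", "h17"), 6),
                            genealogy = "two_level",
                            line_id = "1s", seed = seed),
    "1o" = synthetic_params(n_clones = 46L, gene_length = gene_length,
                            lambda_subs = 3.3, ts_bias = 9,
                            met_multiplier = 0.75,
                            hotspot_regions = hot("h33", 10),
                            genealogy = "star",
                            line_id = "1o", seed = seed)
  )
}

#' Simulate one cell line and write its files
#'
#' Generates a reference, a preset clone set and the region annotation,
#' and writes `ref.fa`, `clones.fa`, `regions.tsv` and `truth.tsv` to
#' `out_dir`. All randomness flows from `seed`.
#'
#' @param line Preset name (see [preset_params()]).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return List with `ref`, `clones`, `truth`, `regions` and `paths`.
#' @export
simulate_line <- function(line = "9s", seed = 1L, out_dir = NULL) {
  with_seed(seed, {
    ref <- generate_reference(seed = NULL)
    params <- preset_params(line, seed = NULL)
    sim <- generate_clone_set(ref, params)
    regions <- default_regions(ref$length)
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(
        ref = write_fasta(c(synthetic_ref = ref$seq),
                          file.path(out_dir, "ref.fa")),
        clones = write_fasta(sim$clones$clones,
                             file.path(out_dir, "clones.fa")),
        regions = write_regions(regions, file.path(out_dir, "regions.tsv")),
        truth = {
          p <- file.path(out_dir, "truth.tsv")
          utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          p
        }
      )
    }
    list(ref = ref, clones = sim$clones, truth = sim$truth,
         regions = regions, paths = paths)
  })
}
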