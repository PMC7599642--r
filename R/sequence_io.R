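# Sequence and annotation I/O, reference alignment, coordinate conventions.
#
# Coordinates are 1-based inclusive everywhere inside the package; BED-style
# 0-based half-open input is converted at the boundary.

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and, in DNA mode, `U` is converted to `T`.
#' Record order is preserved; identifiers are the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @param dna Logical; convert `U` to `T` (default `TRUE`).
#' @return Named character vector of sequences, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, dna = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (dna) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' `to_zero_half_open()` maps a 1-based inclusive interval to BED-style
#' 0-based half-open; `to_one_based()` is its inverse.
#'
#' @param start,end Interval bounds (vectors allowed).
#' @return A data frame with columns `start` and `end` in the target
#'   convention.
#' @export
to_zero_half_open <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_zero_half_open
#' @export
to_one_based <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' Construct a reference gene object
#'
#' Bundles the reference sequence (for example a full-length 18S rDNA of
#' 1809 nt) with optional named region annotations such as expansion
#' segments and hairpins.
#'
#' @param id Identifier.
#' @param seq DNA sequence; only `A`, `C`, `G`, `T`, `N` are permitted.
#' @param regions Optional region data frame as returned by
#'   [read_regions()] (columns `name`, `start`, `end`, 1-based inclusive).
#' @return An object of class `reference_gene` with fields `id`, `seq`,
#'   `length` and `regions`.
#' @export
reference_gene <- function(id, seq, regions = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("reference sequence may contain only A, C, G, T, N")
  len <- nchar(seq)
  if (!is.null(regions)) {
    regions <- validate_regions(regions, ref_length = len)
  }
  structure(list(id = id, seq = seq, length = len, regions = regions),
            class = "reference_gene")
}

#' @export
print.reference_gene <- function(x, ...) {
  cat("Reference gene", x$id, "-", x$length, "nt\n")
  if (!is.null(x$regions))
    cat("Regions:", paste(x$regions$name, collapse = ", "), "\n")
  invisible(x)
}

validate_regions <- function(regions, ref_length = NULL) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(duplicated(regions$name)))
    stop("duplicate region name(s): ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "))
  bad <- regions$start > regions$end
  if (any(bad))
    stop("region start > end: ", paste(regions$name[bad], collapse = ", "))
  if (any(regions$start < 1L))
    stop("region start below 1")
  if (!is.null(ref_length) && any(regions$end > ref_length))
    stop("region end beyond reference length (", ref_length, "): ",
         paste(regions$name[regions$end > ref_length], collapse = ", "))
  rownames(regions) <- NULL
  regions[c("name", "start", "end")]
}

#' Read a BED-like region annotation table
#'
#' Expects three whitespace-separated columns: region name, start, end.
#' The coordinate convention of the file may be declared on a comment line
#' (e.g. `# coords: 0-based` or `# coords: 1-based`) or passed via
#' `coords`; coordinates are normalised to 1-based inclusive internally.
#' Overlapping regions are permitted.
#'
#' @param path Path to the table.
#' @param coords Coordinate convention of the file when no header
#'   declaration is present: `"one_based"` (1-based inclusive, default) or
#'   `"zero_half_open"` (BED-style).
#' @param ref_length Optional reference length for range validation.
#' @return Data frame with columns `name`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_regions <- function(path, coords = c("one_based", "zero_half_open"),
                         ref_length = NULL) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  decl <- grep("coords", comments, ignore.case = TRUE, value = TRUE)
  if (length(decl)) {
    coords <- if (grepl("0-based|zero", decl[1], ignore.case = TRUE))
      "zero_half_open" else "one_based"
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no region rows in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) < 3L))
    stop("each region row needs 3 columns: name start end")
  regions <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L))
  )
  if (coords == "zero_half_open") {
    if (any(regions$start >= regions$end))
      stop("invalid 0-based half-open interval (start >= end)")
    regions$start <- regions$start + 1L
  }
  validate_regions(regions, ref_length = ref_length)
}

#' Write regions as a 1-based inclusive TSV
#'
#' @param regions Region data frame (`name`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coords: 1-based inclusive", con)
  utils::write.table(regions[c("name", "start", "end")], con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a clone set
#'
#' A clone set holds the aligned cloned gene copies of one cell line.
#'
#' @param line_id Cell-line identifier (e.g. `"9s"`).
#' @param clones Named character vector of aligned sequences (equal
#'   lengths; gap character `-`).
#' @return Object of class `clone_set` with fields `line_id`, `clones`,
#'   `n`.
#' @export
clone_set <- function(line_id, clones) {
  if (length(clones) == 0L) stop("clone set is empty")
  if (is.null(names(clones))) names(clones) <- paste0("c", seq_along(clones))
  if (length(unique(nchar(clones))) != 1L)
    stop("aligned clone sequences must have equal length")
  structure(list(line_id = line_id, clones = clones, n = length(clones)),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("Clone set", x$line_id, "-", x$n, "clones of",
      nchar(x$clones[[1]]), "aligned sites\n")
  invisible(x)
}

#' Globally align a cloned sequence to the reference gene
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1 and
#' a linear gap penalty of -2 per gapped position. Clones are full-length
#' gene copies, so terminal gaps are penalised like any other. Identical
#' sequences align gap-free; the alignment is deterministic for the fixed
#' scoring.
#'
#' @param clone_seq Clone DNA sequence (length within 10% of the
#'   reference, otherwise an error is raised).
#' @param ref A [reference_gene()] object or a plain reference sequence.
#' @return List with elements `clone` and `ref` (equal-length aligned
#'   strings, gap `-`) and `score`.
#' @export
align_to_reference <- function(clone_seq, ref) {
  ref_seq <- if (inherits(ref, "reference_gene")) ref$seq else toupper(ref)
  clone_seq <- toupper(clone_seq)
  nr <- nchar(ref_seq)
  if (abs(nchar(clone_seq) - nr) > 0.1 * nr)
    stop("not a full-length clone: length ", nchar(clone_seq),
         " deviates more than 10% from reference length ", nr)
  if (identical(clone_seq, ref_seq)) {
    return(list(clone = clone_seq, ref = ref_seq, score = nr))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = clone_seq, subject = ref_seq, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2
  )
  list(clone = as.character(Biostrings::alignedPattern(pa)),
       ref = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Align every clone of a multi-FASTA to the reference
#'
#' Convenience wrapper around [align_to_reference()]: aligns each clone
#' independently and returns a [clone_set()]. Because clones are
#' near-identical full-length copies, indels are rare; clones whose
#' alignment introduces gaps in the reference are reported via a warning
#' since their coordinates then differ column-wise from gap-free clones.
#'
#' @param clones Named character vector of clone sequences.
#' @param ref [reference_gene()] object.
#' @param line_id Cell-line identifier.
#' @return A [clone_set()] of reference-projected clone sequences: clone
#'   bases at reference positions, `-` where the clone has a deletion
#'   (clone insertions relative to the reference are dropped so that all
#'   clones share the reference coordinate system).
#' @export
align_clone_set <- function(clones, ref, line_id = "line") {
  stopifnot(inherits(ref, "reference_gene"))
  proj <- vapply(clones, function(s) {
    al <- align_to_reference(s, ref)
    rc <- seq_chars(al$ref)
    cc <- seq_chars(al$clone)
    chars_seq(cc[rc != "-"])  # project onto ungapped reference coordinates
  }, character(1))
  clone_set(line_id, proj)
}
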