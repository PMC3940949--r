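#' Construct a genome sequence object
#'
#' A `genome_sequence` is a named nucleotide sequence over the alphabet
#' A, C, G, T, N. Lowercase input is uppercased; IUPAC ambiguity codes other
#' than N (R, Y, S, W, K, M, B, D, H, V) are mapped to N with a warning.
#' Any other character is an error.
#'
#' @param id Character scalar identifier (FASTA headers are truncated at the
#'   first whitespace).
#' @param seq Character scalar nucleotide sequence.
#' @return An object of class `genome_sequence` with fields `id`, `seq`
#'   (uppercase) and `length`.
#' @export
genome_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  seq <- toupper(seq)
  bad_iupac <- grepl("[RYSWKMBDHV]", seq)
  if (bad_iupac) {
    warning("non-ACGT IUPAC codes in '", id, "' mapped to N")
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("characters outside IUPAC nucleotide codes in record '", id, "'")
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp\n", x$id, x$length))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) x$length

#' Read genome sequences from a FASTA file
#'
#' Returns one [genome_sequence()] per record, in file order, with ids
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (multi-record permitted).
#' @return List of `genome_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (!nzchar(s)) stop("record '", ids[i], "' has an empty sequence")
    out[[i]] <- genome_sequence(ids[i], s)
  }
  out
}

#' Select the largest chromosome from a set of records
#'
#' Multi-replicon genomes are analyzed on their largest chromosome; ties are
#' broken by earliest file order.
#'
#' @param records Non-empty list of `genome_sequence` objects.
#' @return The longest record.
#' @export
select_largest <- function(records) {
  if (!is.list(records) || length(records) == 0L)
    stop("'records' must be a non-empty list of genome sequences")
  lens <- vapply(records, function(r) r$length, integer(1))
  records[[which.max(lens)]]
}

#' Reverse complement of a genome sequence
#'
#' @param g A `genome_sequence`.
#' @return A `genome_sequence` with id suffixed "_rc".
#' @export
reverse_complement <- function(g) {
  genome_sequence(paste0(g$id, "_rc"), revcomp_string(g$seq))
}

#' A-tract definitions
#'
#' Two operationalizations of an A-tract are supported: `"A2T2"` scans for
#' the dinucleotides AA and TT; `"AT4"` scans for the tetranucleotides
#' AAAA, AAAT, AATT, ATTT and TTTT. Both word sets are closed under reverse
#' complement, so single-strand scanning is strand-symmetric.
#'
#' @param name `"A2T2"` or `"AT4"` (case-insensitive).
#' @return A `tract_method` object with fields `name`, `patterns`,
#'   `word_length`.
#' @export
tract_method <- function(name = c("A2T2", "AT4")) {
  name <- toupper(name[1])
  name <- match.arg(name, c("A2T2", "AT4"))
  if (name == "A2T2") {
    m <- list(name = "A2T2", patterns = c("AA", "TT"), word_length = 2L)
  } else {
    m <- list(name = "AT4",
              patterns = c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"),
              word_length = 4L)
  }
  structure(m, class = "tract_method")
}

#' Find A-tract start positions
#'
#' Reports every 0-based position whose window of `word_length` bases is in
#' the method's pattern set. Overlapping occurrences are all reported;
#' windows containing N never match.
#'
#' @param g A `genome_sequence`.
#' @param method A [tract_method()] (or its name).
#' @return Strictly increasing integer vector of 0-based start positions.
#' @export
find_a_tracts <- function(g, method = tract_method("A2T2")) {
  if (is.character(method)) method <- tract_method(method)
  w <- method$word_length
  if (g$length < w) return(integer(0))
  code <- seq_to_code(g$seq)           # 1=A 2=C 3=G 4=T, NA for N
  n <- length(code) - w + 1L
  # k-mer id in base 5 with NA propagating; compare against pattern ids
  id <- code[seq_len(n)]
  for (k in seq_len(w - 1L)) {
    id <- id * 5L + code[seq_len(n) + k]
  }
  pat_ids <- vapply(method$patterns, function(p) {
    pc <- seq_to_code(p)
    v <- pc[1]
    for (k in seq_along(pc)[-1]) v <- v * 5L + pc[k]
    v
  }, integer(1))
  which(!is.na(id) & id %in% pat_ids) - 1L
}

#' Write tract start positions as 3-column BED
#'
#' Coordinates are 0-based half-open: each line is
#' `chrom start start+word_length`.
#'
#' @param g A `genome_sequence`.
#' @param positions 0-based starts from [find_a_tracts()].
#' @param method The [tract_method()] used.
#' @param path Output file.
#' @export
tracts_to_bed <- function(g, positions, method, path) {
  if (is.character(method)) method <- tract_method(method)
  df <- data.frame(chrom = g$id, start = positions,
                   end = positions + method$word_length)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
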