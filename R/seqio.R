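# Sequence containers and standard-format I/O.
#
# Sequences travel through the package as plain tibbles ("sequence tables")
# with columns id, description, seq, alphabet. Coordinates are 0-based
# half-open internally; 1-based inclusive only at report boundaries.

# "-" is legal everywhere so aligned sequences flow through the same tables
NT_LETTERS <- c("A", "C", "G", "T", "N", "-")
AA_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")

#' Build a sequence table
#'
#' Constructs the tibble representation of a set of sequences used throughout
#' the package: one row per record with columns `id`, `description`, `seq`
#' and `alphabet` (`"nt"` or `"aa"`). Residues are uppercased and validated
#' against the declared alphabet (nucleotide: A, C, G, T, N; protein: the 20
#' standard residues plus X and `*`).
#'
#' @param id Character vector of unique record identifiers.
#' @param seq Character vector of residues, one string per record.
#' @param description Optional free-text descriptions (recycled).
#' @param alphabet `"nt"`, `"aa"`, or `NULL` to infer from the residues.
#' @return A tibble with one row per sequence.
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGGT"))
#' @export
seq_tbl <- function(id, seq, description = "", alphabet = NULL) {
  stopifnot(is.character(id), is.character(seq), length(id) == length(seq))
  if (length(id) == 0L) abort("sequence table must contain at least one record")
  seq <- toupper(seq)
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (is.null(alphabet)) alphabet <- infer_alphabet(seq)
  alphabet <- match.arg(alphabet, c("nt", "aa"))
  legal <- if (alphabet == "nt") NT_LETTERS else AA_LETTERS
  for (i in seq_along(seq)) {
    if (!nzchar(seq[[i]])) abort(paste0("record '", id[[i]], "' is empty"))
    chars <- unique(strsplit(seq[[i]], "")[[1]])
    bad <- setdiff(chars, legal)
    if (length(bad) > 0L) {
      abort(paste0("record '", id[[i]], "' contains character(s) illegal for ",
                   alphabet, " alphabet: ", paste(bad, collapse = ", ")))
    }
  }
  tibble::tibble(id = id, description = rep_len(description, length(id)),
                 seq = seq, alphabet = alphabet)
}

infer_alphabet <- function(seq) {
  chars <- unique(strsplit(paste(toupper(seq), collapse = ""), "")[[1]])
  chars <- setdiff(chars, "-")
  if (all(chars %in% NT_LETTERS)) "nt" else "aa"
}

check_seq_tbl <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("id", "seq", "alphabet") %in% names(x))) {
    abort(paste0("`", arg, "` must be a sequence table ",
                 "(columns id, seq, alphabet); see seq_tbl()"))
  }
  invisible(x)
}

#' Read a FASTA file into a sequence table
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"`, `"aa"`, or `NULL` to infer.
#' @return A tibble as produced by [seq_tbl()]; record order is preserved and
#'   residues are uppercased. Duplicate ids, empty files and characters
#'   illegal for the alphabet raise errors naming the offending record.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no FASTA records in ", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq_tbl(id = id, seq = unname(as.character(set)),
          description = description, alphabet = alphabet)
}

#' Write a sequence table (or alignment) to FASTA
#'
#' @param x A sequence table; gap characters are permitted (alignments).
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  check_seq_tbl(x)
  nm <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' @param x A nucleotide sequence table or character vector.
#' @return Same shape as the input with each sequence reverse-complemented.
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(x)))))
  }
  check_seq_tbl(x)
  if (any(x$alphabet != "nt")) abort("reverse_complement() requires nt records")
  dplyr::mutate(x, seq = reverse_complement(.data$seq))
}

#' Translate nucleotide sequences
#'
#' Standard genetic code; a trailing partial codon is dropped, stop codons
#' are rendered `*`, and any codon containing N translates to `X`.
#'
#' @param x A nucleotide sequence table or character vector.
#' @param frame Reading frame offset: 0, 1 or 2.
#' @return Protein sequence table (or character vector) of the translations.
#' @examples
#' translate_seq("ATGGCTTCA")
#' @export
translate_seq <- function(x, frame = 0) {
  stopifnot(frame %in% 0:2)
  if (is.character(x)) return(vapply(x, translate_one, "", frame = frame,
                                     USE.NAMES = FALSE))
  check_seq_tbl(x)
  if (any(x$alphabet != "nt")) abort("translate_seq() requires nt records")
  seq_tbl(id = x$id, description = x$description,
          seq = vapply(x$seq, translate_one, "", frame = frame,
                       USE.NAMES = FALSE),
          alphabet = "aa")
}

translate_one <- function(s, frame) {
  s <- toupper(s)
  n <- nchar(s) - frame
  if (n < 3) abort("sequence too short to translate in this frame")
  s <- substr(s, frame + 1, frame + (n %/% 3) * 3)
  aa <- Biostrings::translate(Biostrings::DNAString(s),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

#' Locate the longest open reading frame
#'
#' Scans the three forward frames (and optionally the reverse strand) for
#' ATG-initiated, stop-terminated open reading frames and returns the longest
#' one as a 0-based half-open interval. The reported length includes the stop
#' codon, so an ORF of length 3L nt encodes L - 1 residues plus the stop.
#' Ties are broken toward the 5'-most start on the forward strand.
#'
#' @param x A single-record nucleotide sequence table or one string.
#' @param both_strands Also scan the reverse complement.
#' @param min_len Minimum ORF length in nt (including the stop codon).
#' @return One-row tibble with `start`, `end` (0-based half-open, in the
#'   coordinates of the input sequence), `strand`, and `length`.
#' @examples
#' find_longest_orf("AAATGGCTTAAGG")
#' @export
find_longest_orf <- function(x, both_strands = FALSE, min_len = 30) {
  s <- single_seq(x, "nt")
  hits <- orf_scan(s, "+")
  if (both_strands) {
    rc <- reverse_complement(s)
    h2 <- orf_scan(rc, "-")
    if (nrow(h2) > 0) {
      # map reverse-strand coordinates back onto the input sequence
      L <- nchar(s)
      h2 <- dplyr::mutate(h2, start0 = L - .data$end,
                          end = L - .data$start, start = .data$start0,
                          start0 = NULL)
    }
    hits <- dplyr::bind_rows(hits, h2)
  }
  hits <- dplyr::filter(hits, .data$length >= min_len)
  if (nrow(hits) == 0L) {
    abort(paste0("no open reading frame of length >= ", min_len, " nt found"))
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$length), .data$start)
  hits[1, c("start", "end", "strand", "length")]
}

orf_scan <- function(s, strand) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  out <- list()
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3
    if (n_codon < 2) next
    starts <- frame + 3 * (seq_len(n_codon) - 1) + 1
    codons <- paste0(chars[starts], chars[starts + 1], chars[starts + 2])
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    # segments between stops; an ORF is first ATG .. following stop
    stop_idx <- which(is_stop)
    seg_start <- 1L
    for (k in stop_idx) {
      atg <- which(is_atg[seg_start:k])
      if (length(atg) > 0) {
        i0 <- seg_start + atg[1] - 1L  # codon index of ATG
        out[[length(out) + 1L]] <- tibble::tibble(
          start = starts[i0] - 1L, end = starts[k] + 2L,
          strand = strand, length = starts[k] + 2L - (starts[i0] - 1L))
      }
      seg_start <- k + 1L
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer()))
  }
  dplyr::bind_rows(out)
}

#' Extract the subsequence covered by an interval
#'
#' @param x Single-record nucleotide sequence table or string.
#' @param interval One-row tibble with `start`, `end` (0-based half-open) and
#'   optionally `strand` (`-` returns the reverse complement).
#' @return The subsequence as a character string.
#' @export
interval_seq <- function(x, interval) {
  s <- single_seq(x)
  stopifnot(interval$start >= 0, interval$end <= nchar(s),
            interval$start < interval$end)
  out <- substr(s, interval$start + 1, interval$end)
  if (!is.null(interval$strand) && identical(interval$strand, "-")) {
    out <- reverse_complement(out)
  }
  out
}

single_seq <- function(x, alphabet = NULL) {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  check_seq_tbl(x)
  if (nrow(x) != 1L) abort("expected a single sequence record")
  if (!is.null(alphabet) && x$alphabet != alphabet) {
    abort(paste0("record '", x$id, "' is not a ", alphabet, " sequence"))
  }
  x$seq
}
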