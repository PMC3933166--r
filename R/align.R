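# Global pairwise and progressive multiple alignment.
#
# The pairwise core is a Gotoh dynamic program (src/align.cpp). Multiple
# alignment is center-star progressive: the most central sequence (highest
# total pairwise score) anchors the alignment and every other sequence is
# merged in under "once a gap, always a gap". For coding nucleotide input the
# protein alignment dictates the nucleotide alignment: sequences are
# translated, aligned in protein space and back-threaded to codons.

#' Globally align two sequences
#'
#' Needleman-Wunsch/Gotoh global alignment. The default scoring (match 1,
#' mismatch -1, linear gap -2) is the package's reference scheme; setting
#' `gap_ext` different from `gap_open` gives affine gaps where a gap of
#' length L costs `gap_open + (L - 1) * gap_ext`.
#'
#' @param a,b Sequences (strings or single-record sequence tables).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return List with elements `a`, `b` (aligned strings) and `score`.
#' @examples
#' align_pair("ACGTACGT", "ACGACGT")
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                       gap_ext = gap_open) {
  a <- single_seq(a)
  b <- single_seq(b)
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_ext)
}

#' Progressive multiple alignment
#'
#' Center-star progressive global alignment. With `mode = "codon"` the input
#' must be in-frame coding nucleotide sequences (length a multiple of 3);
#' they are translated, aligned as proteins, and the protein alignment is
#' back-threaded onto codons so that gaps only ever fall on codon boundaries.
#'
#' @param x Sequence table with at least two records of one alphabet.
#' @param mode `"auto"` (residue-level alignment in the input alphabet) or
#'   `"codon"` (protein-guided codon alignment of coding nt).
#' @param match,mismatch,gap_open,gap_ext Pairwise scoring parameters.
#' @return An aligned sequence table: same rows, `seq` columns of equal
#'   length over residues plus `-`; no all-gap columns.
#' @export
align_seqs <- function(x, mode = c("auto", "codon"), match = 1, mismatch = -1,
                       gap_open = -2, gap_ext = gap_open) {
  check_seq_tbl(x)
  mode <- match.arg(mode)
  if (nrow(x) < 2L) abort("alignment requires at least two sequences")
  if (length(unique(x$alphabet)) != 1L) {
    abort("cannot align sequences of mixed alphabets")
  }
  if (mode == "codon") {
    if (any(x$alphabet != "nt")) abort("codon mode requires nt sequences")
    if (any(nchar(x$seq) %% 3 != 0)) {
      abort("codon mode requires lengths that are multiples of 3")
    }
    prot <- translate_seq(x)
    aln <- star_align(prot$seq, match, mismatch, gap_open, gap_ext)
    rows <- thread_codons(aln, x$seq)
  } else {
    rows <- star_align(x$seq, match, mismatch, gap_open, gap_ext)
  }
  out <- x
  out$seq <- drop_allgap_columns(rows)
  out
}

star_align <- function(seqs, match, mismatch, gap_open, gap_ext) {
  n <- length(seqs)
  if (n == 2L) {
    pa <- align_pair_cpp(seqs[1], seqs[2], match, mismatch, gap_open, gap_ext)
    return(c(pa$a, pa$b))
  }
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- align_pair_cpp(seqs[i], seqs[j], match, mismatch,
                           gap_open, gap_ext)$score
      scores[i, j] <- sc
      scores[j, i] <- sc
    }
  }
  center <- which.max(rowSums(scores))
  master <- strsplit(seqs[center], "")[[1]]  # center row, with merged gaps
  rows <- list()
  rows[[center]] <- master
  for (i in setdiff(seq_len(n), center)) {
    pa <- align_pair_cpp(seqs[center], seqs[i], match, mismatch,
                         gap_open, gap_ext)
    pc <- strsplit(pa$a, "")[[1]]  # center as aligned in this pair
    pi_ <- strsplit(pa$b, "")[[1]]
    # merge pairwise alignment into master coordinates
    merged <- merge_into_master(master, pc, pi_)
    if (length(merged$master) > length(master)) {
      # new columns were inserted: pad all previously merged rows
      for (k in seq_along(rows)) {
        if (!is.null(rows[[k]]) && k != center) {
          rows[[k]] <- insert_gaps(rows[[k]], merged$inserted)
        }
      }
      master <- merged$master
      rows[[center]] <- master
    }
    rows[[i]] <- merged$row
  }
  vapply(rows, paste, "", collapse = "")
}

# Align the pairwise view of the center (pc, with gaps) against the running
# master center row (which may already carry gaps from earlier merges).
# Returns the possibly-extended master, the new row in master coordinates,
# and the master positions (before which) new columns were inserted.
merge_into_master <- function(master, pc, prow) {
  im <- 1L
  ip <- 1L
  out_master <- character(0)
  out_row <- character(0)
  inserted <- integer(0)  # positions in the *old* master before which a
                          # column was inserted (for padding merged rows)
  nm <- length(master)
  np <- length(pc)
  old_pos <- 1L
  while (im <= nm || ip <= np) {
    m_gap <- im <= nm && master[im] == "-"
    p_gap <- ip <= np && pc[ip] == "-"
    if (im <= nm && ip <= np && !m_gap && !p_gap) {
      # both show the same center residue
      out_master <- c(out_master, master[im])
      out_row <- c(out_row, prow[ip])
      im <- im + 1L
      ip <- ip + 1L
      old_pos <- old_pos + 1L
    } else if (m_gap) {
      # master has a gap column from an earlier merge; new row gets a gap
      out_master <- c(out_master, "-")
      out_row <- c(out_row, "-")
      im <- im + 1L
      old_pos <- old_pos + 1L
    } else if (p_gap) {
      # this pair inserts a column absent from the master
      out_master <- c(out_master, "-")
      out_row <- c(out_row, prow[ip])
      inserted <- c(inserted, old_pos)
      ip <- ip + 1L
    } else {
      stop("internal error: center rows out of sync")  # nocov
    }
  }
  list(master = out_master, row = out_row, inserted = inserted)
}

insert_gaps <- function(row, inserted) {
  if (length(inserted) == 0L) return(row)
  # inserted holds old-master positions; process left to right with offset
  for (k in seq_along(inserted)) {
    pos <- inserted[k] + (k - 1L)
    row <- append(row, "-", after = pos - 1L)
  }
  row
}

thread_codons <- function(aa_rows, nt_seqs) {
  vapply(seq_along(aa_rows), function(i) {
    aa <- strsplit(aa_rows[i], "")[[1]]
    codons <- substring(nt_seqs[i], seq(1, nchar(nt_seqs[i]), 3),
                        pmin(seq(3, nchar(nt_seqs[i]) + 2, 3),
                             nchar(nt_seqs[i])))
    out <- character(length(aa))
    j <- 1L
    for (k in seq_along(aa)) {
      if (aa[k] == "-") {
        out[k] <- "---"
      } else {
        out[k] <- codons[j]
        j <- j + 1L
      }
    }
    paste(out, collapse = "")
  }, "")
}

drop_allgap_columns <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(mat != "-") > 0
  apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
}

is_aligned <- function(x) {
  length(unique(nchar(x$seq))) == 1L && nrow(x) >= 2L
}
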