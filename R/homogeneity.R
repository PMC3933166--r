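# Repeat homogenization and positional conservation statistics.

#' Percent identity between two aligned rows
#'
#' `100 * identical columns / counted columns`. Under `"pairwise_deletion"`
#' (the default) columns where either row has a gap are not counted; under
#' `"gap_mismatch"` a one-sided gap counts as a mismatch. Columns gapped in
#' both rows are never counted.
#'
#' @param a,b Equal-length aligned strings.
#' @param gap_policy `"pairwise_deletion"` or `"gap_mismatch"`.
#' @return Percent identity in `[0, 100]`; `NA` (with a warning) if no
#'   column is counted.
#' @examples
#' pairwise_identity("AC-T", "ACGT")                       # 100
#' pairwise_identity("AC-T", "ACGT", "gap_mismatch")       # 75
#' @export
pairwise_identity <- function(a, b,
                              gap_policy = c("pairwise_deletion",
                                             "gap_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  a <- single_seq(a)
  b <- single_seq(b)
  if (nchar(a) != nchar(b)) abort("rows must have equal aligned length")
  cnt <- identity_counts_cpp(a, b, gap_policy == "pairwise_deletion")
  if (cnt[2] == 0L) {
    warn("no counted columns; identity undefined")
    return(NA_real_)
  }
  100 * cnt[1] / cnt[2]
}

#' Pairwise identity matrix of an alignment
#'
#' @param aln Aligned sequence table (>= 2 rows of equal length).
#' @param gap_policy See [pairwise_identity()].
#' @return An object of class `identity_matrix`: the square percent-identity
#'   matrix (diagonal 100) with row/column names from `aln$id`. Use
#'   [mean_offdiag()], [per_row_mean()] or [tidy()] for summaries.
#' @export
identity_matrix <- function(aln, gap_policy = c("pairwise_deletion",
                                                "gap_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  check_seq_tbl(aln)
  if (nrow(aln) < 2L) abort("identity matrix requires >= 2 rows")
  if (!is_aligned(aln)) abort("rows must have equal aligned length")
  n <- nrow(aln)
  m <- matrix(100, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pairwise_identity(aln$seq[i], aln$seq[j], gap_policy)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("identity_matrix", "matrix"),
            gap_policy = gap_policy)
}

#' Mean off-diagonal identity
#' @param m An `identity_matrix`.
#' @return Mean percent identity over all unordered pairs.
#' @export
mean_offdiag <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Per-row mean identity to all other rows
#' @param m An `identity_matrix`.
#' @return Tibble with `id` and `mean_identity`.
#' @export
per_row_mean <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  mm <- unclass(m)
  diag(mm) <- NA
  tibble::tibble(id = rownames(mm),
                 mean_identity = rowMeans(mm, na.rm = TRUE))
}

#' @export
tidy.identity_matrix <- function(x, ...) {
  mm <- unclass(x)
  out <- tibble::as_tibble(as.data.frame.table(mm, stringsAsFactors = FALSE))
  names(out) <- c("id_a", "id_b", "identity")
  dplyr::filter(out, .data$id_a != .data$id_b)
}

#' Majority-rule consensus of an alignment
#'
#' Per column the most frequent residue wins, with the gap character counted
#' as a residue; columns whose majority is a gap are dropped from the
#' consensus string. Ties are broken toward the alphabetically first residue
#' and flagged in the `ties` attribute.
#'
#' @param aln Aligned sequence table (>= 2 rows).
#' @param id Identifier for the consensus record.
#' @return One-row sequence table; attributes `ties` (tibble of column,
#'   residues involved) and `dropped_columns` (gap-majority columns).
#' @export
consensus_seq <- function(aln, id = "consensus") {
  check_seq_tbl(aln)
  if (nrow(aln) < 2L) abort("consensus requires >= 2 rows")
  if (!is_aligned(aln)) abort("rows must have equal aligned length")
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  ncol_ <- ncol(mat)
  cons <- character(ncol_)
  tie_cols <- integer(0)
  tie_res <- character(0)
  for (k in seq_len(ncol_)) {
    tab <- table(mat[, k])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      tie_cols <- c(tie_cols, k)
      tie_res <- c(tie_res, paste(sort(top), collapse = "/"))
    }
    cons[k] <- sort(top)[1]
  }
  dropped <- which(cons == "-")
  out_seq <- paste(cons[cons != "-"], collapse = "")
  out <- seq_tbl(id = id, seq = out_seq, alphabet = aln$alphabet[1])
  attr(out, "ties") <- tibble::tibble(column = tie_cols, residues = tie_res)
  attr(out, "dropped_columns") <- dropped
  out
}

#' Per-column conservation profile against a reference
#'
#' Aligns the input if needed, then reports for every alignment column the
#' fraction of non-reference rows whose residue equals the reference row's
#' residue. Domain annotations (0-based half-open column intervals with
#' labels) are attached so regional means can be computed.
#'
#' @param x Sequence table of consensus sequences (aligned or not).
#' @param reference_id Row to compare the others against.
#' @param domains Optional tibble with `start`, `end` (0-based half-open
#'   alignment columns) and `label`.
#' @return A `positional_profile`: tibble with `column` (1-based),
#'   `reference_residue` and `frac_identical` in `[0, 1]`; the domain table
#'   is carried in the `domains` attribute.
#' @export
positional_profile <- function(x, reference_id, domains = NULL) {
  check_seq_tbl(x)
  if (!reference_id %in% x$id) {
    abort(paste0("reference id '", reference_id, "' not present"))
  }
  if (!is_aligned(x)) x <- align_seqs(x)
  mat <- do.call(rbind, strsplit(x$seq, ""))
  ref <- mat[x$id == reference_id, ]
  others <- mat[x$id != reference_id, , drop = FALSE]
  frac <- colMeans(sweep(others, 2, ref, FUN = "=="))
  out <- tibble::tibble(column = seq_along(ref), reference_residue = ref,
                        frac_identical = frac)
  if (!is.null(domains)) {
    stopifnot(all(c("start", "end", "label") %in% names(domains)))
    if (any(domains$start < 0) || any(domains$end > length(ref))) {
      abort("domain interval outside alignment columns")
    }
    attr(out, "domains") <- tibble::as_tibble(domains)
  }
  class(out) <- c("positional_profile", class(out))
  out
}

#' Read a BED-like domain annotation table
#'
#' Tab-separated with columns `ref`, `start`, `end` (0-based half-open)
#' and `label`; `#` lines are comments. A repeat-unit annotation with the
#' published helix-rich / unstructured split ships with the package:
#' `system.file("extdata", "acsp1_repeat_domains.tsv", package = "spidrhom")`.
#'
#' @param path Path to the TSV.
#' @return Tibble with `ref`, `start`, `end`, `label`.
#' @export
read_domains <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("start", "end", "label") %in% names(out)))
  out
}

#' Mean conservation per annotated region
#'
#' @param profile A [positional_profile()] with a domain annotation.
#' @param domains Optional annotation overriding the attached one.
#' @return Tibble with `label`, `n_columns` and `mean_identity_pct`.
#' @export
region_means <- function(profile, domains = NULL) {
  if (is.null(domains)) domains <- attr(profile, "domains")
  if (is.null(domains)) abort("no domain annotation supplied")
  purrr::pmap_dfr(domains, function(start, end, label, ...) {
    cols <- profile$frac_identical[(start + 1):end]
    tibble::tibble(label = label, n_columns = length(cols),
                   mean_identity_pct = 100 * mean(cols))
  })
}

#' Amino-acid composition
#'
#' @param x Protein sequence (table or string). Stop characters (`*`) are
#'   excluded before computing percentages.
#' @return Tibble with `residue` and `percent`, summing to 100.
#' @export
aa_composition <- function(x) {
  s <- if (is.character(x)) toupper(x) else {
    check_seq_tbl(x)
    if (any(x$alphabet != "aa")) abort("aa_composition() requires aa records")
    paste(x$seq, collapse = "")
  }
  chars <- strsplit(s, "")[[1]]
  chars <- chars[chars != "*" & chars != "-"]
  tab <- table(chars)
  tibble::tibble(residue = names(tab),
                 percent = 100 * as.numeric(tab) / sum(tab)) |>
    dplyr::arrange(dplyr::desc(.data$percent))
}

#' Codon usage of a coding sequence
#'
#' @param x Coding nucleotide sequence (length a multiple of 3). An internal
#'   stop codon raises a warning but is still counted.
#' @return A `codon_usage` tibble with `amino_acid`, `codon`, `count` and
#'   `fraction` (fractions sum to 1 within each amino acid).
#' @export
codon_usage <- function(x) {
  s <- single_seq(x)
  if (nchar(s) %% 3 != 0) abort("length must be a multiple of 3")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  internal_stop <- which(aa == "*" & seq_along(aa) < length(aa))
  if (length(internal_stop) > 0) {
    warn(paste0(length(internal_stop), " internal stop codon(s) present"))
  }
  tab <- dplyr::count(tibble::tibble(amino_acid = aa, codon = codons),
                      .data$amino_acid, .data$codon, name = "count")
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$amino_acid),
                       fraction = .data$count / sum(.data$count))
  tab <- dplyr::ungroup(tab)
  class(tab) <- c("codon_usage", class(tab))
  tab
}

#' Fraction of alanine codons that are GCA or GCT (GCW)
#'
#' @param cu A [codon_usage()] table.
#' @return Fraction in `[0, 1]`, or `NA` (flagged with a warning) when no
#'   alanine codon is present.
#' @export
gcw_fraction <- function(cu) {
  stopifnot(inherits(cu, "codon_usage"))
  ala <- dplyr::filter(cu, .data$amino_acid == "A")
  if (nrow(ala) == 0L || sum(ala$count) == 0L) {
    warn("no alanine codons; GCW fraction undefined")
    return(NA_real_)
  }
  sum(ala$count[ala$codon %in% c("GCA", "GCT")]) / sum(ala$count)
}

#' Positional codon table across aligned repeat units
#'
#' For a codon-aligned nucleotide alignment of repeat units, reports the
#' codon used by each unit at every codon column, and flags columns where
#' all units share one codon. A gap that breaks the reading frame (not a
#' whole aligned codon) is an error.
#'
#' @param aln Codon-aligned nucleotide alignment (sequence table).
#' @return List with `table` (tibble: `codon_column`, `nt_start` 1-based,
#'   `id`, `codon`) and `summary` (tibble: `codon_column`, `uniform`,
#'   `codon` when uniform).
#' @export
positional_codon_table <- function(aln) {
  check_seq_tbl(aln)
  if (!is_aligned(aln)) abort("rows must have equal aligned length")
  W <- nchar(aln$seq[1])
  if (W %% 3 != 0) abort("alignment width must be a multiple of 3")
  rows <- purrr::map_dfr(seq_len(nrow(aln)), function(i) {
    codons <- substring(aln$seq[i], seq(1, W, 3), seq(3, W, 3))
    has_gap <- grepl("-", codons) & codons != "---"
    if (any(has_gap)) {
      abort(paste0("frame-breaking gap in record '", aln$id[i], "'"))
    }
    tibble::tibble(codon_column = seq_along(codons),
                   nt_start = seq(1, W, 3), id = aln$id[i], codon = codons)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$codon_column, .data$nt_start),
    uniform = dplyr::n_distinct(.data$codon) == 1L,
    codon = if (dplyr::n_distinct(.data$codon) == 1L) .data$codon[1]
            else NA_character_,
    .groups = "drop")
  list(table = rows, summary = summary)
}

#' Mean pairwise divergence per region
#'
#' @param groups Named list of aligned sequence tables, one per region
#'   (e.g. `n_term`, `repeat`, `c_term`).
#' @param gap_policy See [pairwise_identity()].
#' @return Tibble with `region`, `n_seqs`, `mean_p_distance`, ordered from
#'   least to most divergent.
#' @export
region_divergence <- function(groups, gap_policy = "pairwise_deletion") {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- purrr::imap_dfr(groups, function(aln, region) {
    m <- identity_matrix(aln, gap_policy)
    tibble::tibble(region = region, n_seqs = nrow(aln),
                   mean_p_distance = 1 - mean_offdiag(m) / 100)
  })
  dplyr::arrange(out, .data$mean_p_distance)
}

#' P-distance matrix from an alignment
#'
#' @param aln Aligned sequence table.
#' @param gap_policy See [pairwise_identity()].
#' @return A base `dist`-compatible square matrix of p-distances in `[0, 1]`.
#' @export
p_distance_matrix <- function(aln, gap_policy = "pairwise_deletion") {
  m <- identity_matrix(aln, gap_policy)
  d <- 1 - unclass(m) / 100
  diag(d) <- 0
  d
}
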