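# Tandem-repeat period detection and architecture segmentation.
#
# A spidroin ORF is modeled as n_term | R1..Rn | c_term where all repeat
# units except possibly the last share one codon-multiple period. Period
# detection maximizes shift self-identity; segmentation scans every
# codon-aligned phase exhaustively and classifies flanking low-similarity
# stretches as terminals.

#' Detect the tandem-repeat period of a coding sequence
#'
#' Scores every codon-multiple shift `p` in `[min_period, max_period]` by
#' the mean identity between the sequence and itself shifted by `p`
#' (computed over the overlap). Because every multiple of the fundamental
#' period scores nearly as high, the reported period is the smallest shift
#' whose score is within `tol` of the maximum.
#'
#' @param x In-frame coding nucleotide sequence (table or string).
#' @param min_period,max_period Search range in nt; `min_period` must be a
#'   multiple of 3 and at least 3.
#' @param floor Minimum acceptable self-identity; below it the sequence is
#'   declared non-tandem (error).
#' @param tol Score slack used to prefer the fundamental period over its
#'   multiples.
#' @return An object of class `period_scan`: list with `period`, `score`,
#'   `runner_up` (next-best distinct period and score) and `scores`
#'   (tibble of all shifts).
#' @export
detect_period <- function(x, min_period = 90, max_period = 2100,
                          floor = 0.60, tol = 0.01) {
  s <- single_seq(x, NULL)
  if (min_period < 3 || min_period %% 3 != 0) {
    abort("min_period must be >= 3 and a multiple of 3")
  }
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  max_period <- min(max_period, L - 3)
  periods <- seq(min_period, max_period, by = 3)
  if (length(periods) == 0L) abort("sequence too short for the period range")
  score <- vapply(periods, function(p) {
    mean(chars[seq_len(L - p)] == chars[(p + 1):L])
  }, 0)
  best <- max(score)
  if (best < floor) {
    abort(paste0("no tandem structure: best self-identity ",
                 round(best, 3), " is below floor ", floor))
  }
  idx <- which(score >= best - tol)[1]  # smallest qualifying shift
  period <- periods[idx]
  others <- which(periods != period)
  ru <- others[which.max(score[others])]
  structure(list(period = period, score = score[idx],
                 runner_up = tibble::tibble(period = periods[ru],
                                            score = score[ru]),
                 scores = tibble::tibble(period = periods, score = score)),
            class = "period_scan")
}

#' @export
print.period_scan <- function(x, ...) {
  cat("Tandem period scan\n")
  cat("  period:", x$period, "nt (self-identity",
      sprintf("%.3f)", x$score), "\n")
  cat("  runner-up:", x$runner_up$period, "nt (self-identity",
      sprintf("%.3f)", x$runner_up$score), "\n")
  invisible(x)
}

#' Segment an ORF into terminals and repeat units
#'
#' Scans every codon-aligned phase in `[0, period)`. For each phase the ORF
#' is chopped into full-length units; units at least `terminal_threshold`
#' identical to the unit majority consensus are classified as repeats, and
#' the unmatched 5' and 3' stretches are re-fit one unit at a time, ending
#' in at most one truncated unit per side chosen by a maximum-scoring
#' codon-aligned overlap against the consensus. The phase maximizing total
#' repeat-region matches wins, with truncated overlaps penalized so the
#' tiling with the fewest truncations (truncation at the 3' end by
#' convention) is preferred; residual ties go to the phase with the
#' longest run of full-length units.
#'
#' @param x In-frame coding nucleotide ORF (table or string).
#' @param period Repeat period in nt (multiple of 3), e.g. from
#'   [detect_period()].
#' @param terminal_threshold Identity below which a flanking unit is
#'   assigned to a terminal rather than the repeat array (default 0.5).
#' @param allow_truncated Keep a truncated final (or leading) repeat when
#'   its aligned overlap with the consensus clears the threshold.
#' @return A `gene_model`: list with `length`, `period_nt`, intervals
#'   `n_term`, `repeats` (tibble, rows R1..Rn) and `c_term` (0-based
#'   half-open, ORF coordinates), the unit `consensus`, and per-unit
#'   identities. `tidy()` returns the intervals as one tibble.
#' @export
segment_repeats <- function(x, period, terminal_threshold = 0.5,
                            allow_truncated = TRUE) {
  s <- single_seq(x, NULL)
  if (inherits(period, "period_scan")) period <- period$period
  if (period %% 3 != 0) abort("period must be a multiple of 3")
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  if (L < 2 * period) abort("fewer than 2 repeat units fit in the sequence")

  best <- NULL
  for (phase in seq(0, period - 3, by = 3)) {
    cand <- score_phase(chars, L, period, phase, terminal_threshold,
                        allow_truncated)
    if (is.null(cand)) next
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$n_full > best$n_full)) {
      best <- cand
    }
  }
  if (is.null(best) || nrow(best$repeats) < 2L) {
    abort("fewer than 2 repeat units detected")
  }
  rep_tbl <- best$repeats
  rep_tbl$unit <- paste0("R", seq_len(nrow(rep_tbl)))
  model <- structure(list(
    length = L,
    period_nt = as.integer(period),
    n_term = tibble::tibble(start = 0L, end = rep_tbl$start[1]),
    repeats = rep_tbl[, c("unit", "start", "end", "identity")],
    c_term = tibble::tibble(start = rep_tbl$end[nrow(rep_tbl)], end = L),
    consensus = best$consensus,
    phase = best$phase
  ), class = "gene_model")
  validate_gene_model(model)
  model
}

score_phase <- function(chars, L, period, phase, thr, allow_truncated,
                        trunc_penalty = 0.25) {
  n_full <- (L - phase) %/% period
  if (n_full < 2) return(NULL)
  starts <- phase + period * (seq_len(n_full) - 1)  # 0-based
  units <- matrix("", n_full, period)
  for (i in seq_len(n_full)) {
    units[i, ] <- chars[(starts[i] + 1):(starts[i] + period)]
  }
  cons <- apply(units, 2, function(col) {
    tab <- table(col)
    sort(names(tab)[tab == max(tab)])[1]
  })
  ident <- rowMeans(units == matrix(cons, n_full, period, byrow = TRUE))
  is_rep <- ident >= thr
  if (!any(is_rep)) return(NULL)
  # repeats must be contiguous: take the longest run of qualifying units
  runs <- rle(is_rep)
  run_ends <- cumsum(runs$lengths)
  good <- which(runs$values)
  if (length(good) == 0L) return(NULL)
  pick <- good[which.max(runs$lengths[good])]
  i1 <- run_ends[pick] - runs$lengths[pick] + 1L
  i2 <- run_ends[pick]
  if (allow_truncated && i2 - i1 >= 2L) {
    # boundary units are re-fit below rather than taken as full windows:
    # a truncated last repeat otherwise swallows the start of c_term
    i2 <- i2 - 1L
    i1 <- i1 + 1L
  }
  rep_start <- starts[i1]
  rep_end <- starts[i2] + period
  cmat <- matrix(cons, n_full, period, byrow = TRUE)
  score <- sum(units[i1:i2, ] == cmat[i1:i2, , drop = FALSE])
  reps <- tibble::tibble(start = starts[i1:i2],
                         end = starts[i1:i2] + period,
                         identity = ident[i1:i2])
  if (allow_truncated) {
    # 3' boundary: repeatedly refit full units (k = period), then at most
    # one truncated final repeat (k < period). Truncated overlaps enter
    # the phase score net of the threshold penalty plus a fixed
    # per-truncation cost, so the phase that tiles the array with the
    # fewest truncated units wins (rotated phases need two truncations
    # where the true phase needs at most one).
    repeat {
      rest <- if (rep_end < L) chars[(rep_end + 1):L] else character(0)
      k3 <- best_overlap(rest, cons, thr, from_start = TRUE)
      if (k3$len == 0) break
      reps <- dplyr::bind_rows(reps, tibble::tibble(
        start = rep_end, end = rep_end + k3$len, identity = k3$identity))
      rep_end <- rep_end + k3$len
      score <- score + if (k3$len == period) k3$matches else
        k3$matches - 0.72 * k3$len - trunc_penalty * period
      if (k3$len < period) break
    }
    # 5' boundary: same, walking toward the start
    repeat {
      head_ <- if (rep_start > 0) chars[seq_len(rep_start)] else character(0)
      k5 <- best_overlap(head_, cons, thr, from_start = FALSE)
      if (k5$len == 0) break
      reps <- dplyr::bind_rows(tibble::tibble(
        start = rep_start - k5$len, end = rep_start,
        identity = k5$identity), reps)
      rep_start <- rep_start - k5$len
      # a 5' truncation costs more than a 3' one: a tandem array truncated
      # at one end admits two mirror tilings, and the convention here (as
      # in spidroin annotation) is that the truncated unit is the last
      score <- score + if (k5$len == period) k5$matches else
        k5$matches - 0.72 * k5$len - 1.4 * trunc_penalty * period
      if (k5$len < period) break
    }
  }
  list(phase = phase, score = score, n_full = i2 - i1 + 1L,
       repeats = reps, consensus = paste(cons, collapse = ""))
}

# Maximum-scoring codon-aligned overlap between a flanking stretch and the
# unit consensus; the cut maximizes matches - slope * k, where the default
# slope 0.72 approximates the log-likelihood-ratio changepoint between a
# near-identical repeat (~98% per-base identity) and unrelated terminal
# sequence (~25% chance identity). When a full unit fits and scores within
# `snap` of the maximum, the overlap snaps to the full period so that a
# single mutated boundary codon does not shave a codon off a full unit.
# from_start = TRUE compares the first k of `rest` against the consensus
# prefix (truncated last unit); from_start = FALSE compares the last k of
# `head` against the consensus suffix (truncated first unit).
best_overlap <- function(flank, cons, thr, from_start, slope = 0.72,
                         snap = 1.0) {
  n <- length(flank)
  p <- length(cons)
  if (n == 0L) return(list(len = 0L, matches = 0, identity = NA_real_))
  kmax <- min(n, p)  # k = p refits a full boundary unit
  if (kmax < 3L) return(list(len = 0L, matches = 0, identity = NA_real_))
  ks <- seq(3L, kmax - kmax %% 3L, by = 3L)
  mk <- max(ks)
  eq <- if (from_start) {
    flank[seq_len(mk)] == cons[seq_len(mk)]
  } else {
    rev(flank)[seq_len(mk)] == rev(cons)[seq_len(mk)]
  }
  matches <- cumsum(eq)[ks]
  sc <- matches - slope * ks
  if (max(sc) <= 0) return(list(len = 0L, matches = 0, identity = NA_real_))
  pick <- which.max(sc)
  if (mk == p && sc[length(sc)] >= max(sc) - snap) pick <- length(sc)
  k <- ks[pick]
  m <- matches[pick]
  # a few chance-matching codons are not a truncated repeat
  if (k < p && k < 15L) return(list(len = 0L, matches = 0,
                                    identity = NA_real_))
  list(len = k, matches = m, identity = m / k)
}

validate_gene_model <- function(model) {
  reps <- model$repeats
  stopifnot(model$n_term$end == reps$start[1],
            model$c_term$start == reps$end[nrow(reps)],
            all(reps$start[-1] == reps$end[-nrow(reps)]),
            model$n_term$start == 0, model$c_term$end == model$length)
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model (", x$length, " nt ORF, period ", x$period_nt, " nt)\n",
      sep = "")
  cat("  n_term: ", x$n_term$end - x$n_term$start, " nt\n", sep = "")
  cat("  repeats: ", nrow(x$repeats), " units (",
      sum(x$repeats$end - x$repeats$start), " nt)\n", sep = "")
  cat("  c_term: ", x$c_term$end - x$c_term$start, " nt\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(region = "n_term", start = x$n_term$start,
                   end = x$n_term$end),
    tibble::tibble(region = x$repeats$unit, start = x$repeats$start,
                   end = x$repeats$end),
    tibble::tibble(region = "c_term", start = x$c_term$start,
                   end = x$c_term$end)) |>
    dplyr::mutate(length = .data$end - .data$start)
}

#' @export
glance.gene_model <- function(x, ...) {
  tibble::tibble(
    orf_length_nt = x$length, period_nt = x$period_nt,
    n_repeats = nrow(x$repeats),
    n_term_nt = x$n_term$end - x$n_term$start,
    c_term_nt = x$c_term$end - x$c_term$start,
    last_repeat_nt = x$repeats$end[nrow(x$repeats)] -
      x$repeats$start[nrow(x$repeats)])
}

#' Extract the region sequences of a gene model
#'
#' @param model A [segment_repeats()] gene model.
#' @param x The ORF the model was fit to.
#' @param keep_empty Keep zero-length terminal records (flagged by a
#'   `zero_length` attribute) instead of dropping them.
#' @return Sequence table with rows `n_term`, `R1..Rn`, `c_term` (5' to 3');
#'   the concatenation of `seq` equals the ORF.
#' @export
extract_regions <- function(model, x, keep_empty = TRUE) {
  s <- single_seq(x)
  if (model$length != nchar(s)) abort("model does not match sequence length")
  td <- tidy(model)
  td <- dplyr::filter(td, .data$length > 0 | keep_empty)
  empty <- td$region[td$length == 0]
  td <- dplyr::filter(td, .data$length > 0)
  out <- seq_tbl(id = td$region,
                 seq = substring(s, td$start + 1, td$end),
                 alphabet = "nt")
  attr(out, "zero_length") <- empty
  out
}

#' Serialize a gene model to JSON
#'
#' Coordinates are written 1-based inclusive for human readability (the
#' programmatic contract stays 0-based half-open).
#' @param model A gene model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  td <- tidy(model)
  obj <- list(orf_length_nt = model$length, period_nt = model$period_nt,
              coordinates = "1-based inclusive",
              regions = dplyr::mutate(td, start = .data$start + 1L,
                                      end = .data$end,
                                      length = NULL))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' One-call architecture decomposition of a gene
#'
#' Finds the longest ORF, detects the repeat period, segments the ORF and
#' extracts region sequences.
#'
#' @param x Nucleotide sequence table (single record) or string containing
#'   the gene.
#' @inheritParams detect_period
#' @inheritParams segment_repeats
#' @param both_strands Scan both strands for the ORF.
#' @return List with `orf_interval`, `orf` (string), `period` (scan object),
#'   `model` and `regions`.
#' @export
decompose_gene <- function(x, min_period = 90, max_period = 2100,
                           floor = 0.60, terminal_threshold = 0.5,
                           both_strands = FALSE) {
  orf_iv <- find_longest_orf(x, both_strands = both_strands)
  orf <- interval_seq(x, orf_iv)
  scan <- detect_period(orf, min_period, max_period, floor)
  model <- segment_repeats(orf, scan$period,
                           terminal_threshold = terminal_threshold)
  regions <- extract_regions(model, orf)
  list(orf_interval = orf_iv, orf = orf, period = scan, model = model,
       regions = regions)
}
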