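# Pairwise and region-averaged dN/dS by Nei-Gojobori counting.
#
# Synonymous/nonsynonymous site fractions are enumerated per codon over all
# single-base changes; stop-creating changes are excluded from the
# denominator so the site fractions of each codon still sum to 3.
# Multi-difference codon pairs are averaged over all shortest mutational
# pathways, excluding pathways that pass through a stop codon. Jukes-Cantor
# correction is applied to both proportions; raw proportions are reported
# alongside.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# synonymous and nonsynonymous site counts of one codon (sums to 3)
ng_sites <- function(codon) {
  if (codon %in% STOP_CODONS || grepl("[^ACGT]", codon)) {
    return(c(syn = NA_real_, nonsyn = NA_real_))
  }
  aa0 <- codon_aa(codon)
  syn <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    alts <- setdiff(c("A", "C", "G", "T"), base)
    mut <- vapply(alts, function(b) {
      cc <- codon
      substr(cc, pos, pos) <- b
      cc
    }, "")
    valid <- !(mut %in% STOP_CODONS)
    if (!any(valid)) next
    syn <- syn + sum(codon_aa(mut[valid]) == aa0) / sum(valid)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

ng_sites_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      all_codons <- apply(expand.grid(c("T", "C", "A", "G"),
                                      c("T", "C", "A", "G"),
                                      c("T", "C", "A", "G")), 1, paste,
                          collapse = "")
      tab <- t(vapply(all_codons, ng_sites, c(syn = 0, nonsyn = 0)))
      cache <<- tab
    }
    cache
  }
})

# Average synonymous/nonsynonymous difference counts between two codons
# over all shortest mutational pathways, skipping pathways through stops.
ng_differences <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(pos)
  path_counts <- list()
  for (ord in perms) {
    cur <- c1
    syn <- 0
    nonsyn <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && nxt != c2) {
        blocked <- TRUE
        break
      }
      if (codon_aa(cur) == codon_aa(nxt)) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (!blocked) path_counts[[length(path_counts) + 1]] <- c(syn, nonsyn)
  }
  if (length(path_counts) == 0L) {
    # every pathway passes a stop; fall back to counting through all
    # pathways with stop steps treated as nonsynonymous
    for (ord in perms) {
      cur <- c1
      syn <- 0
      nonsyn <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (codon_aa(cur) == codon_aa(nxt)) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      path_counts[[length(path_counts) + 1]] <- c(syn, nonsyn)
    }
  }
  avg <- Reduce(`+`, path_counts) / length(path_counts)
  c(syn = avg[1], nonsyn = avg[2])
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # correction undefined
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS (Nei-Gojobori counting)
#'
#' @param a,b Codon-aligned coding sequences of equal length (strings or
#'   single-record tables). Codons with a gap or ambiguous base in either
#'   sequence are excluded.
#' @param correction `"jc"` (Jukes-Cantor, default) or `"none"`.
#' @param id Optional label for the pair.
#' @return One-row tibble of class `dnds` with synonymous/nonsynonymous
#'   site counts (`s_sites`, `n_sites`), difference counts (`sd`, `nd`),
#'   raw proportions (`ps`, `pn`), corrected rates (`ds`, `dn`), `ratio`
#'   (`NA` when dS is 0 or the correction is undefined) and `method`.
#' @examples
#' pairwise_dnds("TTTGGG", "TTAGGG")
#' @export
pairwise_dnds <- function(a, b, correction = c("jc", "none"), id = NULL) {
  correction <- match.arg(correction)
  a <- single_seq(a)
  b <- single_seq(b)
  if (nchar(a) != nchar(b)) abort("sequences must be codon-aligned")
  if (nchar(a) %% 3 != 0) abort("aligned length must be a multiple of 3")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  ca <- ca[usable]
  cb <- cb[usable]
  if (length(ca) == 0L) abort("no usable codons in the pair")
  st <- ng_sites_table()
  S <- (sum(st[ca, "syn"]) + sum(st[cb, "syn"])) / 2
  N <- (sum(st[ca, "nonsyn"]) + sum(st[cb, "nonsyn"])) / 2
  diffs <- which(ca != cb)
  sd_ <- 0
  nd_ <- 0
  for (i in diffs) {
    d <- ng_differences(ca[i], cb[i])
    sd_ <- sd_ + d["syn"]
    nd_ <- nd_ + d["nonsyn"]
  }
  ps <- unname(sd_) / S
  pn <- unname(nd_) / N
  if (correction == "jc") {
    ds <- jc_correct(ps)
    dn <- jc_correct(pn)
  } else {
    ds <- ps
    dn <- pn
  }
  ratio <- if (!is.na(ds) && !is.na(dn) && ds > 0) {
    dn / ds
  } else if (!is.na(dn) && dn == 0 && ps > 0) {
    0  # no nonsynonymous change against real synonymous divergence
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    id = id %||% NA_character_, n_codons = length(ca),
    s_sites = S, n_sites = N, sd = unname(sd_), nd = unname(nd_),
    ps = ps, pn = pn, ds = ds, dn = dn, ratio = ratio,
    method = paste0("NG86", if (correction == "jc") "+JC" else ""))
  class(out) <- c("dnds", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Region-averaged dN/dS over all sequence pairs
#'
#' Averages pairwise dN and dS over all pairs of an alignment. The headline
#' summary is the ratio of mean dN to mean dS (robust when single pairs
#' have dS = 0); the mean of pairwise ratios is reported alongside.
#'
#' @param aln Codon-aligned sequence table (>= 2 rows).
#' @param correction See [pairwise_dnds()].
#' @return List of class `dnds_region` with `pairs` (per-pair tibble) and
#'   `summary` (one-row tibble: `mean_dn`, `mean_ds`, `ratio_of_means`,
#'   `mean_of_ratios`, `n_pairs`, `regime`).
#' @export
region_dnds <- function(aln, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  check_seq_tbl(aln)
  if (nrow(aln) < 2L) abort("region dN/dS requires >= 2 sequences")
  if (!is_aligned(aln)) abort("rows must have equal aligned length")
  combos <- utils::combn(nrow(aln), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]
    j <- combos[2, k]
    pairwise_dnds(aln$seq[i], aln$seq[j], correction,
                  id = paste(aln$id[i], aln$id[j], sep = "|"))
  })
  mean_dn <- mean(pairs$dn, na.rm = TRUE)
  mean_ds <- mean(pairs$ds, na.rm = TRUE)
  rom <- if (is.finite(mean_ds) && mean_ds > 0) mean_dn / mean_ds else
    NA_real_
  mor <- if (all(is.na(pairs$ratio))) NA_real_ else
    mean(pairs$ratio, na.rm = TRUE)
  if (is.na(rom)) warn("all pairs undefined; region dN/dS undefined")
  summary <- tibble::tibble(mean_dn = mean_dn, mean_ds = mean_ds,
                            ratio_of_means = rom, mean_of_ratios = mor,
                            n_pairs = nrow(pairs),
                            regime = classify_selection(rom))
  structure(list(pairs = pairs, summary = summary), class = "dnds_region")
}

#' @export
print.dnds_region <- function(x, ...) {
  cat("Region dN/dS (", x$summary$n_pairs, " pairs): ", sep = "")
  cat(sprintf("dN/dS = %.3f (%s)\n", x$summary$ratio_of_means,
              x$summary$regime))
  invisible(x)
}

#' @export
tidy.dnds_region <- function(x, ...) x$pairs

#' @export
glance.dnds_region <- function(x, ...) x$summary

#' Classify a dN/dS ratio into a selection regime
#'
#' Ratios within `neutral_tol` of 1 are called neutral; below, purifying;
#' above, positive. `NA` passes through as `"undefined"`.
#'
#' @param ratio Numeric vector of dN/dS ratios.
#' @param neutral_tol Half-width of the neutral band around 1.
#' @return Character vector over `purifying`, `neutral`, `positive`,
#'   `undefined`.
#' @examples
#' classify_selection(c(0.2, 1, 2.5, NA))
#' @export
classify_selection <- function(ratio, neutral_tol = 0.05) {
  dplyr::case_when(
    is.na(ratio) ~ "undefined",
    abs(ratio - 1) <= neutral_tol ~ "neutral",
    ratio < 1 ~ "purifying",
    TRUE ~ "positive")
}
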