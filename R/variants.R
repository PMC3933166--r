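# Clone-based variant diagnosis: singleton-SNP masking, unsupported-clone
# discard, identity-threshold clustering, and minimum gene-copy inference.
#
# The unit of diagnosis is a clone set: all amplicon clones from one
# individual and one region (N, C or repeat). Singleton SNPs are treated as
# polymerase error; surviving clones are clustered by single linkage on
# percent identical sites, and clusters supported by at least two clones
# become variant calls.

#' Build a clone-set table
#'
#' @param clone_id Unique clone identifiers.
#' @param seq Amplicon sequences.
#' @param individual,species,region Metadata (recycled); `region` must be
#'   one of `"N"`, `"C"`, `"repeat"` and unique within the set.
#' @return Tibble with one row per clone.
#' @export
clone_set <- function(clone_id, seq, individual = "ind1", species = "sp",
                      region = c("N", "C", "repeat")) {
  region <- match.arg(region)
  x <- seq_tbl(id = clone_id, seq = seq, alphabet = "nt")
  tibble::tibble(clone_id = x$id, individual = rep_len(individual, nrow(x)),
                 species = rep_len(species, nrow(x)), region = region,
                 seq = x$seq)
}

#' Mask singleton SNPs as putative polymerase error
#'
#' In every alignment column, a residue carried by exactly one clone while
#' the majority residue is carried by at least two is replaced with the
#' column majority and recorded. Residues shared by two or more clones are
#' never touched. In a 2-clone set every difference is a reciprocal
#' singleton, so masking is skipped with a warning.
#'
#' @param aln Aligned clone sequences (sequence table, >= 2 rows).
#' @return List with `alignment` (masked sequence table) and `mask_report`
#'   (tibble: `clone_id`, `column` 1-based, `original`, `replacement`).
#' @export
mask_singletons <- function(aln) {
  check_seq_tbl(aln)
  if (!is_aligned(aln)) abort("clones must be aligned first")
  empty_report <- tibble::tibble(clone_id = character(),
                                 column = integer(),
                                 original = character(),
                                 replacement = character())
  if (nrow(aln) == 2L) {
    warn(paste("2-clone set: every difference is a reciprocal singleton;",
               "masking skipped"))
    return(list(alignment = aln, mask_report = empty_report,
                skipped = TRUE))
  }
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  report <- list()
  for (k in seq_len(ncol(mat))) {
    tab <- table(mat[, k])
    if (length(tab) < 2L) next
    major <- names(tab)[which.max(tab)]
    if (tab[major] < 2L) next  # no supported majority to restore to
    singles <- names(tab)[tab == 1L]
    for (res in singles) {
      row <- which(mat[, k] == res)
      report[[length(report) + 1]] <- tibble::tibble(
        clone_id = aln$id[row], column = k, original = res,
        replacement = major)
      mat[row, k] <- major
    }
  }
  out <- aln
  out$seq <- apply(mat, 1, paste, collapse = "")
  list(alignment = out,
       mask_report = if (length(report)) dplyr::bind_rows(report)
                     else empty_report,
       skipped = FALSE)
}

#' Discard clones with unsupported polymorphism patterns
#'
#' After masking, a clone is retained only if its residue pattern across
#' all polymorphic columns is identical to at least one other clone's
#' pattern; unique (e.g. chimeric) patterns are discarded.
#'
#' @param aln Masked aligned clone sequences.
#' @return List with `retained` (sequence table) and `discards` (tibble:
#'   `clone_id`, `reason`). If every clone is discarded, `retained` is
#'   empty and a warning is raised.
#' @export
discard_unsupported <- function(aln) {
  check_seq_tbl(aln)
  if (!is_aligned(aln)) abort("clones must be aligned first")
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  poly <- apply(mat, 2, function(col) length(unique(col)) > 1L)
  if (!any(poly)) {
    return(list(retained = aln,
                discards = tibble::tibble(clone_id = character(),
                                          reason = character())))
  }
  pattern <- apply(mat[, poly, drop = FALSE], 1, paste, collapse = "")
  supported <- pattern %in% pattern[duplicated(pattern)]
  discards <- tibble::tibble(
    clone_id = aln$id[!supported],
    reason = "polymorphism pattern not shared by any other clone")
  if (!any(supported)) {
    warn("all clones discarded: no polymorphism pattern is shared")
  }
  list(retained = aln[supported, , drop = FALSE], discards = discards)
}

#' Cluster retained clones into variant calls
#'
#' Single-linkage clustering on pairwise percent identical sites; clones
#' join a cluster when their identity exceeds `threshold_pct`. Clusters
#' supported by a single clone are dropped. Each surviving cluster's
#' majority-rule consensus becomes a variant call.
#'
#' @param aln Retained aligned clones (sequence table).
#' @param threshold_pct Identity threshold in `(50, 100]` (default 95).
#' @param species,individual,region Metadata copied onto the calls.
#' @param gap_policy See [pairwise_identity()].
#' @return Tibble of variant calls: `variant_id`, `region`, `species`,
#'   `individual`, `consensus` (gap-free), `n_support`, `support`
#'   (list-column of clone ids), `within_identity_pct`.
#' @export
cluster_variants <- function(aln, threshold_pct = 95, species = NA,
                             individual = NA, region = NA,
                             gap_policy = "pairwise_deletion") {
  check_seq_tbl(aln)
  if (threshold_pct <= 50 || threshold_pct > 100) {
    abort("threshold_pct must be in (50, 100]")
  }
  empty <- tibble::tibble(variant_id = character(), region = character(),
                          species = character(), individual = character(),
                          consensus = character(), n_support = integer(),
                          support = list(), within_identity_pct = double())
  if (nrow(aln) < 2L) return(empty)
  im <- identity_matrix(aln, gap_policy)
  d <- stats::as.dist(100 - unclass(im))
  hc <- stats::hclust(d, method = "single")
  # merge while identity > threshold, i.e. distance < 100 - threshold
  cl <- stats::cutree(hc, h = (100 - threshold_pct) - 1e-9)
  out <- list()
  v <- 0L
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) < 2L) next  # unsupported: no variant emitted
    sub <- aln[members, , drop = FALSE]
    v <- v + 1L
    cons <- consensus_seq(sub, id = paste0("V", v))
    sub_im <- identity_matrix(sub, gap_policy)
    out[[v]] <- tibble::tibble(
      variant_id = paste0("V", v), region = as.character(region),
      species = as.character(species), individual = as.character(individual),
      consensus = gsub("-", "", cons$seq), n_support = length(members),
      support = list(aln$id[members]),
      within_identity_pct = mean_offdiag(sub_im))
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Minimum gene-copy number consistent with a variant count
#'
#' A diploid individual carries at most `ploidy` alleles per locus, so `n`
#' distinct variants require at least `ceiling(n / ploidy)` loci.
#'
#' @param n_variants Non-negative variant count.
#' @param ploidy Number of allele slots per locus (default 2).
#' @return Integer minimum locus count.
#' @examples
#' min_loci(7)  # 4
#' @export
min_loci <- function(n_variants, ploidy = 2) {
  if (any(ploidy < 1)) abort("ploidy must be >= 1")
  if (any(n_variants < 0)) abort("n_variants must be >= 0")
  as.integer(ceiling(n_variants / ploidy))
}

#' Diagnose variants from a clone set
#'
#' Full pipeline: align clones, mask singleton SNPs, discard unsupported
#' patterns, cluster at the identity threshold, and infer the minimum locus
#' count. The masking/discard order can be flipped for sensitivity
#' analysis.
#'
#' @param clones A [clone_set()] tibble (one individual, one region).
#' @param threshold_pct Clustering threshold, percent identical sites.
#' @param ploidy Allele slots per locus.
#' @param mask_first Mask singletons before the unsupported-pattern discard
#'   (the default order).
#' @param gap_policy See [pairwise_identity()].
#' @return Object of class `variant_diagnosis`: list with `variants`,
#'   `mask_report`, `discards`, `min_loci`, `alignment` and `params`.
#'   `tidy()` returns the variant calls; `glance()` a one-row summary.
#' @export
diagnose_variants <- function(clones, threshold_pct = 95, ploidy = 2,
                              mask_first = TRUE,
                              gap_policy = "pairwise_deletion") {
  stopifnot(is.data.frame(clones),
            all(c("clone_id", "seq", "region") %in% names(clones)))
  if (length(unique(clones$region)) != 1L) {
    abort("a clone set must cover exactly one region")
  }
  x <- seq_tbl(id = clones$clone_id, seq = clones$seq, alphabet = "nt")
  empty_report <- tibble::tibble(clone_id = character(), column = integer(),
                                 original = character(),
                                 replacement = character())
  if (nrow(x) < 2L) {
    warn("fewer than 2 clones: no variant can be supported")
    return(structure(list(
      variants = cluster_variants(x[0, ], threshold_pct),
      mask_report = empty_report,
      discards = tibble::tibble(clone_id = x$id,
                                reason = "single clone, unsupported"),
      min_loci = min_loci(0, ploidy), alignment = x[0, ],
      params = list(threshold_pct = threshold_pct, ploidy = ploidy,
                    mask_first = mask_first, gap_policy = gap_policy)
    ), class = "variant_diagnosis"))
  }
  aln <- if (length(unique(nchar(x$seq))) == 1L) x else align_seqs(x)

  if (mask_first) {
    masked <- mask_singletons(aln)
    kept <- discard_unsupported(masked$alignment)
  } else {
    kept0 <- discard_unsupported(aln)
    masked <- if (nrow(kept0$retained) >= 2L)
      mask_singletons(kept0$retained)
    else list(alignment = kept0$retained,
              mask_report = tibble::tibble(clone_id = character(),
                                           column = integer(),
                                           original = character(),
                                           replacement = character()))
    kept <- list(retained = masked$alignment, discards = kept0$discards)
  }
  variants <- cluster_variants(
    kept$retained, threshold_pct = threshold_pct,
    species = clones$species[1] %||% NA,
    individual = clones$individual[1] %||% NA,
    region = clones$region[1], gap_policy = gap_policy)
  if (nrow(variants) == 0L) warn("no supported variants found")
  structure(list(
    variants = variants, mask_report = masked$mask_report,
    discards = kept$discards, min_loci = min_loci(nrow(variants), ploidy),
    alignment = kept$retained,
    params = list(threshold_pct = threshold_pct, ploidy = ploidy,
                  mask_first = mask_first, gap_policy = gap_policy)
  ), class = "variant_diagnosis")
}

#' @export
print.variant_diagnosis <- function(x, ...) {
  cat("Variant diagnosis:", nrow(x$variants), "variant(s),",
      nrow(x$mask_report), "masked singleton(s),",
      nrow(x$discards), "discard(s); minimum loci:", x$min_loci, "\n")
  invisible(x)
}

#' @export
tidy.variant_diagnosis <- function(x, ...) x$variants

#' @export
glance.variant_diagnosis <- function(x, ...) {
  tibble::tibble(n_clones = nrow(x$alignment) + nrow(x$discards),
                 n_masked = nrow(x$mask_report),
                 n_discarded = nrow(x$discards),
                 n_variants = nrow(x$variants),
                 min_loci = x$min_loci)
}
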