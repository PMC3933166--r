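# Forward simulator: spidroin-like genes, multi-locus diploid genomes under
# point mutation + intragenic gene conversion, and PCR clone sets with
# polymerase error. Every stage records its ground truth so downstream
# modules can be scored against it.
#
# Gene conversion is modeled as whole-repeat-unit copy-paste between two
# random repeat units of the same gene copy; terminal regions never convert
# (they have no repeat partner). Mutations are uniform per base per
# generation, with an optional terminal-rate multiplier and a
# synonymous-bias knob that redirects a stated fraction of coding mutations
# to synonymous alternatives.

BASES <- c("A", "C", "G", "T")

#' Simulation parameters
#'
#' Defaults mirror the architecture of an aciniform spidroin gene: a 612 nt
#' repeat unit iterated 20 times between a 510 nt N-terminal and a 330 nt
#' C-terminal coding region, diploid genomes, and a per-base PCR error rate
#' of 5e-4 per clone.
#'
#' @param repeat_len_nt Repeat unit length (multiple of 3).
#' @param n_repeats Number of repeat units.
#' @param n_term_len,c_term_len Terminal coding-region lengths (multiples
#'   of 3, including the start and stop codon respectively).
#' @param last_repeat_len_nt Length of a truncated final repeat, or `NULL`
#'   for a full-length final unit.
#' @param flank_len_nt Non-coding flank simulated on each side of the ORF.
#' @param n_loci Gene copies per haploid genome.
#' @param ploidy Allele slots per locus.
#' @param mutation_rate Per-base per-generation substitution probability in
#'   the repeat region.
#' @param terminal_rate_multiplier Terminal mutation rate relative to the
#'   repeat region.
#' @param conversion_events Mean whole-unit gene-conversion events per gene
#'   copy per generation (Poisson).
#' @param n_generations Generations of evolution.
#' @param synonymous_bias Fraction of coding mutations redirected to a
#'   synonymous alternative at the same site when one exists.
#' @param pcr_error_rate Per-base error probability per clone.
#' @param clones_per_template Clones sequenced per template.
#' @param composition_skew Weight serine/alanine/glycine codons more
#'   heavily when drawing the ancestral sequence, mimicking silk
#'   composition.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(repeat_len_nt = 612, n_repeats = 20,
                       n_term_len = 510, c_term_len = 330,
                       last_repeat_len_nt = NULL, flank_len_nt = 300,
                       n_loci = 2, ploidy = 2,
                       mutation_rate = 1e-4, terminal_rate_multiplier = 5,
                       conversion_events = 1, n_generations = 200,
                       synonymous_bias = 0, pcr_error_rate = 5e-4,
                       clones_per_template = 6, composition_skew = TRUE) {
  p <- list(repeat_len_nt = repeat_len_nt, n_repeats = n_repeats,
            n_term_len = n_term_len, c_term_len = c_term_len,
            last_repeat_len_nt = last_repeat_len_nt,
            flank_len_nt = flank_len_nt, n_loci = n_loci, ploidy = ploidy,
            mutation_rate = mutation_rate,
            terminal_rate_multiplier = terminal_rate_multiplier,
            conversion_events = conversion_events,
            n_generations = n_generations,
            synonymous_bias = synonymous_bias,
            pcr_error_rate = pcr_error_rate,
            clones_per_template = clones_per_template,
            composition_skew = composition_skew)
  for (f in c("repeat_len_nt", "n_term_len", "c_term_len")) {
    if (p[[f]] <= 0 || p[[f]] %% 3 != 0) {
      abort(paste0(f, " must be a positive multiple of 3"))
    }
  }
  if (!is.null(p$last_repeat_len_nt) &&
      (p$last_repeat_len_nt <= 0 || p$last_repeat_len_nt %% 3 != 0 ||
       p$last_repeat_len_nt > p$repeat_len_nt)) {
    abort("last_repeat_len_nt must be a positive multiple of 3 <= repeat_len_nt")
  }
  for (f in c("mutation_rate", "synonymous_bias", "pcr_error_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (p$n_repeats < 2) abort("n_repeats must be >= 2")
  if (p$ploidy < 1) abort("ploidy must be >= 1")
  structure(p, class = "sim_params")
}

# codon pool without stops; optionally skewed toward Ser/Ala/Gly
codon_pool <- function(skew) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  w <- rep(1, length(codons))
  if (skew) {
    aa <- unname(gc[codons])
    w[aa == "S"] <- 8
    w[aa == "A"] <- 8
    w[aa == "G"] <- 6
    w[aa == "Q"] <- 3
  }
  list(codons = codons, weights = w / sum(w))
}

random_codons <- function(n, pool) {
  sample(pool$codons, n, replace = TRUE, prob = pool$weights)
}

#' Simulate a spidroin-like gene
#'
#' Grows a repeat array by tandem duplication of one random ancestral unit
#' and flanks it with random non-repetitive terminal coding regions, then
#' with non-coding flanks. The ORF starts with ATG, ends with a stop codon,
#' and contains no internal stops; a stop codon is planted in frame at the
#' end of the 5' flank so the ORF start is unambiguous.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed (deterministic output per seed).
#' @return List with `gene` (sequence table), `orf` (string), `truth`
#'   (list: `model` tibble of true region intervals in ORF coordinates,
#'   `unit` ancestral repeat, `orf_interval` in gene coordinates, and the
#'   parameters).
#' @export
simulate_gene <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  pool <- codon_pool(params$composition_skew)
  unit <- paste(random_codons(params$repeat_len_nt / 3, pool),
                collapse = "")
  n_term <- paste0("ATG", paste(random_codons(params$n_term_len / 3 - 1,
                                              pool), collapse = ""))
  c_term <- paste0(paste(random_codons(params$c_term_len / 3 - 1, pool),
                         collapse = ""), "TAA")
  reps <- rep(unit, params$n_repeats)
  if (!is.null(params$last_repeat_len_nt)) {
    reps[params$n_repeats] <- substr(unit, 1, params$last_repeat_len_nt)
  }
  # terminals are non-repetitive by definition, so keep the junction codons
  # distinct from the adjacent repeat codons: otherwise the true boundary
  # is ambiguous and architecture truth is ill-defined
  ul <- nchar(unit)
  while (substr(n_term, nchar(n_term) - 2, nchar(n_term)) ==
         substr(unit, ul - 2, ul)) {
    substr(n_term, nchar(n_term) - 2, nchar(n_term)) <-
      random_codons(1, pool)
  }
  last_len <- nchar(reps[params$n_repeats])
  next_codon <- substr(paste0(unit, unit), last_len + 1, last_len + 3)
  while (substr(c_term, 1, 3) == next_codon) {
    substr(c_term, 1, 3) <- random_codons(1, pool)
  }
  orf <- paste0(n_term, paste(reps, collapse = ""), c_term)
  fl <- params$flank_len_nt
  flank5 <- if (fl > 0) {
    paste0(paste(sample(BASES, max(fl - 3, 0), replace = TRUE),
                 collapse = ""), "TAA")  # in-frame stop guards the ORF start
  } else ""
  flank3 <- if (fl > 0) paste(sample(BASES, fl, replace = TRUE),
                              collapse = "") else ""
  gene_seq <- paste0(flank5, orf, flank3)
  rep_len <- nchar(reps)
  rep_start <- params$n_term_len + c(0, cumsum(rep_len[-length(rep_len)]))
  model <- dplyr::bind_rows(
    tibble::tibble(region = "n_term", start = 0L,
                   end = params$n_term_len),
    tibble::tibble(region = paste0("R", seq_len(params$n_repeats)),
                   start = as.integer(rep_start),
                   end = as.integer(rep_start + rep_len)),
    tibble::tibble(region = "c_term",
                   start = as.integer(params$n_term_len + sum(rep_len)),
                   end = as.integer(nchar(orf))))
  list(
    gene = seq_tbl(id = "sim_gene", seq = gene_seq, alphabet = "nt",
                   description = "synthetic spidroin-like gene"),
    orf = orf,
    truth = list(model = model, unit = unit,
                 orf_interval = tibble::tibble(start = nchar(flank5),
                                               end = nchar(flank5) +
                                                 nchar(orf), strand = "+"),
                 params = params, seed = seed))
}

# point mutation of a character vector; returns the mutated vector and the
# 1-based positions hit. With avoid_stop, mutations that would write an
# in-frame stop codon are rejected (an intact ORF is a survival condition
# for a functional gene copy); PCR errors are applied without it.
mutate_chars <- function(chars, rate, syn_bias = 0, frame_offset = 0,
                         avoid_stop = FALSE) {
  L <- length(chars)
  n_mut <- stats::rbinom(1, L, rate)
  if (n_mut == 0L) return(list(chars = chars, positions = integer()))
  pos <- sample.int(L, n_mut)
  hit <- logical(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    alts <- setdiff(BASES, chars[p])
    if (syn_bias > 0 && stats::runif(1) < syn_bias) {
      # this mutation is constrained to be synonymous; sites with no
      # synonymous alternative reject it
      alts <- synonymous_alts(chars, p, frame_offset)
      if (length(alts) == 0L) next
    } else if (avoid_stop) {
      alts <- alts[!vapply(alts, function(b) {
        makes_stop(chars, p, b, frame_offset)
      }, TRUE)]
      if (length(alts) == 0L) next
    }
    chars[p] <- if (length(alts) == 1L) alts else sample(alts, 1)
    hit[i] <- TRUE
  }
  list(chars = chars, positions = pos[hit])
}

makes_stop <- function(chars, p, base, frame_offset) {
  idx0 <- p - 1 + frame_offset
  cstart <- p - idx0 %% 3
  if (cstart < 1 || cstart + 2 > length(chars)) return(FALSE)
  codon <- paste(chars[cstart:(cstart + 2)], collapse = "")
  substr(codon, p - cstart + 1, p - cstart + 1) <- base
  codon %in% STOP_CODONS
}

# alternatives at position p (1-based within chars) keeping the encoded
# amino acid, given the reading frame offset of chars[1]
synonymous_alts <- function(chars, p, frame_offset) {
  idx0 <- p - 1 + frame_offset
  cstart <- p - idx0 %% 3
  if (cstart < 1 || cstart + 2 > length(chars)) return(character())
  codon <- paste(chars[cstart:(cstart + 2)], collapse = "")
  if (grepl("[^ACGT]", codon)) return(character())
  aa0 <- codon_aa(codon)
  within <- p - cstart + 1
  alts <- setdiff(BASES, chars[p])
  keep <- vapply(alts, function(b) {
    cc <- codon
    substr(cc, within, within) <- b
    !(cc %in% STOP_CODONS) && codon_aa(cc) == aa0
  }, TRUE)
  alts[keep]
}

#' Evolve a gene into multi-locus diploid genomes
#'
#' Duplicates the simulated gene into `n_loci * ploidy` independent copies
#' and evolves each for `n_generations`: point mutations every generation
#' (terminals at `terminal_rate_multiplier` times the repeat-region rate)
#' and Poisson-distributed whole-unit gene conversion between random repeat
#' pairs of the same copy. Conversion uses the true unit boundaries, which
#' stay fixed because no indels are simulated.
#'
#' @param gene Output of [simulate_gene()].
#' @param params A [sim_params()] list (may differ from the gene's).
#' @param seed Integer seed.
#' @return List with `genomes` (tibble: `locus`, `allele`, `copy_id`,
#'   `seq` — the evolved ORFs) and `truth` (true region model shared by all
#'   copies, parameters, seed).
#' @export
evolve_loci <- function(gene, params = gene$truth$params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  model <- gene$truth$model
  rep_rows <- grepl("^R\\d+$", model$region)
  rep_iv <- model[rep_rows, ]
  nt_iv <- model[model$region == "n_term", ]
  ct_iv <- model[model$region == "c_term", ]
  # the start codon and the terminal stop codon never mutate: losing either
  # destroys the ORF, which a functional gene copy cannot survive
  nt_span <- if (nt_iv$end > nt_iv$start + 3)
    seq(nt_iv$start + 4, nt_iv$end) else integer(0)
  ct_span <- if (ct_iv$end - 3 > ct_iv$start)
    seq(ct_iv$start + 1, ct_iv$end - 3) else integer(0)
  n_copies <- params$n_loci * params$ploidy
  copies <- replicate(n_copies, strsplit(gene$orf, "")[[1]],
                      simplify = FALSE)
  mu <- params$mutation_rate
  mu_t <- min(1, mu * params$terminal_rate_multiplier)
  for (g in seq_len(params$n_generations)) {
    for (i in seq_len(n_copies)) {
      chars <- copies[[i]]
      # repeat region + terminals mutated at their own rates
      rep_span <- seq(rep_iv$start[1] + 1, rep_iv$end[nrow(rep_iv)])
      mr <- mutate_chars(chars[rep_span], mu, params$synonymous_bias,
                         frame_offset = rep_iv$start[1], avoid_stop = TRUE)
      chars[rep_span] <- mr$chars
      m5 <- mutate_chars(chars[nt_span], mu_t, frame_offset = 0,
                         avoid_stop = TRUE)
      chars[nt_span] <- m5$chars
      m3 <- mutate_chars(chars[ct_span], mu_t, frame_offset = 0,
                         avoid_stop = TRUE)
      chars[ct_span] <- m3$chars
      # gene conversion: whole-unit copy-paste within this copy
      n_conv <- stats::rpois(1, params$conversion_events)
      if (n_conv > 0 && nrow(rep_iv) >= 2) {
        for (k in seq_len(n_conv)) {
          pair <- sample.int(nrow(rep_iv), 2)
          don <- seq(rep_iv$start[pair[1]] + 1, rep_iv$end[pair[1]])
          acc <- seq(rep_iv$start[pair[2]] + 1, rep_iv$end[pair[2]])
          n <- min(length(don), length(acc))  # truncated last unit
          chars[acc[seq_len(n)]] <- chars[don[seq_len(n)]]
        }
      }
      copies[[i]] <- chars
    }
  }
  genomes <- tibble::tibble(
    locus = rep(seq_len(params$n_loci), each = params$ploidy),
    allele = rep(seq_len(params$ploidy), times = params$n_loci),
    copy_id = paste0("L", rep(seq_len(params$n_loci),
                              each = params$ploidy), "a",
                     rep(seq_len(params$ploidy), times = params$n_loci)),
    seq = vapply(copies, paste, "", collapse = ""))
  list(genomes = genomes,
       truth = list(model = model, params = params, seed = seed,
                    ancestor = gene$orf))
}

#' Simulate PCR clone sets from template sequences
#'
#' Each template yields `clones_per_template` clones; every clone carries
#' independent uniform base errors at `pcr_error_rate`, recorded in the
#' truth table.
#'
#' @param templates Tibble with `template_id`, `seq` and optionally
#'   `region`, `species`, `individual`.
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return List with `clones` (clone-set tibble including the true
#'   `template_id` of each clone) and `truth` (`errors` tibble: `clone_id`,
#'   `position`, `original`, `observed`).
#' @export
simulate_clones <- function(templates, params = sim_params(), seed = 1) {
  stopifnot(is.data.frame(templates),
            all(c("template_id", "seq") %in% names(templates)))
  set.seed(seed)
  out <- list()
  errs <- list()
  for (i in seq_len(nrow(templates))) {
    tpl <- templates[i, ]
    for (j in seq_len(params$clones_per_template)) {
      cid <- paste0(tpl$template_id, "_c", j)
      chars <- strsplit(tpl$seq, "")[[1]]
      m <- mutate_chars(chars, params$pcr_error_rate)
      if (length(m$positions) > 0) {
        errs[[length(errs) + 1]] <- tibble::tibble(
          clone_id = cid, position = sort(m$positions),
          original = strsplit(tpl$seq, "")[[1]][sort(m$positions)],
          observed = m$chars[sort(m$positions)])
      }
      col_or <- function(nm, default) {
        if (nm %in% names(templates)) tpl[[nm]] else default
      }
      out[[length(out) + 1]] <- tibble::tibble(
        clone_id = cid,
        individual = col_or("individual", "ind1"),
        species = col_or("species", "sp"),
        region = col_or("region", "C"),
        template_id = tpl$template_id,
        seq = paste(m$chars, collapse = ""))
    }
  }
  list(clones = dplyr::bind_rows(out),
       truth = list(errors = if (length(errs)) dplyr::bind_rows(errs)
                    else tibble::tibble(clone_id = character(),
                                        position = integer(),
                                        original = character(),
                                        observed = character()),
                    seed = seed))
}

#' Extract region templates from evolved genomes
#'
#' The distinct sequences of one region across an individual's gene copies
#' are the templates a PCR survey would amplify.
#'
#' @param genomes Output of [evolve_loci()].
#' @param region `"N"`, `"C"` or `"repeat"`.
#' @return Tibble with `template_id`, `region`, `seq` and the contributing
#'   `copy_ids` (list-column).
#' @export
region_templates <- function(genomes, region = c("N", "C", "repeat")) {
  region <- match.arg(region)
  model <- genomes$truth$model
  iv <- switch(region,
               N = model[model$region == "n_term", ],
               C = model[model$region == "c_term", ],
               `repeat` = {
                 rr <- model[grepl("^R\\d+$", model$region), ]
                 tibble::tibble(start = rr$start[1], end = rr$end[nrow(rr)])
               })
  seqs <- substring(genomes$genomes$seq, iv$start + 1, iv$end)
  uniq <- unique(seqs)
  tibble::tibble(
    template_id = paste0(region, "_t", seq_along(uniq)),
    region = region, seq = uniq,
    copy_ids = purrr::map(uniq,
                          ~ genomes$genomes$copy_id[seqs == .x]))
}

#' End-to-end synthetic study
#'
#' Simulates a gene, evolves it into a multi-locus diploid genome, extracts
#' the region templates of one individual, and sequences PCR clones from
#' them — the full ground-truth counterpart of a clone survey.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed; stage seeds are derived from it.
#' @param region Region to survey.
#' @return List with `gene`, `genomes`, `templates`, `clones` and the
#'   combined `truth`.
#' @export
simulate_study <- function(params = sim_params(), seed = 1,
                           region = c("C", "N", "repeat")) {
  region <- match.arg(region)
  gene <- simulate_gene(params, seed = seed)
  genomes <- evolve_loci(gene, params, seed = seed + 1000L)
  templates <- region_templates(genomes, region)
  templates$individual <- "ind1"
  templates$species <- "sim_sp"
  clones <- simulate_clones(templates, params, seed = seed + 2000L)
  list(gene = gene, genomes = genomes, templates = templates,
       clones = clones$clones,
       truth = list(gene = gene$truth, errors = clones$truth$errors,
                    n_templates = nrow(templates),
                    true_loci = params$n_loci))
}
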