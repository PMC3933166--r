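# One-call orchestration: decompose -> homogeneity -> variants -> dN/dS ->
# trees -> report bundle. All defaults mirror the package-wide conventions
# (95% clustering threshold, diploid ploidy, 50% terminal boundary, 0.60
# period floor) and the resolved configuration is serialized next to the
# outputs so a bundle is self-describing.

#' Assemble a run configuration
#'
#' @param gene_fasta Path to a FASTA with the gene (or ORF) to decompose.
#' @param clones_fasta Optional FASTA of amplicon clones.
#' @param clones_meta Optional TSV with columns `clone_id`, `individual`,
#'   `species`, `region` describing the clones.
#' @param out_dir Output directory (created if absent).
#' @param cluster_threshold_pct Variant clustering threshold.
#' @param terminal_threshold Terminal/repeat boundary identity threshold.
#' @param period_floor Minimum self-identity for tandem detection.
#' @param min_period,max_period Period search range (nt).
#' @param gap_policy Identity gap policy for all identity computations.
#' @param ploidy Ploidy for minimum-locus inference.
#' @param bootstrap_reps NJ bootstrap replicates (0 disables supports).
#' @param seed Seed for the bootstrap.
#' @return A validated `run_config` list.
#' @export
run_config <- function(gene_fasta, clones_fasta = NULL, clones_meta = NULL,
                       out_dir = tempfile("spidrhom_run_"),
                       cluster_threshold_pct = 95,
                       terminal_threshold = 0.5, period_floor = 0.60,
                       min_period = 90, max_period = 2100,
                       gap_policy = "pairwise_deletion", ploidy = 2,
                       bootstrap_reps = 0, seed = 1) {
  cfg <- list(gene_fasta = gene_fasta, clones_fasta = clones_fasta,
              clones_meta = clones_meta, out_dir = out_dir,
              cluster_threshold_pct = cluster_threshold_pct,
              terminal_threshold = terminal_threshold,
              period_floor = period_floor, min_period = min_period,
              max_period = max_period, gap_policy = gap_policy,
              ploidy = ploidy, bootstrap_reps = bootstrap_reps, seed = seed)
  if (cfg$cluster_threshold_pct <= 50 || cfg$cluster_threshold_pct > 100) {
    abort("cluster_threshold_pct must be in (50, 100]")
  }
  if (cfg$terminal_threshold <= 0 || cfg$terminal_threshold >= 1) {
    abort("terminal_threshold must be in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Decomposes the gene into its architecture, quantifies repeat
#' homogenization (identity matrix, consensus, codon usage, composition),
#' optionally diagnoses variants from clone sets and estimates region
#' dN/dS, builds NJ trees, and writes a report bundle: gene model JSON,
#' identity/profile/dN/dS TSVs, variants FASTA + TSV, newick trees, a
#' plain-text summary and the resolved config YAML. Two runs with the same
#' config and inputs produce identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects and the output file
#'   manifest; errors name the failing stage.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$gene_fasta)) {
    abort(paste0("stage decompose: input file not found: ",
                 config$gene_fasta))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  emit <- function(name) {
    path <- file.path(config$out_dir, name)
    manifest <<- c(manifest, path)
    path
  }
  yaml::write_yaml(unclass(config), emit("config.yaml"))

  # -- decompose ------------------------------------------------------
  gene <- read_fasta(config$gene_fasta, alphabet = "nt")[1, ]
  dec <- decompose_gene(gene, min_period = config$min_period,
                        max_period = config$max_period,
                        floor = config$period_floor,
                        terminal_threshold = config$terminal_threshold)
  write_gene_model(dec$model, emit("gene_model.json"))
  reps <- dec$regions[grepl("^R\\d+$", dec$regions$id), ]
  write_fasta(reps, emit("repeat_units.fasta"))

  # -- homogeneity ----------------------------------------------------
  rep_aln <- align_seqs(reps, mode = "codon")
  im <- identity_matrix(rep_aln, config$gap_policy)
  readr::write_tsv(tidy(im), emit("repeat_identity.tsv"))
  cons <- consensus_seq(rep_aln, id = "repeat_consensus")
  write_fasta(cons, emit("repeat_consensus.fasta"))
  orf_tbl <- seq_tbl("orf", dec$orf, alphabet = "nt")
  protein <- translate_seq(orf_tbl)
  protein$seq <- sub("\\*$", "", protein$seq)
  comp <- aa_composition(protein)
  readr::write_tsv(comp, emit("composition.tsv"))
  cu <- codon_usage(dec$orf)
  readr::write_tsv(cu, emit("codon_usage.tsv"))
  gcw <- gcw_fraction(cu)

  # -- variants + selection + trees (optional) ------------------------
  diagnoses <- NULL
  dnds <- NULL
  if (!is.null(config$clones_fasta)) {
    if (!file.exists(config$clones_fasta)) {
      abort(paste0("stage variants: input file not found: ",
                   config$clones_fasta))
    }
    clones <- read_fasta(config$clones_fasta, alphabet = "nt")
    meta <- if (!is.null(config$clones_meta)) {
      readr::read_tsv(config$clones_meta, show_col_types = FALSE)
    } else {
      parse_clone_headers(clones)
    }
    cl <- dplyr::inner_join(
      dplyr::rename(clones, clone_id = "id"), meta, by = "clone_id")
    groups <- dplyr::group_split(cl, .data$individual, .data$region)
    diagnoses <- purrr::map(groups, function(g) {
      diagnose_variants(g, threshold_pct = config$cluster_threshold_pct,
                        ploidy = config$ploidy,
                        gap_policy = config$gap_policy)
    })
    all_variants <- purrr::map_dfr(diagnoses, tidy)
    if (nrow(all_variants) > 0) {
      readr::write_tsv(
        dplyr::mutate(all_variants,
                      support = purrr::map_chr(.data$support, paste,
                                               collapse = ",")),
        emit("variants.tsv"))
      vf <- seq_tbl(id = paste(all_variants$individual,
                               all_variants$region,
                               all_variants$variant_id, sep = "_"),
                    seq = all_variants$consensus, alphabet = "nt")
      write_fasta(vf, emit("variants.fasta"))
      # region dN/dS over variant consensuses where >= 2 codon-sized
      dnds <- purrr::map_dfr(split(all_variants, all_variants$region),
                             function(g) {
        if (nrow(g) < 2) return(NULL)
        x <- seq_tbl(id = paste0(g$individual, "_", g$variant_id),
                     seq = g$consensus, alphabet = "nt")
        x$seq <- substr(x$seq, 1, (nchar(x$seq) %/% 3) * 3)
        aln <- if (length(unique(nchar(x$seq))) == 1L) x
               else align_seqs(x, mode = "codon")
        est <- region_dnds(aln)
        dplyr::mutate(glance(est), region = g$region[1],
                      .before = 1)
      })
      if (!is.null(dnds) && nrow(dnds) > 0) {
        readr::write_tsv(dnds, emit("dnds.tsv"))
      }
      # NJ tree of variants per region (needs >= 3)
      for (rg in unique(all_variants$region)) {
        g <- all_variants[all_variants$region == rg, ]
        if (nrow(g) >= 3) {
          x <- seq_tbl(id = paste0(g$individual, "_", g$variant_id),
                       seq = g$consensus, alphabet = "nt")
          aln <- if (length(unique(nchar(x$seq))) == 1L) x
                 else align_seqs(x)
          tr <- if (config$bootstrap_reps > 0) {
            bootstrap_support(aln, config$bootstrap_reps,
                              seed = config$seed,
                              gap_policy = config$gap_policy)
          } else {
            nj_tree(p_distance_matrix(aln, config$gap_policy))
          }
          write_newick(tr, emit(paste0("variants_", rg, ".nwk")))
        }
      }
    }
  }

  # -- summary --------------------------------------------------------
  gm <- glance(dec$model)
  lines <- c(
    "spidrhom run summary",
    "====================",
    sprintf("ORF length: %d nt (%d aa + stop)", gm$orf_length_nt,
            gm$orf_length_nt / 3 - 1),
    sprintf("Repeat period: %d nt", gm$period_nt),
    sprintf("Repeat units: %d (last %d nt)", gm$n_repeats,
            gm$last_repeat_nt),
    sprintf("Terminals: n_term %d nt, c_term %d nt", gm$n_term_nt,
            gm$c_term_nt),
    sprintf("Mean off-diagonal repeat identity: %.1f%%", mean_offdiag(im)),
    sprintf("Most abundant residue: %s (%.1f%%)", comp$residue[1],
            comp$percent[1]),
    sprintf("Alanine GCW codon fraction: %s",
            if (is.na(gcw)) "undefined" else sprintf("%.1f%%", 100 * gcw)))
  if (!is.null(diagnoses)) {
    gl <- purrr::map_dfr(diagnoses, glance)
    lines <- c(lines,
               sprintf("Clone sets diagnosed: %d", length(diagnoses)),
               sprintf("Variants: %s; minimum loci: %s",
                       paste(gl$n_variants, collapse = "/"),
                       paste(gl$min_loci, collapse = "/")))
  }
  writeLines(lines, emit("summary.txt"))
  invisible(list(decomposition = dec, identity = im, composition = comp,
                 codon_usage = cu, gcw_fraction = gcw,
                 diagnoses = diagnoses, dnds = dnds, manifest = manifest))
}

# structured FASTA headers: >cloneID|species|individual|region
parse_clone_headers <- function(clones) {
  parts <- strsplit(clones$id, "|", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    abort(paste("clone metadata absent and headers are not",
                "cloneID|species|individual|region"))
  }
  tibble::tibble(clone_id = clones$id,
                 species = purrr::map_chr(parts, 2),
                 individual = purrr::map_chr(parts, 3),
                 region = purrr::map_chr(parts, 4))
}
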