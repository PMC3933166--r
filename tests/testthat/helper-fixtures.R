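# Small fixture builders shared across test files.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# point-mutate k positions of a sequence (substitutions only)
mutate_k <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA, ch[p]), 1)
  paste(ch, collapse = "")
}

rand_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# templates for variant-diagnosis simulations: mutually < 95% identical so
# the clustering threshold can in principle separate every pair
make_templates <- function(n, len, div, region = "C") {
  repeat {
    base <- rand_seq(len)
    seqs <- vapply(seq_len(n), function(i) {
      mutate_k(base, max(2, round(div * len)))
    }, "")
    if (n < 2) break
    im <- identity_matrix(seq_tbl(paste0("t", seq_len(n)), seqs))
    if (max(im[upper.tri(im)]) < 94.8) break
  }
  tibble::tibble(template_id = paste0("t", seq_len(n)), region = region,
                 seq = seqs)
}

write_tmp_fasta <- function(x) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(x, path)
  path
}

model_matches_truth <- function(model_tidy, truth) {
  isTRUE(all.equal(unname(as.matrix(model_tidy[, c("start", "end")]) * 1.0),
                   unname(as.matrix(truth[, c("start", "end")]) * 1.0))) &&
    identical(model_tidy$region, truth$region)
}
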