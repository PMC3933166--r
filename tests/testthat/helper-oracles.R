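# Independent oracles used to check the package implementations.

# Brute-force Needleman-Wunsch score, linear gap penalty. Used to check the
# Gotoh aligner with gap_open == gap_ext.
nw_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n)
  f[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      f[i + 1, j + 1] <- max(f[i, j] + s, f[i, j + 1] + gap,
                             f[i + 1, j] + gap)
    }
  }
  f[n + 1, m + 1]
}

# Exhaustive Nei-Gojobori oracle: site fractions by looping over every
# position and base; difference counts by enumerating every ordering of the
# differing positions and walking each pathway, skipping those through stop
# codons. Kept deliberately plain (nested loops, no caching).
GC <- Biostrings::GENETIC_CODE
STOPS <- names(GC)[GC == "*"]

oracle_sites <- function(codon) {
  syn <- 0
  total <- 0
  for (pos in 1:3) {
    nsyn_pos <- 0
    nvalid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (alt %in% STOPS) next
      nvalid <- nvalid + 1
      if (GC[[alt]] == GC[[codon]]) nsyn_pos <- nsyn_pos + 1
    }
    if (nvalid > 0) syn <- syn + nsyn_pos / nvalid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

oracle_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    out <- list()
    rec <- function(prefix, left) {
      if (length(left) == 0) out[[length(out) + 1]] <<- prefix
      for (i in seq_along(left)) rec(c(prefix, left[i]), left[-i])
    }
    rec(integer(), pos)
    out
  }
  acc <- list()
  for (ord in perms) {
    cur <- c1
    sy <- 0
    ns <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOPS && nxt != c2) {
        ok <- FALSE
        break
      }
      if (GC[[cur]] == GC[[nxt]]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) acc[[length(acc) + 1]] <- c(sy, ns)
  }
  if (length(acc) == 0) {
    for (ord in perms) {
      cur <- c1
      sy <- 0
      ns <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GC[[cur]] == GC[[nxt]]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      acc[[length(acc) + 1]] <- c(sy, ns)
    }
  }
  m <- Reduce(`+`, acc) / length(acc)
  c(syn = m[1], nonsyn = m[2])
}

oracle_dnds_raw <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- !(ca %in% STOPS) & !(cb %in% STOPS) &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]
  cb <- cb[keep]
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i])
    sb <- oracle_sites(cb[i])
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d["syn"]
    Nd <- Nd + d["nonsyn"]
  }
  c(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
    ps = unname(Sd / S), pn = unname(Nd / N))
}
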