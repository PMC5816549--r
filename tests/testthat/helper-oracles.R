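# Independent oracles, written separately from the package implementation:
# a brute-force all-substrings motif scanner and an enumeration-based
# Nei-Gojobori counter (translation via seqinr, explicit recursion over
# substitution pathways).

oracle_scan <- function(sequence, class) {
  chars <- strsplit(sequence, "")[[1L]]
  len <- length(chars)
  is_hit <- function(i) {
    switch(class,
      SP3 = i + 3L <= len && chars[i] == "S" &&
        all(chars[(i + 1L):(i + 3L)] == "P") &&
        (i + 4L > len || chars[i + 4L] != "P"),
      SP4 = i + 4L <= len && chars[i] == "S" &&
        all(chars[(i + 1L):(i + 4L)] == "P") &&
        (i + 5L > len || chars[i + 5L] != "P"),
      SP5 = i + 5L <= len && chars[i] == "S" &&
        all(chars[(i + 1L):(i + 5L)] == "P"),
      PRP_PPV = i + 4L <= len && chars[i] == "P" && chars[i + 1L] == "P" &&
        chars[i + 2L] == "V" && chars[i + 4L] %in% c("K", "C"),
      PRP_KKPCPP = i + 5L <= len &&
        paste(chars[i:(i + 5L)], collapse = "") == "KKPCPP",
      LYS_XKK = i + 2L <= len && chars[i + 1L] == "K" && chars[i + 2L] == "K",
      LYS_KKK = i + 2L <= len && all(chars[i:(i + 2L)] == "K"),
      LYS_KXK = i + 2L <= len && chars[i] == "K" && chars[i + 2L] == "K",
      stop("unknown class"))
  }
  which(vapply(seq_len(len), is_hit, TRUE)) - 1L  # 0-based starts
}

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1L]])
}

oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1L]]
  aa <- oracle_translate(codon)
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[pos]) next
      alt <- chars; alt[pos] <- b
      alt_aa <- oracle_translate(paste(alt, collapse = ""))
      if (alt_aa == "*") next
      nonstop <- nonstop + 1
      if (alt_aa == aa) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# All orderings of the differing positions, by explicit recursion.
oracle_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_orderings(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

oracle_pathway_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  diff <- which(ca != cb)
  paths <- list(); blocked_paths <- list()
  for (ord in oracle_orderings(diff)) {
    cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      before <- oracle_translate(paste(cur, collapse = ""))
      cur[pos] <- cb[pos]
      after <- oracle_translate(paste(cur, collapse = ""))
      if (after == "*") blocked <- TRUE
      if (after == before) sd <- sd + 1 else nd <- nd + 1
    }
    rec <- c(sd, nd)
    if (blocked) blocked_paths <- c(blocked_paths, list(rec))
    else paths <- c(paths, list(rec))
  }
  use <- if (length(paths)) paths else blocked_paths
  colMeans(do.call(rbind, use))
}

oracle_ng_kaks <- function(seq_a, seq_b) {
  n <- nchar(seq_a) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  cod_a <- substring(seq_a, starts, starts + 2L)
  cod_b <- substring(seq_b, starts, starts + 2L)
  keep <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[keep]; cod_b <- cod_b[keep]
  keep <- vapply(cod_a, oracle_translate, "") != "*" &
    vapply(cod_b, oracle_translate, "") != "*"
  cod_a <- cod_a[keep]; cod_b <- cod_b[keep]
  S <- (sum(vapply(cod_a, oracle_syn_sites, 0)) +
          sum(vapply(cod_b, oracle_syn_sites, 0))) / 2
  N <- 3 * length(cod_a) - S
  Sd <- 0; Nd <- 0
  for (i in which(cod_a != cod_b)) {
    cnt <- oracle_pathway_counts(cod_a[i], cod_b[i])
    Sd <- Sd + cnt[1L]; Nd <- Nd + cnt[2L]
  }
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ks = jc(ps), ka = jc(pn))
}

# Random aligned, stop-free codon pair for oracle cross-checks.
random_cds_pair <- function(n_codons, p_mut = 0.1) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- vapply(a, function(cod) {
    chars <- strsplit(cod, "")[[1L]]
    for (pos in 1:3) {
      if (stats::runif(1) < p_mut) {
        chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
      }
    }
    paste(chars, collapse = "")
  }, "")
  # re-draw mutated codons that became stops
  stop_b <- Biostrings::GENETIC_CODE[b] == "*"
  b[stop_b] <- a[stop_b]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
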