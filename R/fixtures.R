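# Seeded generators for synthetic proteomes, expression matrices and codon
# pair alignments with known ground truth. Backgrounds are drawn from an
# alphabet that excludes S, P, K, V and C, so no Hyp-rich, lysine or PRP
# motif can arise by chance: planted motifs are the only motifs present and
# negatives are unambiguous. PAST content comes from exact A/T counts.

bg_past_letters <- c("A", "T")
bg_other_letters <- c("G", "L", "I", "F", "W", "Y", "N", "Q", "D", "E",
                      "H", "R", "M")

# Background with an exact PAST fraction (rounded count of A/T residues).
background_sequence <- function(len, past_frac) {
  n_past <- round(past_frac * len)
  chars <- sample(bg_other_letters, len, replace = TRUE)
  pos <- sample.int(len, n_past)
  chars[pos] <- sample(bg_past_letters, n_past, replace = TRUE)
  chars
}

# Overwrite `motif` at evenly spread random offsets, one per segment.
plant_motifs <- function(chars, motif, n_times) {
  m <- strsplit(motif, "")[[1L]]
  len <- length(chars)
  seg <- len %/% n_times
  stopifnot(seg >= length(m) + 2L)
  for (k in seq_len(n_times)) {
    lo <- (k - 1L) * seg + 1L
    hi <- k * seg - length(m)
    at <- sample(lo:hi, 1L)
    chars[at:(at + length(m) - 1L)] <- m
  }
  chars
}

proteome_archetypes <- c("AG_PEPTIDE", "CLASSICAL_AGP", "LYS_RICH_AGP",
                         "EXT_AGP", "SP3_EXT", "SP4_EXT", "SP5_EXT",
                         "PRP", "FLA")

make_archetype <- function(subfamily) {
  switch(subfamily,
    AG_PEPTIDE = background_sequence(sample(60:80, 1L), stats::runif(1, 0.38, 0.45)),
    CLASSICAL_AGP = background_sequence(sample(200:400, 1L),
                                        stats::runif(1, 0.38, 0.45)),
    LYS_RICH_AGP = plant_motifs(
      background_sequence(sample(150:250, 1L), stats::runif(1, 0.16, 0.24)),
      "AKKKA", 1L),
    EXT_AGP = plant_motifs(
      background_sequence(sample(150:250, 1L), stats::runif(1, 0.16, 0.24)),
      "SPPPG", 2L),
    SP3_EXT = plant_motifs(
      background_sequence(sample(350:450, 1L), 0.01), "SPPPG", 3L),
    SP4_EXT = plant_motifs(
      background_sequence(sample(350:450, 1L), 0.01), "SPPPPG", 3L),
    SP5_EXT = plant_motifs(
      background_sequence(sample(350:450, 1L), 0.01), "SPPPPPG", 3L),
    PRP = plant_motifs(
      background_sequence(sample(200:300, 1L), 0.02), "PPVAKG", 2L),
    FLA = background_sequence(sample(150:250, 1L), stats::runif(1, 0.16, 0.24)),
    NEGATIVE = background_sequence(sample(100:300, 1L), 0.04),
    stop("unknown archetype: ", subfamily))
}

#' Generate a synthetic proteome with planted subfamily archetypes
#'
#' Each archetype is built with a safety margin from every classifier
#' threshold: AG peptides (length 60-80, PAST 38-45\%, motif-free),
#' classical AGPs (length 200-400, PAST 38-45\%), lysine-rich AGPs
#' (PAST 16-24\% plus a planted KKK cluster), EXT-AGPs (PAST 16-24\% plus
#' two planted SPPP), SPn-EXTs (PAST < 8\% plus three planted SPn runs),
#' PRPs (PAST < 8\% plus two planted PPVAK) and FLAs (PAST 16-24\%,
#' motif-free, with a matching fasciclin row in the returned synthetic
#' domain table). Negatives are motif-free background at PAST ~4\%.
#' Identical seeds give identical output.
#'
#' @param counts Named integer vector of records per archetype; names from
#'   \code{AG_PEPTIDE, CLASSICAL_AGP, LYS_RICH_AGP, EXT_AGP, SP3_EXT,
#'   SP4_EXT, SP5_EXT, PRP, FLA}.
#' @param n_negatives Number of motif-free negative records.
#' @param seed RNG seed.
#' @return List: \code{records} (proteome data frame), \code{manifest}
#'   (data frame \code{id}, \code{subfamily}, \code{family},
#'   \code{length}, \code{seed}) and \code{domtbl} (synthetic fasciclin
#'   domain-hit data frame, NULL when no FLA was requested).
#' @export
generate_proteome <- function(counts, n_negatives = 0L, seed = 1L) {
  stopifnot(all(names(counts) %in% proteome_archetypes), all(counts >= 0))
  labels <- c(rep(names(counts), times = counts),
              rep("NEGATIVE", n_negatives))
  with_seed(seed, {
    seqs <- vapply(labels, function(sub)
      paste(make_archetype(sub), collapse = ""), "")
  })
  ids <- sprintf("SYN%05d", seq_along(labels))
  records <- data.frame(id = ids, sequence = unname(seqs),
                        length = nchar(unname(seqs)),
                        stringsAsFactors = FALSE)
  fam <- ifelse(labels == "NEGATIVE", "NONE",
                unname(subfamily_family[labels]))
  manifest <- data.frame(id = ids, subfamily = ifelse(labels == "NEGATIVE",
                                                      "NONE", labels),
                         family = fam, length = records$length,
                         seed = as.integer(seed), stringsAsFactors = FALSE)
  domtbl <- NULL
  fla <- manifest$id[manifest$subfamily == "FLA"]
  if (length(fla)) {
    domtbl <- data.frame(
      gene_id = fla, domain_accession = "PF02469",
      env_start = 10L,
      env_end = pmin(records$length[match(fla, records$id)], 100L),
      i_evalue = 1e-20, stringsAsFactors = FALSE)
  }
  list(records = records, manifest = manifest, domtbl = domtbl)
}

#' Generate correlated paralog expression profiles
#'
#' Each gene pair is drawn from a bivariate normal with correlation
#' \code{rho} on the log scale and exponentiated to a non-negative,
#' right-skewed RPKM-like scale (log-normal marginals).
#'
#' @param n_pairs Number of gene pairs.
#' @param rho True log-scale correlation, in (-1, 1).
#' @param n_samples Number of samples (libraries), >= 3.
#' @param seed RNG seed.
#' @return List: \code{matrix} (2*n_pairs genes x n_samples RPKM matrix),
#'   \code{pairs} (data frame \code{gene_a}, \code{gene_b}),
#'   \code{manifest} (rho, n_samples, seed).
#' @export
generate_expression <- function(n_pairs, rho, n_samples = 6L, seed = 1L) {
  stopifnot(n_pairs >= 1L, rho > -1, rho < 1, n_samples >= 3L)
  with_seed(seed, {
    z1 <- matrix(stats::rnorm(n_pairs * n_samples), n_pairs, n_samples)
    e <- matrix(stats::rnorm(n_pairs * n_samples), n_pairs, n_samples)
  })
  z2 <- rho * z1 + sqrt(1 - rho^2) * e
  a <- exp(z1 + 1)
  b <- exp(z2 + 1)
  ids_a <- sprintf("gA%05d", seq_len(n_pairs))
  ids_b <- sprintf("gB%05d", seq_len(n_pairs))
  m <- rbind(a, b)
  rownames(m) <- c(ids_a, ids_b)
  colnames(m) <- sprintf("lib%02d", seq_len(n_samples))
  list(matrix = m,
       pairs = data.frame(gene_a = ids_a, gene_b = ids_b,
                          stringsAsFactors = FALSE),
       manifest = list(rho = rho, n_samples = n_samples,
                       seed = as.integer(seed)))
}

cds_edit_tables <- function() {
  tab <- ng_tables()
  if (is.null(.ng_cache$syn_nb)) {
    gc <- tab$aa
    bases <- c("A", "C", "G", "T")
    syn_nb <- list(); nonsyn_nb <- list()
    for (cod in names(gc)) {
      if (gc[[cod]] == "*") next
      chars <- strsplit(cod, "")[[1L]]
      alts <- character(0)
      for (pos in 1:3) for (b in setdiff(bases, chars[pos])) {
        alt <- chars; alt[pos] <- b
        alts <- c(alts, paste(alt, collapse = ""))
      }
      alts <- alts[gc[alts] != "*"]
      syn_nb[[cod]] <- alts[gc[alts] == gc[[cod]]]
      nonsyn_nb[[cod]] <- alts[gc[alts] != gc[[cod]]]
    }
    .ng_cache$syn_nb <- syn_nb
    .ng_cache$nonsyn_nb <- nonsyn_nb
  }
  list(syn = .ng_cache$syn_nb, nonsyn = .ng_cache$nonsyn_nb)
}

#' Generate an aligned codon-sequence pair with planted substitutions
#'
#' Samples a stop-free ancestor codon string, then applies exactly
#' \code{n_syn} single-base synonymous and \code{n_nonsyn} single-base
#' nonsynonymous edits to distinct codons of one copy (edits never create
#' stop codons). The ancestor is drawn from sense codons that admit both
#' edit types (ATG and TGG, which have no synonymous single-base
#' neighbour, are excluded).
#'
#' @param n_codons Number of codons.
#' @param n_syn,n_nonsyn Numbers of synonymous / nonsynonymous edits;
#'   their sum must not exceed \code{n_codons}.
#' @param seed RNG seed.
#' @return List: \code{pair} (\code{id_a}, \code{id_b}, \code{seq_a},
#'   \code{seq_b}) and \code{truth} (\code{n_syn}, \code{n_nonsyn},
#'   \code{edited_codons}).
#' @export
generate_cds_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L) {
  stopifnot(n_codons >= 1L, n_syn >= 0L, n_nonsyn >= 0L)
  if (n_syn + n_nonsyn > n_codons) {
    stop("infeasible edit request: n_syn + n_nonsyn exceeds n_codons")
  }
  nb <- cds_edit_tables()
  pool <- names(nb$syn)[vapply(nb$syn, length, 0L) > 0L &
                          vapply(nb$nonsyn, length, 0L) > 0L]
  with_seed(seed, {
    anc <- sample(pool, n_codons, replace = TRUE)
    targets <- sample.int(n_codons, n_syn + n_nonsyn)
    der <- anc
    for (i in seq_len(n_syn)) {
      cod <- anc[targets[i]]
      der[targets[i]] <- if (length(nb$syn[[cod]]) == 1L) nb$syn[[cod]] else
        sample(nb$syn[[cod]], 1L)
    }
    for (i in seq_len(n_nonsyn)) {
      cod <- anc[targets[n_syn + i]]
      der[targets[n_syn + i]] <-
        if (length(nb$nonsyn[[cod]]) == 1L) nb$nonsyn[[cod]] else
          sample(nb$nonsyn[[cod]], 1L)
    }
  })
  list(pair = list(id_a = "ancestor", id_b = "derived",
                   seq_a = paste(anc, collapse = ""),
                   seq_b = paste(der, collapse = "")),
       truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                    edited_codons = sort(targets)))
}
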