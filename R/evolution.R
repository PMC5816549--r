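# Molecular-evolution arithmetic for duplicated gene pairs: Nei-Gojobori
# (1986) Ka/Ks with Jukes-Cantor correction, Ks-based divergence dating,
# the chi-square likelihood-ratio test, and duplicate-gene-mode labelling
# from homology + collinearity input.

.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (is.null(.ng_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    syn_sites <- stats::setNames(rep(NA_real_, length(gc)), names(gc))
    for (cod in names(gc)) {
      if (gc[[cod]] == "*") next
      chars <- strsplit(cod, "")[[1L]]
      s <- 0
      for (pos in 1:3) {
        alts <- vapply(setdiff(bases, chars[pos]), function(b) {
          alt <- chars; alt[pos] <- b
          paste(alt, collapse = "")
        }, "")
        aa_alt <- unname(gc[alts])
        nonstop <- aa_alt != "*"
        # synonymous-site fraction over non-stop single-base alternatives
        if (any(nonstop)) s <- s + sum(aa_alt[nonstop] == gc[[cod]]) /
            sum(nonstop)
      }
      syn_sites[cod] <- s
    }
    .ng_cache$aa <- gc
    .ng_cache$syn_sites <- syn_sites
    .ng_cache$pair <- new.env(parent = emptyenv())
  }
  .ng_cache
}

perms_of <- function(n) {
  switch(n,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# Average (Sd, Nd) over minimal substitution pathways between two non-stop
# codons; pathways passing through a stop codon are excluded (all pathways
# are used if every one is blocked).
codon_pair_counts <- function(a, b, tab) {
  key <- paste0(a, b)
  hit <- tab$pair[[key]]
  if (!is.null(hit)) return(hit)
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  diff <- which(ca != cb)
  valid <- matrix(0, nrow = 0L, ncol = 2L)
  all_paths <- matrix(0, nrow = 0L, ncol = 2L)
  for (ord in perms_of(length(diff))) {
    cur <- ca
    sd <- 0; nd <- 0; blocked <- FALSE
    for (i in ord) {
      pos <- diff[i]
      prev_aa <- tab$aa[[paste(cur, collapse = "")]]
      cur[pos] <- cb[pos]
      step_aa <- tab$aa[[paste(cur, collapse = "")]]
      if (step_aa == "*") { blocked <- TRUE }
      if (step_aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
    }
    all_paths <- rbind(all_paths, c(sd, nd))
    if (!blocked) valid <- rbind(valid, c(sd, nd))
  }
  use <- if (nrow(valid)) valid else all_paths
  res <- c(sd = mean(use[, 1L]), nd = mean(use[, 2L]))
  tab$pair[[key]] <- res
  res
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

#' Nei-Gojobori Ka/Ks for one aligned coding-sequence pair
#'
#' The NG (1986) pathway-counting estimator with Jukes-Cantor multiple-hit
#' correction. Per codon, synonymous-site fractions are computed over
#' non-stop single-base alternatives; site totals S and N are averaged over
#' the two sequences; codons differing at several positions average their
#' synonymous/nonsynonymous difference counts over all minimal substitution
#' pathways, excluding pathways through stop codons. ps = Sd/S and
#' pn = Nd/N are corrected by d = -(3/4) ln(1 - (4/3) p).
#'
#' @param seq_a,seq_b Aligned coding sequences of equal length (gaps
#'   \code{"-"} allowed; gap-containing codon columns are dropped, as are
#'   codon columns with ambiguous bases or a stop codon in either sequence,
#'   the latter with a warning).
#' @param id_a,id_b Optional sequence identifiers.
#' @return A list of class \code{kaks_result}: \code{id_a}, \code{id_b},
#'   \code{S}, \code{N} (site counts), \code{Sd}, \code{Nd} (difference
#'   counts), \code{ka}, \code{ks}, \code{omega} and \code{status} —
#'   \code{"ok"}, \code{"saturated"} (p >= 3/4, distance undefined),
#'   \code{"undefined"} (S or N is zero) or \code{"undefined_omega"}
#'   (Ks = 0, so the ratio has no finite value).
#' @examples
#' ng_kaks("AAAAAAGGA", "AAAAAAGGG")$ks  # ~1.2071
#' @export
ng_kaks <- function(seq_a, seq_b, id_a = NA_character_,
                    id_b = NA_character_) {
  seq_a <- chartr("U", "T", toupper(seq_a))
  seq_b <- chartr("U", "T", toupper(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stop("aligned length not divisible by 3")
  n_col <- nchar(seq_a) %/% 3
  if (n_col < 1L) stop("zero codons")
  starts <- 3L * seq_len(n_col) - 2L
  cod_a <- substring(seq_a, starts, starts + 2L)
  cod_b <- substring(seq_b, starts, starts + 2L)
  gap <- grepl("-", cod_a, fixed = TRUE) | grepl("-", cod_b, fixed = TRUE)
  cod_a <- cod_a[!gap]; cod_b <- cod_b[!gap]
  ok_base <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[ok_base]; cod_b <- cod_b[ok_base]
  tab <- ng_tables()
  stops <- tab$aa[cod_a] == "*" | tab$aa[cod_b] == "*"
  if (any(stops)) {
    warning(sum(stops), " codon column(s) containing a stop codon dropped")
    cod_a <- cod_a[!stops]; cod_b <- cod_b[!stops]
  }
  if (!length(cod_a)) stop("zero comparable codons after filtering")

  s_a <- sum(tab$syn_sites[cod_a])
  s_b <- sum(tab$syn_sites[cod_b])
  S <- (s_a + s_b) / 2
  N <- 3 * length(cod_a) - S
  diffs <- which(cod_a != cod_b)
  Sd <- 0; Nd <- 0
  for (i in diffs) {
    cnt <- codon_pair_counts(cod_a[i], cod_b[i], tab)
    Sd <- Sd + cnt[["sd"]]; Nd <- Nd + cnt[["nd"]]
  }

  status <- "ok"
  ks <- ka <- NA_real_
  if (S <= 0 || N <= 0) {
    status <- "undefined"
  } else {
    ps <- Sd / S; pn <- Nd / N
    if (ps >= 0.75 || pn >= 0.75) {
      status <- "saturated"
      if (ps < 0.75) ks <- jc_correct(ps)
      if (pn < 0.75) ka <- jc_correct(pn)
    } else {
      ks <- jc_correct(ps); ka <- jc_correct(pn)
      if (ks == 0) status <- "undefined_omega"
    }
  }
  omega <- if (status == "ok" && is.finite(ks) && ks > 0) ka / ks else NA_real_
  structure(list(id_a = id_a, id_b = id_b, S = S, N = N, Sd = Sd, Nd = Nd,
                 ka = ka, ks = ks, omega = omega, status = status),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori Ka/Ks (%s vs %s)\n",
              if (is.na(x$id_a)) "seq A" else x$id_a,
              if (is.na(x$id_b)) "seq B" else x$id_b))
  cat(sprintf("  sites      S = %.4f   N = %.4f\n", x$S, x$N))
  cat(sprintf("  differences Sd = %.4f  Nd = %.4f\n", x$Sd, x$Nd))
  cat(sprintf("  Ka = %s  Ks = %s  omega = %s  [%s]\n",
              format(x$ka), format(x$ks), format(x$omega), x$status))
  invisible(x)
}

#' Read consecutive 2-record aligned FASTA blocks
#'
#' @param path FASTA file whose entries pair up consecutively
#'   (record 1 with 2, 3 with 4, ...), gap character \code{"-"}.
#' @return List of pairs, each \code{list(id_a, id_b, seq_a, seq_b)}.
#' @export
read_aligned_pairs <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  if (length(set) %% 2L != 0L) stop("odd number of records; pairs expected")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  lapply(seq_len(length(set) %/% 2L), function(k) {
    i <- 2L * k - 1L
    list(id_a = ids[i], id_b = ids[i + 1L],
         seq_a = unname(seqs[i]), seq_b = unname(seqs[i + 1L]))
  })
}

#' Ka/Ks table for many aligned pairs
#'
#' @param pairs List of pairs from [read_aligned_pairs()].
#' @param lambda,wgd_window Dating parameters passed to
#'   [divergence_time()].
#' @return Data frame with one row per pair: ids, S, N, Sd, Nd, Ka, Ks,
#'   omega, status, T_years and wgd_window flag.
#' @export
ng_kaks_table <- function(pairs, lambda = 9.1e-9, wgd_window = c(0.15, 0.3)) {
  rows <- lapply(pairs, function(p) {
    r <- ng_kaks(p$seq_a, p$seq_b, p$id_a, p$id_b)
    t_years <- if (is.finite(r$ks))
      divergence_time(r$ks, lambda, wgd_window) else NULL
    data.frame(id_a = r$id_a, id_b = r$id_b, S = r$S, N = r$N,
               Sd = r$Sd, Nd = r$Nd, ka = r$ka, ks = r$ks,
               omega = r$omega, status = r$status,
               T_years = if (is.null(t_years)) NA_real_ else t_years$t_years,
               wgd_window = if (is.null(t_years)) NA else
                 t_years$in_recent_wgd_window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ks-based divergence time
#'
#' T = Ks / (2 lambda), with the default synonymous substitution rate
#' lambda = 9.1e-9 per site per year (derived from black cottonwood) and a
#' flag for the recent whole-genome-duplication Ks window shared by pear
#' and apple (closed interval, default [0.15, 0.3]).
#'
#' @param ks Synonymous distance(s), >= 0.
#' @param lambda Substitutions/site/year, > 0.
#' @param window Closed Ks interval flagged as the recent WGD.
#' @return Data frame: \code{ks}, \code{lambda}, \code{t_years},
#'   \code{in_recent_wgd_window}.
#' @examples
#' divergence_time(0.4871)$t_years  # ~2.676e7 years
#' @export
divergence_time <- function(ks, lambda = 9.1e-9, window = c(0.15, 0.3)) {
  if (lambda <= 0) stop("lambda must be positive")
  stopifnot(all(ks >= 0), length(window) == 2L, window[1L] <= window[2L])
  data.frame(ks = ks, lambda = lambda, t_years = ks / (2 * lambda),
             in_recent_wgd_window = ks >= window[1L] & ks <= window[2L])
}

#' Histogram of Ks values in half-open bins
#'
#' Bins are [k w, (k+1) w); a value exactly on an edge falls in the upper
#' bin. Non-finite values (saturated/undefined pairs) are excluded from the
#' bins and counted separately.
#'
#' @param ks_values Numeric vector of Ks values.
#' @param bin_width Bin width, > 0.
#' @return List: \code{bins} (data frame \code{bin}, \code{lower},
#'   \code{upper}, \code{count}; empty bins omitted) and \code{excluded}.
#' @export
ks_histogram <- function(ks_values, bin_width) {
  stopifnot(bin_width > 0)
  finite <- ks_values[is.finite(ks_values)]
  excluded <- length(ks_values) - length(finite)
  if (!length(finite)) {
    return(list(bins = data.frame(bin = integer(0), lower = numeric(0),
                                  upper = numeric(0), count = integer(0)),
                excluded = excluded))
  }
  idx <- pmax(0L, as.integer(floor(finite / bin_width + 1e-9)))
  tab <- table(idx)
  bin <- as.integer(names(tab))
  list(bins = data.frame(bin = bin, lower = bin * bin_width,
                         upper = (bin + 1L) * bin_width,
                         count = as.integer(tab)),
       excluded = excluded)
}

#' Likelihood-ratio test statistic and p-value
#'
#' For nested site-model comparisons (e.g. M7 vs M8) the statistic is
#' 2 |lnL_alt - lnL_null| compared to an upper-tail chi-square with
#' \code{df} degrees of freedom (default 2).
#'
#' @param lnl_null,lnl_alt Log-likelihoods of the nested and alternative
#'   models.
#' @param df Degrees of freedom, >= 1.
#' @return List of class \code{lrt_result}: \code{lnl_null},
#'   \code{lnl_alt}, \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' lrt(-100, -95)$p_value  # exp(-5)
#' @export
lrt <- function(lnl_null, lnl_alt, df = 2L) {
  stopifnot(df >= 1)
  stat <- 2 * abs(lnl_alt - lnl_null)
  structure(list(lnl_null = lnl_null, lnl_alt = lnl_alt, statistic = stat,
                 df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Read a 12-column BLAST tabular hit file
#'
#' Standard outfmt 6: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore.
#'
#' @param path Path to the tabular file (\code{#} comments skipped).
#' @return Data frame with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns, got ", ncol(df))
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Read MCScanX .collinearity blocks
#'
#' Skips \code{#} header/"## Alignment" lines; pair lines have the form
#' \code{"<block>-<index>: geneA geneB e-value"}.
#'
#' @param path Path to the .collinearity file.
#' @return Data frame: \code{block}, \code{gene_a}, \code{gene_b},
#'   \code{evalue}.
#' @export
read_collinearity <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(data.frame(block = integer(0), gene_a = character(0),
                      gene_b = character(0), evalue = numeric(0)))
  }
  has_colon <- grepl(":", lines, fixed = TRUE)
  if (any(!has_colon)) stop("unparseable collinearity line: ",
                            lines[which(!has_colon)[1L]])
  prefix <- sub(":.*$", "", lines)
  block <- suppressWarnings(as.integer(sub("-.*$", "", trimws(prefix))))
  rest <- trimws(sub("^[^:]*:", "", lines))
  parts <- strsplit(rest, "\\s+")
  n <- vapply(parts, length, 0L)
  if (any(n < 2L)) stop("unparseable collinearity line: ", lines[which(n < 2L)[1L]])
  data.frame(block = block,
             gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             evalue = suppressWarnings(as.numeric(vapply(parts, function(p)
               if (length(p) >= 3L) p[3L] else NA_character_, ""))),
             stringsAsFactors = FALSE)
}

pair_columns <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  if (all(c("qseqid", "sseqid") %in% names(tab))) {
    data.frame(a = tab$qseqid, b = tab$sseqid, stringsAsFactors = FALSE)
  } else if (all(c("gene_a", "gene_b") %in% names(tab))) {
    data.frame(a = tab$gene_a, b = tab$gene_b, stringsAsFactors = FALSE)
  } else {
    data.frame(a = as.character(tab[[1L]]), b = as.character(tab[[2L]]),
               stringsAsFactors = FALSE)
  }
}

#' Classify gene duplication modes
#'
#' Assigns each positioned gene one of five duplication modes, in priority
#' order: \code{wgd_segmental} (appears in a collinear pair),
#' \code{tandem} (a homolog at rank distance exactly 1 on the same
#' chromosome), \code{proximal} (same-chromosome homolog at rank distance
#' <= \code{proximal_max_rank_gap}), \code{dispersed} (any other homolog),
#' \code{singleton} (no homolog). Self-hits are ignored.
#'
#' @param positions Data frame from [read_gene_positions()].
#' @param homolog_pairs Optional homology hit table ([read_blast_tab()] or
#'   any two-gene-column data frame).
#' @param collinear_pairs Optional collinear pair table
#'   ([read_collinearity()]).
#' @param proximal_max_rank_gap Maximum rank distance for \code{proximal}
#'   (default 10).
#' @return Data frame: \code{gene_id}, \code{mode}; one row per positioned
#'   gene.
#' @export
classify_duplication <- function(positions, homolog_pairs = NULL,
                                 collinear_pairs = NULL,
                                 proximal_max_rank_gap = 10L) {
  stopifnot(all(c("gene_id", "chromosome", "rank") %in% names(positions)))
  hom <- pair_columns(homolog_pairs)
  col <- pair_columns(collinear_pairs)
  known <- positions$gene_id
  unknown <- setdiff(unique(c(hom$a, hom$b, col$a, col$b)), known)
  if (length(unknown)) {
    stop("gene(s) in pair tables without a position: ",
         paste(unknown, collapse = ", "))
  }
  hom <- hom[hom$a != hom$b, , drop = FALSE]
  col <- col[col$a != col$b, , drop = FALSE]
  collinear_genes <- unique(c(col$a, col$b))
  partners <- split(c(hom$b, hom$a), c(hom$a, hom$b))
  chrom <- stats::setNames(positions$chromosome, positions$gene_id)
  rank <- stats::setNames(positions$rank, positions$gene_id)
  mode <- vapply(known, function(g) {
    if (g %in% collinear_genes) return("wgd_segmental")
    p <- unique(partners[[g]])
    if (is.null(p) || !length(p)) return("singleton")
    same <- p[chrom[p] == chrom[g]]
    gaps <- abs(rank[same] - rank[g])
    if (length(gaps) && any(gaps == 1L)) return("tandem")
    if (length(gaps) && any(gaps <= proximal_max_rank_gap)) return("proximal")
    "dispersed"
  }, "")
  data.frame(gene_id = known, mode = unname(mode), stringsAsFactors = FALSE)
}
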