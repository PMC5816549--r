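# Expression divergence of duplicated gene pairs: Pearson-correlation
# expression conservation EC, divergence 1 - EC, a seeded random-pair null,
# heatmap range normalization and the 2^-ddCt qPCR utility.

#' Read an RPKM expression matrix from TSV
#'
#' Genes in rows (first column = gene id), samples in columns.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes x samples, with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Expression divergence of one gene pair
#'
#' Expression conservation EC is the sample Pearson correlation of the two
#' genes' RPKM vectors across shared samples; divergence is 1 - EC.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param gene_a,gene_b Gene ids (must be present; >= 3 shared samples).
#' @return List of class \code{expression_divergence}: \code{gene_a},
#'   \code{gene_b}, \code{ec}, \code{divergence}, \code{status}
#'   (\code{"ok"} or \code{"undefined"} when either vector has zero
#'   variance).
#' @examples
#' m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 3, 2))
#' colnames(m) <- paste0("s", 1:3)
#' expression_divergence(m, "g1", "g2")$divergence  # 0.5
#' @export
expression_divergence <- function(matrix, gene_a, gene_b) {
  miss <- setdiff(c(gene_a, gene_b), rownames(matrix))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  a <- matrix[gene_a, ]; b <- matrix[gene_b, ]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3L) stop("fewer than 3 shared samples")
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(gene_a = gene_a, gene_b = gene_b, ec = NA_real_,
                          divergence = NA_real_, status = "undefined"),
                     class = "expression_divergence"))
  }
  ec <- stats::cor(a, b)
  structure(list(gene_a = gene_a, gene_b = gene_b, ec = ec,
                 divergence = 1 - ec, status = "ok"),
            class = "expression_divergence")
}

divergence_vector <- function(matrix, pairs) {
  vapply(seq_len(nrow(pairs)), function(i) {
    expression_divergence(matrix, pairs[[1L]][i], pairs[[2L]][i])$divergence
  }, 0)
}

# Unrank k-th (1-based) unordered pair out of choose(m, 2), enumerated
# (1,2), (1,3), ..., (1,m), (2,3), ...
unrank_pair <- function(k, m) {
  first_count <- m - seq_len(m - 1L)      # pairs starting at i
  cum <- cumsum(first_count)
  i <- findInterval(k - 1L, c(0, cum), rightmost.closed = FALSE)
  j <- i + (k - c(0, cum)[i])
  c(i, j)
}

#' Divergence distributions: duplicated vs random vs control pairs
#'
#' Computes expression divergence for (1) the supplied duplicated gene
#' pairs, (2) \code{n_random} unordered pairs drawn uniformly without
#' replacement from the HRGP id set (seeded, self-pairs excluded), and
#' (3) an optional user-supplied control pair set; plus pairwise two-sided
#' Wilcoxon rank-sum p-values. Pairs with undefined divergence
#' (zero-variance vectors) are dropped and counted.
#'
#' @param matrix Expression matrix.
#' @param duplicated_pairs Two-column data frame of duplicated gene pairs.
#' @param hrgp_ids Character vector of >= 2 HRGP gene ids present in the
#'   matrix.
#' @param n_random Number of random pairs (>= 1, at most
#'   \code{choose(length(hrgp_ids), 2)}).
#' @param seed RNG seed for the random pair draw.
#' @param control_pairs Optional two-column data frame of control pairs.
#' @return List: \code{duplicated}, \code{random}, \code{control}
#'   (divergence vectors; control NULL when not supplied),
#'   \code{random_pairs} (the drawn id pairs), \code{p_values} (named:
#'   \code{dup_vs_random}, \code{dup_vs_control}, \code{random_vs_control}
#'   where computable) and \code{n_undefined}.
#' @export
divergence_distributions <- function(matrix, duplicated_pairs, hrgp_ids,
                                     n_random, seed, control_pairs = NULL) {
  hrgp_ids <- unique(hrgp_ids)
  if (length(hrgp_ids) < 2L) stop("need at least 2 HRGP ids")
  miss <- setdiff(hrgp_ids, rownames(matrix))
  if (length(miss)) stop("HRGP id(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  total <- choose(length(hrgp_ids), 2)
  if (n_random < 1L) stop("n_random must be >= 1")
  if (n_random > total) {
    stop("n_random (", n_random, ") exceeds the ", total,
         " distinct unordered pairs")
  }
  ks <- with_seed(seed, sample.int(total, n_random, replace = FALSE))
  idx <- t(vapply(ks, unrank_pair, numeric(2), m = length(hrgp_ids)))
  random_pairs <- data.frame(gene_a = hrgp_ids[idx[, 1L]],
                             gene_b = hrgp_ids[idx[, 2L]],
                             stringsAsFactors = FALSE)

  dup <- divergence_vector(matrix, duplicated_pairs)
  rnd <- divergence_vector(matrix, random_pairs)
  ctl <- if (!is.null(control_pairs)) divergence_vector(matrix, control_pairs)
  n_undef <- sum(is.na(dup)) + sum(is.na(rnd)) + sum(is.na(ctl %||% numeric(0)))
  dup <- dup[!is.na(dup)]; rnd <- rnd[!is.na(rnd)]
  if (!is.null(ctl)) ctl <- ctl[!is.na(ctl)]

  pv <- c(dup_vs_random = if (length(dup) && length(rnd))
    stats::wilcox.test(dup, rnd, exact = FALSE)$p.value else NA_real_)
  if (!is.null(ctl)) {
    pv <- c(pv,
            dup_vs_control = if (length(dup) && length(ctl))
              stats::wilcox.test(dup, ctl, exact = FALSE)$p.value else NA_real_,
            random_vs_control = if (length(rnd) && length(ctl))
              stats::wilcox.test(rnd, ctl, exact = FALSE)$p.value else NA_real_)
  }
  list(duplicated = dup, random = rnd, control = ctl,
       random_pairs = random_pairs, p_values = pv, n_undefined = n_undef)
}

#' Range-normalize an expression matrix for heatmap display
#'
#' Per gene row: v -> log2(v + 1), then an affine map of the row's
#' [min, max] onto [-bound, +bound] (default bound 3; 4.55 reproduces a
#' wider display range). Constant rows map to all zeros. An alternative
#' \code{"zscore"} mode row-standardizes the log values and clips at
#' +/- bound.
#'
#' @param matrix Non-negative expression matrix.
#' @param bound Positive range bound.
#' @param method \code{"minmax"} (default) or \code{"zscore"}.
#' @return Transformed matrix, same dimensions and dimnames.
#' @export
normalize_for_heatmap <- function(matrix, bound = 3,
                                  method = c("minmax", "zscore")) {
  stopifnot(bound > 0)
  method <- match.arg(method)
  lg <- log2(matrix + 1)
  out <- t(apply(lg, 1L, function(row) {
    if (method == "minmax") {
      rng <- range(row)
      if (rng[1L] == rng[2L]) return(rep(0, length(row)))
      (row - rng[1L]) / (rng[2L] - rng[1L]) * 2 * bound - bound
    } else {
      s <- stats::sd(row)
      if (s == 0) return(rep(0, length(row)))
      pmin(pmax((row - mean(row)) / s, -bound), bound)
    }
  }))
  dimnames(out) <- dimnames(matrix)
  out
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in
#'   the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in
#'   the control sample.
#' @return Relative expression
#'   \code{2^-((ct_target_case - ct_ref_case) -
#'   (ct_target_ctrl - ct_ref_ctrl))}.
#' @examples
#' ddct(20, 18, 22, 18)  # 4
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
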