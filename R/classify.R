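# HRGP family/subfamily classification from biased amino-acid composition
# (PAST content) plus motif evidence, in the style of family-specific search
# strategies for AGPs, EXTs and PRPs.

#' Classifier rule configuration
#'
#' All thresholds of the HRGP search strategies in one place. Defaults:
#' PAST fraction >= 0.10 for AGP-type rules, >= 0.30 for classical AGPs,
#' AG-peptide maximum length 90 aa, >= 2 SPn hits (same n) for extensins,
#' fasciclin i-E-value <= 1e-5, lysine-rich region = >= 2 lysine hits in a
#' 30-residue window. Thresholds are inclusive. \code{rule_order} gives the
#' first-match-wins precedence; it must be a permutation of the default.
#'
#' @param past_agp PAST fraction threshold for AGP rules.
#' @param past_classical PAST fraction threshold for classical AGPs.
#' @param ag_peptide_max_len Maximum AG-peptide length (residues).
#' @param min_ext_hits Minimum SPn hits for an extensin call.
#' @param ext_same_n If TRUE (default) the \code{min_ext_hits} must share
#'   one n; if FALSE hits of any n are pooled.
#' @param lys_min_hits,lys_window Lysine-rich region parameters.
#' @param fla_evalue Fasciclin domain E-value cutoff.
#' @param fla_accessions Pfam accessions counted as fasciclin.
#' @param prp_fifth Fifth-position alphabet of the PPV[X][.] motif.
#' @param rule_order Rule precedence (character vector).
#' @param lambda Substitution rate per site per year for Ks dating.
#' @param wgd_window Closed Ks interval flagged as the recent WGD event.
#' @param heatmap_bound Range bound for heatmap normalization.
#' @return A list of class \code{rule_config}.
#' @export
rule_config <- function(past_agp = 0.10, past_classical = 0.30,
                        ag_peptide_max_len = 90L, min_ext_hits = 2L,
                        ext_same_n = TRUE, lys_min_hits = 2L,
                        lys_window = 30L, fla_evalue = 1e-5,
                        fla_accessions = "PF02469",
                        prp_fifth = c("K", "C"),
                        rule_order = c("FLA", "EXT_AGP", "LYS_RICH_AGP",
                                       "AG_PEPTIDE", "CLASSICAL_AGP",
                                       "SPN_EXT", "PRP"),
                        lambda = 9.1e-9, wgd_window = c(0.15, 0.3),
                        heatmap_bound = 3) {
  stopifnot(past_agp > 0, past_agp <= 1, past_classical > 0,
            past_classical <= 1, ag_peptide_max_len >= 1,
            min_ext_hits >= 1, lys_min_hits >= 1, lys_window >= 1,
            fla_evalue > 0, lambda > 0, length(wgd_window) == 2L,
            wgd_window[1L] < wgd_window[2L], heatmap_bound > 0)
  default_rules <- c("FLA", "EXT_AGP", "LYS_RICH_AGP", "AG_PEPTIDE",
                     "CLASSICAL_AGP", "SPN_EXT", "PRP")
  if (!setequal(rule_order, default_rules) ||
      length(rule_order) != length(default_rules)) {
    stop("rule_order must be a permutation of: ",
         paste(default_rules, collapse = ", "))
  }
  structure(list(past_agp = past_agp, past_classical = past_classical,
                 ag_peptide_max_len = as.integer(ag_peptide_max_len),
                 min_ext_hits = as.integer(min_ext_hits),
                 ext_same_n = isTRUE(ext_same_n),
                 lys_min_hits = as.integer(lys_min_hits),
                 lys_window = as.integer(lys_window),
                 fla_evalue = fla_evalue, fla_accessions = fla_accessions,
                 prp_fifth = prp_fifth, rule_order = rule_order,
                 lambda = lambda, wgd_window = wgd_window,
                 heatmap_bound = heatmap_bound),
            class = "rule_config")
}

#' Amino-acid composition profile
#'
#' Counts P, A, S, T and K residues and the PAST fraction
#' (P+A+S+T)/length, the basic criterion for AGP bias. Ambiguous residues
#' (X, B, Z, U) count towards length but never towards P/A/S/T/K.
#'
#' @param sequence Amino-acid string, or a one-row proteome record.
#' @param protein_id Optional identifier.
#' @return List of class \code{composition_profile}: \code{protein_id},
#'   \code{counts} (named P/A/S/T/K), \code{past_fraction}, \code{length}.
#' @examples
#' compute_composition("GGGGGPPAST")$past_fraction  # 0.5
#' @export
compute_composition <- function(sequence, protein_id = NA_character_) {
  if (is.data.frame(sequence)) {
    protein_id <- sequence$id[1L]
    sequence <- sequence$sequence[1L]
  }
  len <- nchar(sequence)
  if (is.na(sequence) || len < 1L) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- vapply(c(P = "P", A = "A", S = "S", T = "T", K = "K"),
                   function(a) sum(chars == a), 0L)
  structure(list(protein_id = protein_id, counts = counts,
                 past_fraction = sum(counts[c("P", "A", "S", "T")]) / len,
                 length = len),
            class = "composition_profile")
}

# Non-fasciclin domain hits with a credible E-value, used by the classical
# AGP "no swapped domains" check.
has_foreign_domain <- function(ann, config) {
  d <- ann$domains
  if (is.null(d) || nrow(d) == 0L) return(FALSE)
  any(!(d$domain_accession %in% config$fla_accessions) &
        d$i_evalue <= config$fla_evalue)
}

subfamily_family <- c(AG_PEPTIDE = "AGP", LYS_RICH_AGP = "AGP", FLA = "AGP",
                      EXT_AGP = "AGP", CLASSICAL_AGP = "AGP",
                      SP3_EXT = "EXT", SP4_EXT = "EXT", SP5_EXT = "EXT",
                      PRP = "PRP", NONE = "NONE")

#' Classify one protein as AGP/EXT/PRP subfamily or NONE
#'
#' Applies the ordered first-match-wins rule list (see [rule_config()]):
#' FLA, EXT-AGP, lysine-rich AGP, AG peptide, classical AGP, SPn-EXT
#' (largest n with enough hits wins), PRP, else NONE. Signal-peptide and
#' GPI flags are copied from the annotation and never change the call.
#'
#' @param profile A \code{composition_profile}.
#' @param motifs A \code{motif_profile} for the same protein.
#' @param annotation Optional \code{hrgp_annotation}.
#' @param config A [rule_config()].
#' @return One-row data frame: \code{protein_id}, \code{family},
#'   \code{subfamily}, \code{past_fraction}, \code{length}, motif counts,
#'   \code{has_sp}, \code{has_gpi}, \code{flags} (semicolon-joined notes).
#' @export
classify_protein <- function(profile, motifs, annotation = NULL,
                             config = rule_config()) {
  stopifnot(inherits(profile, "composition_profile"),
            inherits(motifs, "motif_profile"),
            inherits(config, "rule_config"))
  if (!is.na(profile$protein_id) && !is.na(motifs$protein_id) &&
      profile$protein_id != motifs$protein_id) {
    stop("profile and motif inputs refer to different proteins")
  }
  ann <- annotation_for(annotation, profile$protein_id)
  counts <- motifs$counts
  past <- profile$past_fraction
  spn_total <- sum(counts[c("SP3", "SP4", "SP5")])
  notes <- character(0)

  fla_flag <- FALSE
  if (!is.null(annotation) && ann$domains_annotated) {
    fla_flag <- isTRUE(as.logical(fasciclin_hits(
      annotation, profile$protein_id, config$fla_accessions,
      config$fla_evalue)))
  }
  lys_flag <- lysine_rich_region_present(motifs$hits, config$lys_min_hits,
                                         config$lys_window)

  subfam <- "NONE"
  for (rule in config$rule_order) {
    fired <- switch(rule,
      FLA = fla_flag && past >= config$past_agp,
      EXT_AGP = past >= config$past_agp && spn_total >= 1L,
      LYS_RICH_AGP = past >= config$past_agp && lys_flag,
      AG_PEPTIDE = past >= config$past_agp &&
        profile$length <= config$ag_peptide_max_len,
      CLASSICAL_AGP = {
        ok <- past >= config$past_classical
        if (ok && !ann$domains_annotated) {
          notes <- c(notes, "domain-check-skipped")
        }
        ok && (!ann$domains_annotated || !has_foreign_domain(ann, config))
      },
      SPN_EXT = {
        if (config$ext_same_n) {
          any(counts[c("SP5", "SP4", "SP3")] >= config$min_ext_hits)
        } else {
          spn_total >= config$min_ext_hits
        }
      },
      PRP = counts["PRP_PPV"] + counts["PRP_KKPCPP"] >= 1L,
      stop("unknown rule: ", rule))
    if (fired) {
      subfam <- if (rule == "SPN_EXT") {
        if (config$ext_same_n) {
          ns <- c(5L, 4L, 3L)[which(counts[c("SP5", "SP4", "SP3")] >=
                                      config$min_ext_hits)]
        } else {
          ns <- c(5L, 4L, 3L)[which(counts[c("SP5", "SP4", "SP3")] >= 1L)]
        }
        paste0("SP", max(ns), "_EXT")
      } else rule
      break
    }
  }
  if (subfam != "CLASSICAL_AGP") notes <- setdiff(notes, "domain-check-skipped")
  if (!ann$sp_annotated) notes <- c(notes, "sp-not-annotated")
  if (!ann$gpi_annotated) notes <- c(notes, "gpi-not-annotated")

  data.frame(
    protein_id = profile$protein_id,
    family = unname(subfamily_family[subfam]),
    subfamily = subfam,
    past_fraction = past,
    length = profile$length,
    sp3 = unname(counts["SP3"]), sp4 = unname(counts["SP4"]),
    sp5 = unname(counts["SP5"]),
    prp = unname(counts["PRP_PPV"] + counts["PRP_KKPCPP"]),
    lys = unname(counts["LYS_XKK"] + counts["LYS_KKK"] + counts["LYS_KXK"]),
    has_sp = ann$has_signal_peptide,
    has_gpi = ann$has_gpi_anchor,
    flags = paste(notes, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Classify every protein of a proteome
#'
#' @param records Proteome data frame from [read_proteome()].
#' @param annotation Optional \code{hrgp_annotation}.
#' @param config A [rule_config()].
#' @return Data frame of calls, one row per protein (see
#'   [classify_protein()]).
#' @export
classify_proteome <- function(records, annotation = NULL,
                              config = rule_config()) {
  calls <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    seq <- records$sequence[i]
    classify_protein(compute_composition(seq, id),
                     motif_profile(seq, id, config$prp_fifth),
                     annotation, config)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

subfamily_order <- c("SP3_EXT", "SP4_EXT", "SP5_EXT", "EXT_AGP",
                     "AG_PEPTIDE", "LYS_RICH_AGP", "FLA", "CLASSICAL_AGP",
                     "PRP", "NONE")

#' Summarize calls into a family/subfamily count table
#'
#' Per subfamily: total members, members with a predicted signal peptide,
#' members with a GPI anchor; plus per-family totals and a grand total over
#' the three HRGP families (NONE calls are listed but excluded from the
#' grand total).
#'
#' @param calls Data frame of calls from [classify_proteome()].
#' @return Data frame with columns \code{family}, \code{subfamily},
#'   \code{with_sp}, \code{with_gpi}, \code{total}. Family total rows carry
#'   subfamily \code{"(all)"}; the grand total row has family
#'   \code{"HRGP"}.
#' @export
summarize_calls <- function(calls) {
  row_for <- function(fam, sub, sel) {
    data.frame(family = fam, subfamily = sub,
               with_sp = sum(calls$has_sp[sel]),
               with_gpi = sum(calls$has_gpi[sel]),
               total = sum(sel), stringsAsFactors = FALSE)
  }
  if (is.null(calls) || nrow(calls) == 0L) {
    calls <- data.frame(subfamily = character(0), family = character(0),
                        has_sp = logical(0), has_gpi = logical(0))
  }
  rows <- lapply(subfamily_order, function(sub) {
    row_for(unname(subfamily_family[sub]), sub, calls$subfamily == sub)
  })
  fams <- lapply(c("EXT", "AGP", "PRP"), function(fam) {
    row_for(fam, "(all)", calls$family == fam)
  })
  grand <- row_for("HRGP", "(all)", calls$family %in% c("AGP", "EXT", "PRP"))
  out <- rbind(do.call(rbind, rows), do.call(rbind, fams), grand)
  rownames(out) <- NULL
  out
}

#' Flag borderline calls and homology support
#'
#' Proteins whose PAST fraction lies near the 10% screening threshold
#' (within [0.08, 0.12]) are flagged \code{borderline}; when a
#' candidate-vs-known-HRGP homology table is supplied, a supporting hit
#' with identity >= 30% and E <= 1e-5 adds \code{homology-supported}.
#' No call is changed.
#'
#' @param calls Data frame of calls.
#' @param candidate_hits Optional BLAST-tabular data frame from
#'   [read_blast_tab()], query ids matching protein ids.
#' @return The calls with updated \code{flags}.
#' @export
validate_by_homology <- function(calls, candidate_hits = NULL) {
  border <- calls$past_fraction >= 0.08 & calls$past_fraction <= 0.12
  supported <- rep(FALSE, nrow(calls))
  if (!is.null(candidate_hits) && nrow(candidate_hits)) {
    good <- candidate_hits$pident >= 30 & candidate_hits$evalue <= 1e-5
    supported <- calls$protein_id %in% candidate_hits$qseqid[good]
  }
  add <- function(flags, new) ifelse(nzchar(flags), paste(flags, new,
                                                          sep = ";"), new)
  out <- calls
  out$flags[border] <- add(out$flags[border], "borderline")
  sel <- border & supported
  out$flags[sel] <- add(out$flags[sel], "homology-supported")
  out
}
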