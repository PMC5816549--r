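# Hyp-rich motif scanners. All coordinates are 0-based half-open; overlaps
# between classes are allowed and each class reports every occurrence.

motif_hit_df <- function(class, start, sequence, len) {
  if (!length(start)) {
    return(data.frame(motif_class = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(motif_class = class, start = start, end = start + len,
             matched_text = substring(sequence, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

# All (possibly overlapping) match starts of a perl regex, 0-based.
regex_starts <- function(sequence, pattern) {
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan for extensin SPn motifs
#'
#' An SPn motif is one serine followed by exactly \code{n} consecutive
#' prolines, the extensin repeat unit. An S followed by more than \code{n}
#' prolines belongs to the larger class only, so SP3/SP4/SP5 hits are
#' disjoint per occurrence; proline runs longer than 5 after an S count as
#' SP5.
#'
#' @param sequence Amino-acid string (uppercase).
#' @param n Number of prolines, one of 3, 4, 5.
#' @return Data frame of hits: \code{motif_class}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{matched_text}; hit length is \code{n + 1}.
#' @examples
#' scan_spn("ASPPPKSPPP", 3)
#' @export
scan_spn <- function(sequence, n) {
  stopifnot(n %in% c(3L, 4L, 5L))
  pat <- if (n == 5L) "S(?=P{5})" else sprintf("S(?=P{%d}(?!P))", n)
  motif_hit_df(paste0("SP", n), regex_starts(sequence, pat), sequence, n + 1L)
}

#' Scan for proline-rich protein (PRP) motifs
#'
#' Reports every occurrence of the PPV[X][KC] pentamer (class
#' \code{PRP_PPV}: P, P, V, any residue, then K or C by default) and of the
#' literal hexamer KKPCPP (class \code{PRP_KKPCPP}). Overlaps are allowed.
#'
#' @param sequence Amino-acid string.
#' @param fifth Allowed residues at the fifth PPV[X][.] position; default
#'   \code{c("K", "C")}. Some descriptions use (K/T); the set is
#'   configurable for that reason.
#' @return Data frame of hits (see [scan_spn()] for columns).
#' @export
scan_prp_motifs <- function(sequence, fifth = c("K", "C")) {
  stopifnot(length(fifth) >= 1L, all(nchar(fifth) == 1L))
  ppv_pat <- sprintf("(?=PPV.[%s])", paste(fifth, collapse = ""))
  rbind(
    motif_hit_df("PRP_PPV", regex_starts(sequence, ppv_pat), sequence, 5L),
    motif_hit_df("PRP_KKPCPP", regex_starts(sequence, "(?=KKPCPP)"),
                 sequence, 6L)
  )
}

#' Scan for lysine motifs
#'
#' Reports every occurrence of the three lysine motif triplets used to
#' detect lysine-rich AGPs: \code{LYS_XKK} (any residue then KK — the
#' leading residue must exist, so KK at position 0 is not a hit),
#' \code{LYS_KKK} (literal KKK) and \code{LYS_KXK} (K, any residue, K).
#' Overlaps within and across classes are allowed.
#'
#' @param sequence Amino-acid string.
#' @return Data frame of hits of length 3 each.
#' @export
scan_lysine_motifs <- function(sequence) {
  rbind(
    motif_hit_df("LYS_XKK", regex_starts(sequence, "(?=.KK)"), sequence, 3L),
    motif_hit_df("LYS_KKK", regex_starts(sequence, "(?=KKK)"), sequence, 3L),
    motif_hit_df("LYS_KXK", regex_starts(sequence, "(?=K.K)"), sequence, 3L)
  )
}

#' Test for a lysine-rich region
#'
#' A single KXK occurs by chance in most proteins, so a lysine-rich region
#' is called only when several lysine motif hits cluster: at least
#' \code{min_hits} lysine-class hits starting within some window of
#' \code{window} residues.
#'
#' @param hits Data frame of motif hits from one protein
#'   ([scan_lysine_motifs()]); non-lysine classes are ignored.
#' @param min_hits Minimum clustered hits (default 2).
#' @param window Window span in residues (default 30).
#' @return TRUE/FALSE.
#' @export
lysine_rich_region_present <- function(hits, min_hits = 2L, window = 30L) {
  starts <- sort(hits$start[startsWith(hits$motif_class, "LYS_")])
  if (length(starts) < min_hits) return(FALSE)
  k <- min_hits
  any(starts[seq_len(length(starts) - k + 1L) + k - 1L] -
        starts[seq_len(length(starts) - k + 1L)] < window)
}

#' Test for a fasciclin (FLA H1) domain hit
#'
#' Fasciclin detection consumes external hmmsearch \code{--domtblout} output
#' rather than re-running profile HMMs.
#'
#' @param annotation An \code{hrgp_annotation} object.
#' @param protein_id Protein identifier.
#' @param accessions Pfam accessions treated as fasciclin-family domains
#'   (default \code{"PF02469"}).
#' @param evalue_cutoff Maximum independent E-value (default 1e-5).
#' @return TRUE iff at least one fasciclin hit passes the cutoff; FALSE with
#'   a \code{"not annotated"} attribute note when no domain table is loaded
#'   (with a warning) or the protein is absent from it.
#' @export
fasciclin_hits <- function(annotation, protein_id, accessions = "PF02469",
                           evalue_cutoff = 1e-5) {
  ann <- annotation_for(annotation, protein_id)
  if (!ann$domains_annotated) {
    warning("no domain table loaded; fasciclin status unknown for ",
            protein_id)
    return(structure(FALSE, note = "not annotated"))
  }
  d <- ann$domains
  hit <- nrow(d) > 0L &&
    any(d$domain_accession %in% accessions & d$i_evalue <= evalue_cutoff)
  if (nrow(d) == 0L) structure(FALSE, note = "not annotated") else hit
}

#' Full motif profile of one protein
#'
#' @param sequence Amino-acid string.
#' @param protein_id Identifier attached to the profile.
#' @param fifth Fifth-position alphabet for the PPV motif (see
#'   [scan_prp_motifs()]).
#' @return List of class \code{motif_profile}: \code{protein_id},
#'   \code{hits} (all classes), \code{counts} (named integer vector per
#'   motif class).
#' @export
motif_profile <- function(sequence, protein_id = NA_character_,
                          fifth = c("K", "C")) {
  hits <- rbind(scan_spn(sequence, 3L), scan_spn(sequence, 4L),
                scan_spn(sequence, 5L), scan_prp_motifs(sequence, fifth),
                scan_lysine_motifs(sequence))
  classes <- c("SP3", "SP4", "SP5", "PRP_PPV", "PRP_KKPCPP",
               "LYS_XKK", "LYS_KKK", "LYS_KXK")
  counts <- vapply(classes, function(cl) sum(hits$motif_class == cl), 0L)
  structure(list(protein_id = protein_id, hits = hits, counts = counts),
            class = "motif_profile")
}

#' Write motif hits as BED6
#'
#' Protein coordinates, name = motif class, score = 0, strand = ".".
#' BED is 0-based half-open, matching the internal hit coordinates.
#'
#' @param hits Data frame of hits with a \code{protein_id} column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_motif_bed <- function(hits, path) {
  stopifnot("protein_id" %in% names(hits))
  bed <- data.frame(chrom = hits$protein_id, start = hits$start,
                    end = hits$end, name = hits$motif_class,
                    score = 0L, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
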