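#' Read a protein FASTA file into a proteome table
#'
#' Parses an amino-acid FASTA file into a data frame of protein records.
#' Sequences are uppercased, a trailing stop symbol \code{*} is stripped,
#' and the record id is the header token before the first whitespace.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data frame with columns \code{id}, \code{sequence} and
#'   \code{length} (residue count), one row per FASTA entry.
#' @details Ambiguous residues (X, B, Z, U) are retained verbatim; they are
#'   never counted towards P/A/S/T/K composition downstream.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MAST*", ">p2", "SPPPSPPP"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- sub("\\*+$", "", toupper(as.character(aa)))
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Write a proteome table to FASTA
#'
#' @param records Proteome data frame from [read_proteome()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_proteome <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Collapse exact-duplicate protein sequences
#'
#' Proteomes from draft genome annotations often contain repeated identical
#' entries; during composition screening these inflate family counts. This
#' keeps exactly one representative per identical amino-acid sequence (the
#' lexicographically smallest id) and reports every collapsed id.
#'
#' @param records Proteome data frame.
#' @return A list with \code{retained} (data frame, same columns as input)
#'   and \code{removed}, a named list mapping each retained representative to
#'   the character vector of ids it absorbed (representatives with no
#'   duplicates are omitted).
#' @export
collapse_repetitive <- function(records) {
  if (anyDuplicated(records$id)) stop("ids must be unique before collapsing")
  groups <- split(records$id, records$sequence)
  removed <- list()
  keep <- character(0)
  for (ids in groups) {
    ids <- sort(ids)
    keep <- c(keep, ids[1L])
    if (length(ids) > 1L) removed[[ids[1L]]] <- ids[-1L]
  }
  retained <- records[records$id %in% keep, , drop = FALSE]
  retained <- retained[order(match(retained$id, records$id)), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}

#' Read gene positions from GFF3 or MCScanX gff
#'
#' Auto-detects the dialect: tab-separated 4-column lines
#' (chromosome, gene, start, end) are treated as the MCScanX gff dialect;
#' 9-column lines as GFF3, taking \code{gene}/\code{mRNA} features and the
#' \code{ID=} attribute as gene id. Genomic positions are kept 1-based
#' inclusive as in GFF.
#'
#' @param path Path to the position file.
#' @return Data frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end} and \code{rank}; \code{rank} is a dense 0-based
#'   order along each chromosome sorted by start, ties broken by gene id.
#' @export
read_gene_positions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data lines in ", path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  ncol1 <- length(parts[[1L]])
  out <- if (ncol1 == 4L) {
    parse_mcscanx_gff(parts, rows)
  } else if (ncol1 >= 9L) {
    parse_gff3(parts, rows)
  } else {
    stop("unrecognized position format at line ", rows[1L],
         " (", ncol1, " tab-separated fields)")
  }
  assign_ranks(out)
}

parse_mcscanx_gff <- function(parts, rows) {
  bad <- which(vapply(parts, length, 0L) != 4L)
  if (length(bad)) stop("unparseable line ", rows[bad[1L]],
                        ": expected 4 tab-separated fields")
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 3L]))
  end <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(start) || anyNA(end)) {
    stop("unparseable line ", rows[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric coordinates")
  }
  data.frame(gene_id = m[, 2L], chromosome = m[, 1L],
             start = start, end = end, stringsAsFactors = FALSE)
}

parse_gff3 <- function(parts, rows) {
  n <- vapply(parts, length, 0L)
  bad <- which(n < 9L)
  if (length(bad)) stop("unparseable line ", rows[bad[1L]],
                        ": expected 9 tab-separated fields")
  m <- do.call(rbind, lapply(parts, `[`, 1:9))
  feat <- m[, 3L]
  sel <- feat %in% c("gene", "mRNA")
  if (!any(sel)) stop("no gene/mRNA features found")
  ids <- sub("^.*ID=([^;]+).*$", "\\1", m[sel, 9L])
  noid <- !grepl("ID=", m[sel, 9L])
  if (any(noid)) stop("unparseable line ", rows[sel][noid][1L],
                      ": missing ID= attribute")
  start <- suppressWarnings(as.integer(m[sel, 4L]))
  end <- suppressWarnings(as.integer(m[sel, 5L]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in GFF3")
  data.frame(gene_id = ids, chromosome = m[sel, 1L],
             start = start, end = end, stringsAsFactors = FALSE)
}

assign_ranks <- function(pos) {
  stopifnot(all(pos$start <= pos$end))
  if (anyDuplicated(pos$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(pos$gene_id[duplicated(pos$gene_id)]), collapse = ", "))
  }
  pos <- pos[order(pos$chromosome, pos$start, pos$gene_id), , drop = FALSE]
  pos$rank <- stats::ave(seq_len(nrow(pos)), pos$chromosome,
                         FUN = function(i) seq_along(i) - 1L)
  rownames(pos) <- NULL
  pos
}

#' Parse SignalP 4 short-format output
#'
#' The short format is one whitespace-delimited line per protein:
#' \code{name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used},
#' where the \code{?} column is \code{Y}/\code{N} and the position following
#' \code{Ymax} is the predicted cleavage site.
#'
#' @param path Path to a SignalP 4 short output file (\code{#} comments
#'   skipped).
#' @return Data frame: \code{gene_id}, \code{has_signal_peptide},
#'   \code{sp_cleavage_site} (NA when no signal peptide is predicted).
#' @export
read_signalp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(0),
                      has_signal_peptide = logical(0),
                      sp_cleavage_site = integer(0)))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  n <- vapply(parts, length, 0L)
  if (any(n < 10L)) stop("unparseable SignalP line: ", lines[which(n < 10L)[1L]])
  has_sp <- vapply(parts, function(p) p[10L] == "Y", TRUE)
  cleave <- suppressWarnings(vapply(parts, function(p) as.integer(p[5L]), 0L))
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             has_signal_peptide = has_sp,
             sp_cleavage_site = ifelse(has_sp, cleave, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Parse big-PI predictor textual output
#'
#' big-PI writes a free-text block per query. Parsing is by keyword: a block
#' starts at a line matching \code{Sequence ID : <id>} (or a \code{>} FASTA
#' header echo); the protein is flagged GPI-anchored iff the block contains
#' the phrase \code{"Potential GPI-modification site"}, and explicitly
#' unanchored when it contains \code{"No GPI-modification site"}.
#'
#' @param path Path to big-PI output.
#' @return Data frame: \code{gene_id}, \code{has_gpi_anchor}.
#' @export
read_bigpi <- function(path) {
  lines <- readLines(path)
  id_pat <- "^\\s*Sequence ID\\s*:\\s*(\\S+)|^>(\\S+)"
  starts <- grep(id_pat, lines)
  if (!length(starts)) {
    return(data.frame(gene_id = character(0), has_gpi_anchor = logical(0)))
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(length(starts))
  gpi <- logical(length(starts))
  for (i in seq_along(starts)) {
    hdr <- lines[starts[i]]
    ids[i] <- if (startsWith(trimws(hdr), ">")) {
      sub("^>(\\S+).*$", "\\1", trimws(hdr))
    } else {
      sub("^\\s*Sequence ID\\s*:\\s*(\\S+).*$", "\\1", hdr)
    }
    block <- lines[starts[i]:ends[i]]
    gpi[i] <- any(grepl("Potential GPI-modification site", block)) &&
      !any(grepl("No GPI-modification site", block))
  }
  data.frame(gene_id = ids, has_gpi_anchor = gpi, stringsAsFactors = FALSE)
}

#' Parse hmmsearch --domtblout domain hits
#'
#' Whitespace-delimited, \code{#} comment lines skipped. Uses the target
#' name (column 1), the query HMM accession (column 5, version suffix
#' stripped), the independent (i-)E-value (column 13) and the envelope
#' coordinates (columns 20-21).
#'
#' @param path Path to a \code{--domtblout} file.
#' @return Data frame: \code{gene_id}, \code{domain_accession},
#'   \code{env_start}, \code{env_end}, \code{i_evalue}.
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(0), domain_accession = character(0),
                      env_start = integer(0), env_end = integer(0),
                      i_evalue = numeric(0)))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  n <- vapply(parts, length, 0L)
  if (any(n < 21L)) stop("unparseable domtblout line: ", lines[which(n < 21L)[1L]])
  data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    domain_accession = sub("\\.\\d+$", "", vapply(parts, `[`, "", 5L)),
    env_start = as.integer(vapply(parts, `[`, "", 20L)),
    env_end = as.integer(vapply(parts, `[`, "", 21L)),
    i_evalue = as.numeric(vapply(parts, `[`, "", 13L)),
    stringsAsFactors = FALSE
  )
}

#' Assemble per-protein annotation from external prediction tables
#'
#' Combines parsed SignalP, big-PI and hmmsearch tables into one lookup
#' object. Any gene absent from a table is "not annotated" for that field
#' (reported distinctly from an explicit negative prediction).
#'
#' @param signalp Optional data frame from [read_signalp()].
#' @param bigpi Optional data frame from [read_bigpi()].
#' @param domtbl Optional data frame from [read_domtbl()].
#' @return An object of class \code{hrgp_annotation}.
#' @export
build_annotation <- function(signalp = NULL, bigpi = NULL, domtbl = NULL) {
  structure(list(signalp = signalp, bigpi = bigpi, domtbl = domtbl),
            class = "hrgp_annotation")
}

#' Look up annotation flags for one protein
#'
#' @param annotation An \code{hrgp_annotation} object (or NULL).
#' @param protein_id Protein identifier.
#' @return List with \code{has_signal_peptide}, \code{sp_cleavage_site},
#'   \code{has_gpi_anchor}, \code{sp_annotated}, \code{gpi_annotated},
#'   \code{domains} (data frame of domain hits, possibly empty) and
#'   \code{domains_annotated}.
#' @export
annotation_for <- function(annotation, protein_id) {
  out <- list(has_signal_peptide = FALSE, sp_cleavage_site = NA_integer_,
              has_gpi_anchor = FALSE, sp_annotated = FALSE,
              gpi_annotated = FALSE, domains = NULL,
              domains_annotated = FALSE)
  if (is.null(annotation)) return(out)
  stopifnot(inherits(annotation, "hrgp_annotation"))
  sp <- annotation$signalp
  if (!is.null(sp)) {
    i <- match(protein_id, sp$gene_id)
    if (!is.na(i)) {
      out$sp_annotated <- TRUE
      out$has_signal_peptide <- sp$has_signal_peptide[i]
      out$sp_cleavage_site <- sp$sp_cleavage_site[i]
    }
  }
  gp <- annotation$bigpi
  if (!is.null(gp)) {
    i <- match(protein_id, gp$gene_id)
    if (!is.na(i)) {
      out$gpi_annotated <- TRUE
      out$has_gpi_anchor <- gp$has_gpi_anchor[i]
    }
  }
  dt <- annotation$domtbl
  if (!is.null(dt)) {
    out$domains_annotated <- TRUE
    out$domains <- dt[dt$gene_id == protein_id, , drop = FALSE]
  }
  out
}
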