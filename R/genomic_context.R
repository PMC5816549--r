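# Genomic GC-content tracks in fixed windows, for Circos-style display.

#' GC content in fixed genomic windows
#'
#' Tiles each chromosome with non-overlapping windows from position 1
#' (1-based inclusive bounds; the final partial window is emitted) and
#' computes GC = (G+C)/(A+C+G+T) per window. Soft-masked lowercase bases
#' count normally; N and other IUPAC ambiguity codes are excluded from both
#' numerator and denominator, and a window with no unambiguous base gets
#' \code{NA}.
#'
#' @param genome Path to a nucleotide FASTA file, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param window Window size in bases (default 10000, i.e. the 10 kb
#'   display window).
#' @return Data frame: \code{chromosome}, \code{start}, \code{end}
#'   (1-based inclusive), \code{gc_fraction}, \code{n_count} (ambiguous
#'   bases in the window).
#' @export
gc_windows <- function(genome, window = 10000L) {
  stopifnot(window >= 1L)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  out <- lapply(seq_along(genome), function(i) {
    len <- Biostrings::width(genome)[i]
    if (len == 0L) return(NULL)
    chrom <- sub("\\s.*$", "", names(genome)[i])
    starts <- seq.int(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    v <- Biostrings::Views(genome[[i]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    data.frame(chromosome = chrom, start = starts, end = ends,
               gc_fraction = ifelse(acgt > 0,
                                    (freq[, "G"] + freq[, "C"]) / acgt, NA),
               n_count = as.integer((ends - starts + 1L) - acgt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), gc_fraction = numeric(0),
                      n_count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Write GC windows as BED4
#'
#' The BED writer converts the 1-based inclusive windows to BED's 0-based
#' half-open convention; the fourth column is the GC fraction.
#'
#' @param windows Data frame from [gc_windows()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gc_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chromosome,
                    start = windows$start - 1L,
                    end = windows$end,
                    gc = ifelse(is.na(windows$gc_fraction), ".",
                                sprintf("%.6f", windows$gc_fraction)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
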