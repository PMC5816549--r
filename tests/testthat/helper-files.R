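# Small writers for the external annotation formats used in tests; all
# fixture content is synthetic and generated in code.

write_fasta_lines <- function(entries, path) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
}

# SignalP 4 short format: name Cmax pos Ymax pos Smax pos Smean D ? Dcut net
write_signalp_fixture <- function(df, path) {
  lines <- c("# SignalP-4.0 euk predictions (synthetic fixture)",
             sprintf("%s 0.5 20 0.5 %d 0.6 15 0.55 0.55 %s 0.45 SignalP-noTM",
                     df$gene_id, ifelse(is.na(df$cleave), 0L, df$cleave),
                     ifelse(df$has_sp, "Y", "N")))
  writeLines(lines, path)
}

# big-PI textual blocks (synthetic fixture, keyword-parseable).
write_bigpi_fixture <- function(df, path) {
  lines <- unlist(lapply(seq_len(nrow(df)), function(i) {
    c(paste0("Sequence ID : ", df$gene_id[i]),
      if (df$has_gpi[i]) "Potential GPI-modification site was found"
      else "No GPI-modification site was found", "")
  }))
  writeLines(lines, path)
}

# hmmsearch --domtblout rows (23 whitespace-separated fields).
write_domtbl_fixture <- function(df, path) {
  lines <- c("# synthetic domtblout fixture",
             sprintf(paste("%s - 200 FAS1 %s 140 %g 50.0 0.1 1 1 %g %g",
                           "45.0 0.1 1 140 %d %d %d %d 0.9 -"),
                     df$gene_id, df$accession, df$i_evalue, df$i_evalue,
                     df$i_evalue, df$env_start, df$env_end,
                     df$env_start, df$env_end))
  writeLines(lines, path)
}

write_collinearity_fixture <- function(pairs, path) {
  lines <- c("############### Parameters ###############",
             "# MATCH_SCORE: 50 (synthetic fixture)",
             "############### Statistics ###############")
  for (b in unique(pairs$block)) {
    sel <- pairs[pairs$block == b, , drop = FALSE]
    lines <- c(lines, sprintf("## Alignment %d: score=500.0 e_value=0 N=%d",
                              b, nrow(sel)),
               sprintf("%3d-%3d:\t%s\t%s\t%g", b, seq_len(nrow(sel)) - 1L,
                       sel$gene_a, sel$gene_b, 1e-50))
  }
  writeLines(lines, path)
}

write_blast_fixture <- function(pairs, path, pident = 80, evalue = 1e-40) {
  lines <- sprintf("%s\t%s\t%.1f\t100\t5\t0\t1\t100\t1\t100\t%g\t200",
                   pairs$a, pairs$b, pident, evalue)
  writeLines(lines, path)
}
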