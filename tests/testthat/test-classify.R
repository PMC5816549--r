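# Build a sequence with a controlled PAST fraction and optional planted
# motifs; background letters G/L cannot form any motif.
seq_with <- function(len, past, motifs = character(0), at = integer(0)) {
  chars <- rep("G", len)
  n_past <- round(past * len)
  chars[seq_len(n_past)] <- "A"
  for (i in seq_along(motifs)) {
    m <- strsplit(motifs[i], "")[[1L]]
    chars[at[i]:(at[i] + length(m) - 1L)] <- m
  }
  paste(chars, collapse = "")
}

call_for <- function(sequence, annotation = NULL, config = rule_config()) {
  classify_protein(compute_composition(sequence, "q"),
                   motif_profile(sequence, "q", config$prp_fifth),
                   annotation, config)
}

test_that("composition counts PAST exactly and rejects empty input", {
  expect_equal(compute_composition("PAST")$past_fraction, 1.0)
  expect_equal(compute_composition("GGGGGPPAST")$past_fraction, 0.5)
  expect_equal(compute_composition("KKKK")$past_fraction, 0.0)
  expect_error(compute_composition(""), "empty")
  # ambiguous residues count to length but not to PAST
  expect_equal(compute_composition("PAXX")$past_fraction, 0.5)
})

test_that("ordered rules give the documented verdicts", {
  # AGP bias + SPn motifs + lysine region: EXT-AGP outranks both
  ext_agp <- call_for(seq_with(300, 0.15, c("SPPPG", "SPPPG", "AKKKA"),
                               c(120, 160, 200)))
  expect_equal(ext_agp$subfamily, "EXT_AGP")
  expect_equal(ext_agp$family, "AGP")

  # below AGP bias, three SP3 hits: extensin
  ext <- call_for(seq_with(300, 0.05, rep("SPPPG", 3), c(100, 150, 200)))
  expect_equal(ext$subfamily, "SP3_EXT")
  expect_equal(ext$family, "EXT")

  # short, strongly biased, motif-free: AG peptide
  agp <- call_for(seq_with(80, 0.40))
  expect_equal(agp$subfamily, "AG_PEPTIDE")

  # long, >=30% PAST, motif-free, no domain table: classical AGP (flagged)
  cls <- call_for(seq_with(400, 0.35))
  expect_equal(cls$subfamily, "CLASSICAL_AGP")
  expect_match(cls$flags, "domain-check-skipped")

  # low bias, one PPVAK: PRP
  prp <- call_for(seq_with(200, 0.05, "PPVAK", 100))
  expect_equal(prp$subfamily, "PRP")
  expect_equal(prp$family, "PRP")

  # lysine region with AGP bias, no SPn: lysine-rich AGP
  lys <- call_for(seq_with(200, 0.20, "AKKKA", 100))
  expect_equal(lys$subfamily, "LYS_RICH_AGP")

  # nothing fires
  none <- call_for(seq_with(200, 0.05))
  expect_equal(none$subfamily, "NONE")
  expect_equal(none$family, "NONE")
})

test_that("FLA requires both the domain hit and AGP bias", {
  f <- withr::local_tempfile()
  write_domtbl_fixture(data.frame(gene_id = "q", accession = "PF02469.1",
                                  i_evalue = 1e-10, env_start = 5L,
                                  env_end = 100L), f)
  ann <- build_annotation(domtbl = read_domtbl(f))
  fla <- call_for(seq_with(200, 0.20), ann)
  expect_equal(fla$subfamily, "FLA")
  low <- call_for(seq_with(200, 0.05), ann)
  expect_false(low$subfamily == "FLA")
})

test_that("classical AGP honours the swapped-domain check when possible", {
  f <- withr::local_tempfile()
  write_domtbl_fixture(data.frame(gene_id = "q", accession = "PF00069.1",
                                  i_evalue = 1e-10, env_start = 5L,
                                  env_end = 100L), f)
  ann <- build_annotation(domtbl = read_domtbl(f))
  swapped <- call_for(seq_with(400, 0.35), ann)
  expect_false(swapped$subfamily == "CLASSICAL_AGP")
  expect_false(grepl("domain-check-skipped", swapped$flags))
})

test_that("largest n with enough hits names the extensin subfamily", {
  s <- seq_with(400, 0.04, c("SPPPG", "SPPPG", "SPPPPPG", "SPPPPPG"),
                c(50, 100, 200, 300))
  expect_equal(call_for(s)$subfamily, "SP5_EXT")
  # pooled-n mode: one SP4 + one SP3 suffices when ext_same_n = FALSE
  mixed <- seq_with(400, 0.04, c("SPPPG", "SPPPPG"), c(100, 200))
  expect_equal(call_for(mixed)$subfamily, "NONE")
  pooled <- call_for(mixed, config = rule_config(ext_same_n = FALSE))
  expect_equal(pooled$subfamily, "SP4_EXT")
})

test_that("SP/GPI flags are copied but never change the call", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_signalp_fixture(data.frame(gene_id = "q", has_sp = TRUE,
                                   cleave = 22L), f1)
  write_bigpi_fixture(data.frame(gene_id = "q", has_gpi = TRUE), f2)
  ann <- build_annotation(signalp = read_signalp(f1),
                          bigpi = read_bigpi(f2))
  s <- seq_with(80, 0.40)
  with_ann <- call_for(s, ann)
  without <- call_for(s)
  expect_equal(with_ann$subfamily, without$subfamily)
  expect_true(with_ann$has_sp)
  expect_true(with_ann$has_gpi)
  expect_false(without$has_sp)
})

test_that("summaries have the family/subfamily count-table shape", {
  gen <- generate_proteome(c(PRP = 3), seed = 3)
  calls <- classify_proteome(gen$records)
  calls$has_sp <- c(TRUE, FALSE, FALSE)
  tab <- summarize_calls(calls)
  prp_row <- tab[tab$subfamily == "PRP", ]
  expect_equal(prp_row$total, 3L)
  expect_equal(prp_row$with_sp, 1L)
  expect_equal(prp_row$with_gpi, 0L)
  grand <- tab[tab$family == "HRGP", ]
  expect_equal(grand$total, 3L)

  empty <- summarize_calls(NULL)
  expect_true(all(empty$total == 0L))
})

test_that("every protein gets exactly one subfamily and counts partition", {
  gen <- generate_proteome(c(AG_PEPTIDE = 5, CLASSICAL_AGP = 5, PRP = 5,
                             SP3_EXT = 5, EXT_AGP = 5),
                           n_negatives = 10, seed = 21)
  calls <- classify_proteome(gen$records)
  expect_equal(nrow(calls), nrow(gen$records))
  expect_equal(anyDuplicated(calls$protein_id), 0L)
  tab <- summarize_calls(calls)
  sub_rows <- tab[tab$subfamily != "(all)", ]
  expect_equal(sum(sub_rows$total), nrow(gen$records))
  # subfamily NONE iff family NONE
  expect_equal(calls$subfamily == "NONE", calls$family == "NONE")
})

test_that("raising the PAST threshold never increases AGP calls", {
  gen <- generate_proteome(c(AG_PEPTIDE = 10, CLASSICAL_AGP = 10,
                             LYS_RICH_AGP = 10, EXT_AGP = 10),
                           n_negatives = 20, seed = 8)
  n_agp <- vapply(c(0.05, 0.10, 0.20, 0.30, 0.50), function(th) {
    cfg <- rule_config(past_agp = th,
                       past_classical = max(th, 0.30))
    sum(classify_proteome(gen$records, config = cfg)$family == "AGP")
  }, 0)
  expect_true(all(diff(n_agp) <= 0))
})

test_that("classification is deterministic", {
  gen <- generate_proteome(c(PRP = 4, EXT_AGP = 4), seed = 13)
  a <- classify_proteome(gen$records)
  b <- classify_proteome(gen$records)
  expect_identical(a, b)
})

test_that("borderline and homology-supported flags are annotations only", {
  calls <- data.frame(protein_id = c("a", "b", "c"),
                      family = "AGP", subfamily = "AG_PEPTIDE",
                      past_fraction = c(0.11, 0.50, 0.09),
                      length = 80L, sp3 = 0L, sp4 = 0L, sp5 = 0L,
                      prp = 0L, lys = 0L, has_sp = FALSE, has_gpi = FALSE,
                      flags = "", stringsAsFactors = FALSE)
  hits <- data.frame(qseqid = "a", sseqid = "known1", pident = 45,
                     length = 100L, mismatch = 5L, gapopen = 0L,
                     qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                     evalue = 1e-30, bitscore = 200)
  out <- validate_by_homology(calls, hits)
  expect_match(out$flags[1], "borderline")
  expect_match(out$flags[1], "homology-supported")
  expect_equal(out$flags[2], "")
  expect_match(out$flags[3], "borderline")
  expect_false(grepl("homology-supported", out$flags[3]))
  expect_equal(out$subfamily, calls$subfamily)  # no call changed

  # no table loaded: borderline only
  out2 <- validate_by_homology(calls)
  expect_match(out2$flags[1], "borderline")
  expect_false(grepl("homology-supported", out2$flags[1]))
})
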