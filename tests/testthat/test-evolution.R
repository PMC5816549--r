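test_that("identical sequences give Ka = Ks = 0 with undefined omega", {
  r <- ng_kaks("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$status, "undefined_omega")
})

test_that("hand-derived NG86 site and difference counts are reproduced", {
  r <- ng_kaks("AAAAAAGGA", "AAAAAAGGG")
  expect_equal(r$S, 5 / 3)
  expect_equal(r$N, 22 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 3 * 0.6), tolerance = 1e-12)
  expect_equal(r$ka, 0)

  r2 <- ng_kaks("AAAAAA", "AAAGAA")
  expect_equal(r2$Nd, 1)
  expect_equal(r2$Sd, 0)
  expect_equal(r2$N, 16 / 3)
  expect_equal(r2$ka, -0.75 * log(1 - 0.25), tolerance = 1e-12)
  expect_equal(r2$ks, 0)
})

test_that("ng_kaks is symmetric and matches the enumeration oracle", {
  skip_if_not_installed("seqinr")
  set.seed(31)
  for (rep in 1:25) {
    p <- random_cds_pair(sample(5:30, 1), p_mut = stats::runif(1, 0.02, 0.3))
    r_ab <- ng_kaks(p$a, p$b)
    r_ba <- ng_kaks(p$b, p$a)
    expect_equal(r_ab$ks, r_ba$ks)
    expect_equal(r_ab$ka, r_ba$ka)
    o <- oracle_ng_kaks(p$a, p$b)
    expect_equal(r_ab$S, o$S, tolerance = 1e-10)
    expect_equal(r_ab$Sd, o$Sd, tolerance = 1e-10)
    expect_equal(r_ab$Nd, o$Nd, tolerance = 1e-10)
    if (is.finite(r_ab$ks)) expect_equal(r_ab$ks, o$ks, tolerance = 1e-10)
    if (is.finite(r_ab$ka)) expect_equal(r_ab$ka, o$ka, tolerance = 1e-10)
  }
})

test_that("gap codon columns and stop codons are excluded", {
  # gap column removed: remaining codon identical
  r <- ng_kaks("ATG---AAA", "ATGGCT---")
  expect_equal(r$Sd + r$Nd, 0)
  expect_warning(ng_kaks("ATGTAAAAA", "ATGTAAAAA"), "stop codon")
  expect_error(ng_kaks("---", "---"), "zero comparable codons")
  expect_error(ng_kaks("ATGA", "ATGA"), "divisible by 3")
})

test_that("planted-edit fixtures recover pure Ka or pure Ks", {
  for (seed in 1:5) {
    syn <- generate_cds_pair(100, n_syn = 3, n_nonsyn = 0, seed = seed)
    r <- ng_kaks(syn$pair$seq_a, syn$pair$seq_b)
    expect_equal(r$ka, 0)
    expect_gt(r$ks, 0)
    non <- generate_cds_pair(100, n_syn = 0, n_nonsyn = 3, seed = seed)
    r2 <- ng_kaks(non$pair$seq_a, non$pair$seq_b)
    expect_equal(r2$ks, 0)
    expect_gt(r2$ka, 0)
  }
})

test_that("divergence time is Ks/(2 lambda) with the WGD window flag", {
  expect_equal(divergence_time(0)$t_years, 0)
  expect_false(divergence_time(0)$in_recent_wgd_window)
  r <- divergence_time(0.4871, 9.1e-9)
  expect_equal(r$t_years, 0.4871 / (2 * 9.1e-9))
  expect_false(r$in_recent_wgd_window)
  expect_true(divergence_time(0.2)$in_recent_wgd_window)
  # closed interval ends
  expect_true(divergence_time(0.15)$in_recent_wgd_window)
  expect_true(divergence_time(0.3)$in_recent_wgd_window)
  expect_false(divergence_time(0.1499)$in_recent_wgd_window)
  expect_error(divergence_time(0.1, lambda = 0), "positive")
  # linear in Ks, inverse-linear in lambda
  ks <- seq(0, 2, by = 0.25)
  expect_equal(divergence_time(ks)$t_years, ks / (2 * 9.1e-9))
  expect_equal(divergence_time(1, lambda = 2 * 9.1e-9)$t_years,
               divergence_time(1, lambda = 9.1e-9)$t_years / 2)
})

test_that("Ks histogram uses half-open bins and excludes non-finite", {
  h <- ks_histogram(c(0.05, 0.16, 0.29), 0.1)
  expect_equal(h$bins$bin, c(0L, 1L, 2L))
  expect_equal(h$bins$count, c(1L, 1L, 1L))
  expect_equal(h$excluded, 0L)

  empty <- ks_histogram(numeric(0), 0.1)
  expect_equal(nrow(empty$bins), 0L)

  edge <- ks_histogram(0.1, 0.1)
  expect_equal(edge$bins$bin, 1L)

  mixed <- ks_histogram(c(0.05, NA, Inf), 0.1)
  expect_equal(sum(mixed$bins$count), 1L)
  expect_equal(mixed$excluded, 2L)
})

test_that("LRT arithmetic matches the chi-square closed form", {
  eq <- lrt(-50, -50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  r <- lrt(-100, -95, df = 2)
  expect_equal(r$statistic, 10)
  expect_equal(r$p_value, exp(-5), tolerance = 1e-12)
  expect_equal(lrt(-10, -10, df = 1)$p_value, 1)
})

test_that("collinearity and BLAST tabular inputs parse", {
  f <- withr::local_tempfile()
  write_collinearity_fixture(data.frame(block = c(0L, 0L, 1L),
                                        gene_a = c("g1", "g2", "g7"),
                                        gene_b = c("g4", "g5", "g9")), f)
  col <- read_collinearity(f)
  expect_equal(nrow(col), 3L)
  expect_equal(col$gene_a, c("g1", "g2", "g7"))
  expect_equal(col$block, c(0L, 0L, 1L))

  write_blast_fixture(data.frame(a = "g1", b = "g2"), f)
  bl <- read_blast_tab(f)
  expect_equal(names(bl)[1:2], c("qseqid", "sseqid"))
  expect_equal(bl$evalue, 1e-40)
})

# 12-gene toy genome: two chromosomes, hand-laid-out homology and blocks.
toy_genome <- function() {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c(sprintf("chr1\tg%02d\t%d\t%d", 1:6, (1:6) * 1000,
                       (1:6) * 1000 + 500),
               sprintf("chr2\tg%02d\t%d\t%d", 7:12, (1:6) * 1000,
                       (1:6) * 1000 + 500)), f)
  read_gene_positions(f)
}

test_that("duplication modes follow the documented priority", {
  pos <- toy_genome()
  hom <- data.frame(a = c("g01", "g03", "g05", "g07"),
                    b = c("g02", "g04", "g12", "g09"))
  col <- data.frame(gene_a = "g05", gene_b = "g12")
  modes <- classify_duplication(pos, hom, col)
  m <- stats::setNames(modes$mode, modes$gene_id)
  expect_equal(m[["g01"]], "tandem")          # adjacent ranks, same chrom
  expect_equal(m[["g02"]], "tandem")
  expect_equal(m[["g05"]], "wgd_segmental")   # collinearity outranks all
  expect_equal(m[["g12"]], "wgd_segmental")
  expect_equal(m[["g07"]], "proximal")        # rank gap 2 on chr2
  expect_equal(m[["g09"]], "proximal")
  expect_equal(m[["g06"]], "singleton")       # no homolog at all
  # labels partition the gene set
  expect_equal(nrow(modes), nrow(pos))
  expect_false(anyNA(modes$mode))
})

test_that("cross-chromosome homologs are dispersed; unknown genes error", {
  pos <- toy_genome()
  hom <- data.frame(a = "g01", b = "g08")
  modes <- classify_duplication(pos, hom)
  expect_equal(modes$mode[modes$gene_id == "g01"], "dispersed")
  expect_error(classify_duplication(pos, data.frame(a = "g01", b = "gX")),
               "gX")
})

test_that("proximal counts are monotone in the rank-gap parameter", {
  pos <- toy_genome()
  hom <- data.frame(a = c("g01", "g02", "g07"), b = c("g04", "g06", "g11"))
  counts <- vapply(1:6, function(gap) {
    sum(classify_duplication(pos, hom,
                             proximal_max_rank_gap = gap)$mode == "proximal")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("aligned pair FASTA blocks read as consecutive pairs", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a1", "ATGGCT", ">b1", "ATGGCC", ">a2", "AAATTT",
               ">b2", "AAATTT"), f)
  pairs <- read_aligned_pairs(f)
  expect_length(pairs, 2L)
  expect_equal(pairs[[1]]$id_b, "b1")
  tab <- ng_kaks_table(pairs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$status[2], "undefined_omega")
  writeLines(c(">a1", "ATG"), f)
  expect_error(read_aligned_pairs(f), "odd number")
})
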