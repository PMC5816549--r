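Package: hypmine
Title: Mining and Evolutionary Analysis of Hydroxyproline-Rich Glycoproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and classifies hydroxyproline-rich glycoproteins
    (HRGPs) in a proteome by biased amino-acid composition (PAST content)
    and Hyp-rich motif grammar (SPn extensin repeats, PPV[X][KC] and KKPCPP
    proline-rich motifs, lysine-rich regions, fasciclin domains), following
    the family-specific search strategies used for the arabinogalactan
    protein (AGP), extensin (EXT) and proline-rich protein (PRP) families.
    Also implements the downstream molecular-evolution arithmetic for
    duplicated gene pairs: Nei-Gojobori Ka/Ks with Jukes-Cantor correction,
    Ks-based divergence-time dating and whole-genome-duplication window
    flagging, duplicate-gene-mode labelling from homology and collinearity
    input, expression divergence of paralog pairs with a random-pair null,
    heatmap range normalization, genomic GC-content windows, and seeded
    synthetic-data generators with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
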