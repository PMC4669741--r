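test_that("G/C content handles plain, mixed and N-containing sequences", {
  expect_equal(gc_content(c("GGCC", "ATAT", "GCAT")), c(1, 0, 0.5))
  expect_equal(gc_content("GCNNAT"), 0.5)  # N excluded from both sides
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("GC-AT"), "outside")
  expect_error(gc_content(""), "empty")
})

test_that("uAUG counting is frame-agnostic and counts overlaps", {
  expect_equal(count_uaugs(c("AAATGAA", "ATGATG", "CCCCCC")), c(1L, 2L, 0L))
  expect_equal(count_uaugs("ATGTGATGATG"), 3L)
  expect_equal(count_uaugs("AUGAUG"), 2L)  # RNA input
})

test_that("feature extraction is case and U/T invariant", {
  up <- utr_features(c(a = "GGAGGAGGAGGATGT"))
  lo <- utr_features(c(a = "ggaggaggaggatgt"))
  rna <- utr_features(c(a = "GGAGGAGGAGGAUGU"))
  expect_equal(up, lo)
  expect_equal(up, rna)
})

test_that("G4 scanner follows the tract/loop grammar on curated cases", {
  expect_true(scan_g4("GGAGGAGGAGG"))           # three 1-nt loops
  expect_false(scan_g4("ATATATATATAT"))
  expect_false(scan_g4("GGAGGAGG"))             # only three tracts
  expect_true(scan_g4(paste0("GG", strrep("A", 7), "GGTGGTGG")))
  expect_false(scan_g4(paste0("GG", strrep("A", 8), "GGTGGTGG")))  # loop 8
  expect_true(scan_g4("GGGTTGGGTTGGGTTGGG"))    # GGG-tract form
  expect_true(scan_g4("GGGGGGGGGGG"))           # tracts may share a G run
  expect_false(scan_g4("GGGGGGGGGG"))           # 10 Gs cannot chain 4x GG
})

test_that("G4 presence is monotone under concatenation and reports intervals", {
  set.seed(41)
  for (i in 1:50) {
    a <- random_seq(40)
    if (scan_g4(a)) expect_true(scan_g4(paste0(a, random_seq(20))))
  }
  m <- g4_matches("GGAGGAGGAGG")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$end, 11)
  expect_equal(nrow(g4_matches("ATATAT")), 0)
})

test_that("scanners agree with brute-force enumeration on random sequences", {
  set.seed(42)
  for (i in 1:300) {
    s <- random_seq(60, c("A", "G", "G", "T", "C"))  # G-rich to hit motifs
    expect_identical(scan_g4(s), oracle_g4(s), label = s)
    expect_identical(scan_paired_ggagg(s), oracle_paired_ggagg(s),
                     label = s)
    expect_identical(scan_motif(s, "GC(GGC){3}G"), oracle_ggc_repeat(s),
                     label = s)
  }
})

test_that("paired-GGAGG linker bounds are 4-10 nt inclusive", {
  expect_true(scan_paired_ggagg("GGAGGAAAAGGAGG"))           # 4-nt linker
  expect_false(scan_paired_ggagg("GGAGGAAAGGAGG"))           # 3-nt linker
  expect_true(scan_paired_ggagg(paste0("GGAGG", strrep("C", 10), "GGAGG")))
  expect_false(scan_paired_ggagg(paste0("GGAGG", strrep("A", 11), "GGAGG")))
})

test_that("motif grammar accepts IUPAC + quantifiers and rejects junk", {
  expect_true(scan_motif("GCGGCGGCGGCG", "GC(GGC){3}G"))
  expect_false(scan_motif("GCGGCGGCG", "GC(GGC){3}G"))
  expect_true(scan_motif("TTTTTTT", "U{6,}"))
  expect_false(scan_motif("TTTTT", "U{6,}"))
  expect_true(scan_motif("GAAGG", "GRAGG"))   # R = A/G
  expect_false(scan_motif("GCAGG", "GRAGG"))
  expect_error(scan_motif("ACGT", "GC[GGC]G"), "malformed")
  expect_error(scan_motif("ACGT", "GC(GGC{3}G"), "malformed")
})

test_that("built-in fold engine equals exhaustive pairing enumeration", {
  expect_equal(fold_energy("AAAAAAAA"), 0)
  expect_equal(fold_energy("GGGGAAAACCCC"), -4)  # 4 G-C pairs at -1 each
  set.seed(43)
  for (i in 1:25) {
    s <- random_seq(sample(8:14, 1))
    expect_equal(fold_energy(s), -oracle_max_pairs(s), label = s)
  }
})

test_that("fold energies are never positive and engines are pluggable", {
  set.seed(44)
  seqs <- vapply(1:20, function(i) random_seq(50), character(1))
  expect_true(all(fold_energy(seqs) <= 0))
  custom <- function(s) rep(-1, length(s))
  expect_equal(fold_energy(seqs[1:2], engine = custom), c(-1, -1))
  bad <- function(s) rep(1, length(s))
  expect_error(fold_energy(seqs[1], engine = bad), "positive")
  failing <- function(s) stop("boom")
  expect_warning(out <- fold_energy(seqs[1], engine = failing), "failed")
  expect_true(is.na(out))
})

test_that("RNAfold engine returns thermodynamic energies", {
  expect_equal(fold_energy("AAAAAAAAAA", engine = "rnafold"), 0)
  mfe <- fold_energy(c("GGGGAAAACCCC", strrep("GGGGCCCC", 4)),
                     engine = "rnafold")
  expect_true(all(mfe <= 0))
  expect_lt(mfe[2], mfe[1])  # longer stem folds more stably
})

test_that("longest UTR per gene is kept, ties to the smaller transcript id", {
  seqs <- c(t1 = strrep("A", 100), t2 = strrep("A", 250),
            t4 = strrep("C", 100), t3 = strrep("G", 100),
            solo = strrep("T", 80))
  map <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                    gene_id = c("g1", "g1", "g2", "g2"),
                    stringsAsFactors = FALSE)
  kept <- longest_utr_per_gene(seqs, map)
  expect_setequal(names(kept), c("t2", "t3", "solo"))
  expect_equal(nrow(attr(kept, "gene_map")), 3)
  # shape contract: collapsing leaves exactly one record per gene
  expect_equal(length(kept),
               length(unique(c(map$gene_id, "solo"))))
})

test_that("the feature table carries all advertised columns", {
  ft <- utr_features(c(x = "GGAGGAAAAGGAGGATG", y = "ATATATAT"))
  expect_named(ft, c("utr_id", "gc", "length", "dG", "n_uaug",
                     "has_ggc_motif", "has_gagg_motif", "has_urich_motif",
                     "has_g4", "has_paired_ggagg"))
  expect_equal(ft$n_uaug, c(1L, 0L))
  expect_true(ft$has_paired_ggagg[1])
  expect_false(ft$has_paired_ggagg[2])
})
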