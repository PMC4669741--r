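#' Normalize a nucleotide sequence
#'
#' Uppercases and converts U to T so RNA and DNA inputs are treated
#' identically; validates the alphabet (A, C, G, T/U, N).
#'
#' @param seq character vector of sequences.
#' @return Normalized character vector.
#' @export
normalize_seq <- function(seq) {
  out <- chartr("u", "t", toupper(as.character(seq)))
  out <- chartr("U", "T", out)
  names(out) <- names(seq)  # toupper drops attributes
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop_bad_arg("sequence(s) contain characters outside A/C/G/T/U/N: ",
                 paste(head(which(bad), 5), collapse = ", "))
  if (any(!nzchar(out))) stop_bad_arg("empty sequence")
  out
}

#' G/C content of sequences
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from both
#' numerator and denominator. All-N sequences return `NA`.
#'
#' @param seq character vector (DNA or RNA, any case).
#' @return Numeric vector of fractions in \[0, 1\] (or `NA`).
#' @examples
#' gc_content(c("GGCC", "ATAT", "GCAT"))
#' @export
gc_content <- function(seq) {
  seq <- normalize_seq(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("N", "", seq))
  ifelse(acgt == 0, NA_real_, gc / acgt)
}

#' Count upstream AUG codons
#'
#' Occurrences of ATG (AUG) at any position and in any frame; overlapping
#' occurrences are counted.
#'
#' @param seq character vector.
#' @return Integer vector of counts.
#' @export
count_uaugs <- function(seq) {
  seq <- normalize_seq(seq)
  vapply(gregexpr("(?=ATG)", seq, perl = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1))
}

G4_PATTERNS <- c(g2 = "GG.{1,7}GG.{1,7}GG.{1,7}GG",
                 g3 = "GGG.{1,7}GGG.{1,7}GGG.{1,7}GGG")

#' Scan for G-quadruplex-forming potential
#'
#' A sequence has G-quadruplex-forming potential when it contains four
#' tracts of GG (or of GGG) separated by loops of 1-7 arbitrary
#' nucleotides: GG N1-7 GG N1-7 GG N1-7 GG, or the GGG-tract analogue.
#' Presence is decided over the whole string with every candidate start
#' considered (bounded quantifiers with full backtracking), so it does not
#' depend on greedy-match behaviour.
#'
#' @param seq character vector.
#' @return Logical vector.
#' @seealso [g4_matches()] for match intervals.
#' @examples
#' scan_g4(c("GGAGGAGGAGG", "ATATATATATAT"))
#' @export
scan_g4 <- function(seq) {
  seq <- normalize_seq(seq)
  grepl(G4_PATTERNS["g2"], seq, perl = TRUE) |
    grepl(G4_PATTERNS["g3"], seq, perl = TRUE)
}

#' G-quadruplex match intervals
#'
#' Leftmost, non-overlapping, shortest-loop-first intervals for each tract
#' pattern (lazy bounded quantifiers).
#'
#' @param seq a single sequence.
#' @return `data.frame` with columns `start`, `end`, `tract` (2 or 3),
#'   zero rows when no match.
#' @export
g4_matches <- function(seq) {
  seq <- normalize_seq(seq)
  stopifnot(length(seq) == 1L)
  lazy <- gsub("\\{1,7\\}", "{1,7}?", G4_PATTERNS, fixed = FALSE)
  out <- lapply(c(2L, 3L), function(tr) {
    m <- gregexpr(lazy[tr - 1L], seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               tract = tr)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               tract = integer()) else out
}

#' Scan for paired GGAGG elements
#'
#' TRUE when two GGAGG motifs occur separated by a linker of 4-10 arbitrary
#' nucleotides (GGAGG N4-10 GGAGG), a configuration with higher-order
#' structure-forming potential.
#'
#' @param seq character vector.
#' @return Logical vector.
#' @examples
#' scan_paired_ggagg("GGAGGAAAAGGAGG")
#' @export
scan_paired_ggagg <- function(seq) {
  grepl("GGAGG.{4,10}GGAGG", normalize_seq(seq), perl = TRUE)
}

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[GC]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

compile_motif <- function(pattern) {
  pat <- chartr("Uu", "Tt", toupper(pattern))
  if (!grepl("^[ACGTRYSWKMBDHVN(){}0-9,]+$", pat))
    stop_bad_arg("malformed motif pattern '", pattern,
                 "': only IUPAC letters, digits, (), {} and , are allowed")
  chars <- strsplit(pat, "")[[1]]
  rx <- paste(ifelse(chars %in% names(IUPAC_CLASS),
                     IUPAC_CLASS[chars], chars), collapse = "")
  ok <- tryCatch({grepl(rx, "ACGT", perl = TRUE); TRUE},
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop_bad_arg("malformed motif pattern '", pattern, "'")
  rx
}

#' Scan for a motif given in IUPAC/quantifier grammar
#'
#' Patterns use IUPAC nucleotide codes plus regular-expression grouping and
#' bounded repetition, e.g. `"GC(GGC){3}G"` (the GGC-repeat element),
#' `"GGAGG"`, or `"U{6,}"` (a U-rich run). U is equivalent to T.
#'
#' @param seq character vector.
#' @param pattern a single pattern string; malformed patterns are rejected.
#' @return Logical presence vector.
#' @examples
#' scan_motif("GCGGCGGCGGCG", "GC(GGC){3}G")
#' @export
scan_motif <- function(seq, pattern) {
  grepl(compile_motif(pattern), normalize_seq(seq), perl = TRUE)
}

#' Minimum free energy of a 5'UTR
#'
#' Dispatches to a folding engine:
#' \describe{
#'   \item{`"basepair"`}{built-in maximum canonical base-pairing score
#'     (Nussinov-style dynamic program; Watson-Crick plus G-U wobble pairs,
#'     minimum hairpin loop of 3 nt, fixed pseudo-energy of -1 kcal/mol per
#'     pair). Deterministic and dependency-free, but NOT thermodynamic: use
#'     it for offline testing and rank-level comparisons only.}
#'   \item{`"rnafold"`}{shells out to ViennaRNA's `RNAfold` for true
#'     nearest-neighbour minimum free energies (requires the binary on
#'     `PATH`).}
#'   \item{a function}{any `function(seq) -> numeric` taking normalized
#'     sequences; must be deterministic and return values <= 0.}
#' }
#' Engine failures yield `NA` with a warning rather than an error.
#'
#' @param seq character vector of sequences.
#' @param engine `"basepair"` (default), `"rnafold"`, or a function.
#' @return Numeric vector of energies in kcal/mol, all <= 0 (0 for
#'   sequences that cannot pair).
#' @examples
#' fold_energy(c("AAAAAAAA", "GGGGAAAACCCC"))
#' @export
fold_energy <- function(seq, engine = "basepair") {
  seq <- normalize_seq(seq)
  fn <- if (is.function(engine)) engine
  else switch(engine,
              basepair = fold_energy_basepair,
              rnafold = fold_energy_rnafold,
              stop_bad_arg("unknown folding engine '", engine, "'"))
  out <- tryCatch(fn(seq), error = function(e) {
    warning("folding engine failed (", conditionMessage(e),
            "); returning NA")
    rep(NA_real_, length(seq))
  })
  if (any(out > 0, na.rm = TRUE))
    stop_bad_arg("folding engine returned a positive energy")
  out
}

PAIR_PSEUDO_ENERGY <- -1.0  # kcal/mol per canonical pair (basepair engine)

fold_energy_basepair <- function(seq) {
  vapply(seq, function(s) nussinov_pairs(s, 3L) * PAIR_PSEUDO_ENERGY,
         numeric(1), USE.NAMES = FALSE)
}

fold_energy_rnafold <- function(seq) {
  if (Sys.which("RNAfold") == "")
    stop_bad_arg("RNAfold binary not found on PATH")
  rna <- chartr("T", "U", seq)
  out <- system2("RNAfold", c("--noPS"), input = rna, stdout = TRUE)
  # every second line: structure + " (mfe)"
  mfe_lines <- out[seq(2, length(out), by = 2)]
  mfe <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", mfe_lines))
  if (length(mfe) != length(seq) || anyNA(mfe))
    stop_bad_arg("could not parse RNAfold output")
  pmin(mfe, 0)
}

#' Keep the longest UTR per gene
#'
#' When a gene has several transcript UTRs, only the longest is retained;
#' length ties are broken by lexicographically smallest transcript id.
#'
#' @param seq named character vector of sequences (names = transcript ids).
#' @param gene_map `data.frame` with columns `transcript_id`, `gene_id`;
#'   transcripts absent from the map are treated as their own gene.
#' @return Named subset of `seq`, one entry per gene, with the gene ids as
#'   the `gene_id` attribute-free companion: a `data.frame` is attached via
#'   attribute `gene_map` mapping kept transcript to gene.
#' @export
longest_utr_per_gene <- function(seq, gene_map = NULL) {
  if (is.null(names(seq))) stop_bad_arg("sequences must be named")
  gid <- if (is.null(gene_map)) names(seq)
  else {
    g <- gene_map$gene_id[match(names(seq), gene_map$transcript_id)]
    ifelse(is.na(g), names(seq), g)
  }
  df <- data.frame(tx = names(seq), gene = gid, len = nchar(seq),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$len, df$tx), , drop = FALSE]
  keep <- df$tx[!duplicated(df$gene)]
  out <- seq[keep]
  attr(out, "gene_map") <- data.frame(
    transcript_id = keep, gene_id = df$gene[!duplicated(df$gene)],
    stringsAsFactors = FALSE)
  out
}

#' Compute the full 5'UTR feature table
#'
#' One row per sequence: G/C fraction, length, folding energy, upstream AUG
#' count, and presence flags for the GGC-repeat motif, GGAGG consensus,
#' U-rich run, G-quadruplex potential and paired-GGAGG element.
#'
#' @param seq named character vector of sequences.
#' @param engine folding engine for [fold_energy()].
#' @param ggc_pattern,gagg_pattern,urich_pattern motif grammar strings; the
#'   U-rich default is a run of >= 6 U (consensus not uniquely determined,
#'   hence configurable).
#' @return `data.frame` with columns `utr_id`, `gc`, `length`, `dG`,
#'   `n_uaug`, `has_ggc_motif`, `has_gagg_motif`, `has_urich_motif`,
#'   `has_g4`, `has_paired_ggagg`.
#' @export
utr_features <- function(seq, engine = "basepair",
                         ggc_pattern = "GC(GGC){3}G",
                         gagg_pattern = "GGAGG",
                         urich_pattern = "U{6,}") {
  seq <- normalize_seq(seq)
  ids <- names(seq) %||% sprintf("seq%d", seq_along(seq))
  data.frame(
    utr_id = ids,
    gc = gc_content(seq),
    length = nchar(seq),
    dG = fold_energy(seq, engine),
    n_uaug = count_uaugs(seq),
    has_ggc_motif = scan_motif(seq, ggc_pattern),
    has_gagg_motif = scan_motif(seq, gagg_pattern),
    has_urich_motif = scan_motif(seq, urich_pattern),
    has_g4 = scan_g4(seq),
    has_paired_ggagg = scan_paired_ggagg(seq),
    stringsAsFactors = FALSE, row.names = NULL)
}
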