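#' Specification for the 5'UTR sequence simulator
#'
#' Sequences are drawn i.i.d. per base with P(G) = P(C) = gc_target / 2 and
#' P(A) = P(T) = (1 - gc_target) / 2, lengths uniform on `length_range`.
#' Each entry of `planted_motifs` is a `list(pattern =, prob =)`: with the
#' given probability the literal pattern (A/C/G/T/U string) is written over
#' the sequence at a random position, and the plant is recorded in the
#' truth table.
#'
#' @param n_sequences number of sequences.
#' @param length_range integer range of sequence lengths (min >= longest
#'   planted motif).
#' @param gc_target target G+C fraction in \[0, 1\]; 0 or 1 give A/T-only or
#'   G/C-only alphabets (useful for negative controls).
#' @param planted_motifs list of `list(pattern = <literal ACGTU string>,
#'   prob = <plant probability>)`.
#' @param ids optional sequence ids (default `UTR00001`, ...).
#' @param seed integer seed.
#' @return An object of class `utr_sim_spec`.
#' @export
utr_sim_spec <- function(n_sequences = 100, length_range = c(50, 300),
                         gc_target = 0.5, planted_motifs = list(),
                         ids = NULL, seed = 1) {
  if (n_sequences < 1) stop_bad_arg("n_sequences must be positive")
  if (gc_target < 0 || gc_target > 1)
    stop_bad_arg("gc_target must lie in [0, 1]")
  if (length(length_range) != 2 || length_range[1] < 1 ||
      diff(length_range) < 0)
    stop_bad_arg("length_range must be a non-decreasing pair of positive ints")
  for (pm in planted_motifs) {
    if (!is.list(pm) || is.null(pm$pattern) || is.null(pm$prob))
      stop_bad_arg("each planted motif needs fields pattern and prob")
    if (!grepl("^[ACGTUacgtu]+$", pm$pattern))
      stop_bad_arg("planted motif patterns must be literal A/C/G/T/U strings")
    if (pm$prob < 0 || pm$prob > 1)
      stop_bad_arg("plant probabilities must lie in [0, 1]")
    if (nchar(pm$pattern) > length_range[1])
      stop_bad_arg("planted motif '", pm$pattern,
                   "' is longer than the shortest allowed sequence")
  }
  if (!is.null(ids) && length(ids) != n_sequences)
    stop_bad_arg("ids must have length n_sequences")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 gc_target = gc_target, planted_motifs = planted_motifs,
                 ids = ids, seed = as.integer(seed)),
            class = "utr_sim_spec")
}

#' Simulate 5'UTR sequences with known planted motifs
#'
#' @param spec a [utr_sim_spec()].
#' @return A list with `sequences` (named character vector, DNA alphabet)
#'   and `truth` (`data.frame` with `utr_id`, `length`, `gc`, and one
#'   logical `planted_<k>` column per planted motif).
#' @examples
#' sim <- simulate_utrs(utr_sim_spec(n_sequences = 3, seed = 2))
#' sim$sequences
#' @export
simulate_utrs <- function(spec) {
  stopifnot(inherits(spec, "utr_sim_spec"))
  n <- spec$n_sequences
  seeds <- derive_substreams(spec$seed, n)
  ids <- spec$ids %||% sprintf("UTR%05d", seq_len(n))
  p <- c(G = spec$gc_target / 2, C = spec$gc_target / 2,
         A = (1 - spec$gc_target) / 2, T = (1 - spec$gc_target) / 2)
  npm <- length(spec$planted_motifs)
  planted <- matrix(FALSE, n, npm)
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    len <- if (spec$length_range[1] == spec$length_range[2])
      spec$length_range[1]
    else sample(spec$length_range[1]:spec$length_range[2], 1)
    base <- sample(names(p), len, replace = TRUE, prob = p)
    for (k in seq_len(npm)) {
      pm <- spec$planted_motifs[[k]]
      if (runif(1) < pm$prob) {
        pat <- strsplit(chartr("Uu", "Tt", toupper(pm$pattern)), "")[[1]]
        at <- sample.int(len - length(pat) + 1L, 1)
        base[at:(at + length(pat) - 1L)] <- pat
        planted[i, k] <- TRUE
      }
    }
    seqs[i] <- paste(base, collapse = "")
  }
  names(seqs) <- ids
  truth <- data.frame(utr_id = ids, length = nchar(seqs),
                      gc = gc_content(seqs), stringsAsFactors = FALSE)
  if (npm > 0) {
    colnames(planted) <- sprintf("planted_%d", seq_len(npm))
    truth <- cbind(truth, as.data.frame(planted))
  }
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}
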