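#' Mononucleotide composition of a coding sequence
#'
#' Base fractions are computed over non-N positions of the positive strand.
#' The percentages `%AT`, `%GC` and `%A` reported for element families are
#' derived from these fractions.
#'
#' @param seq a [coding_sequence()].
#' @return List with `frac_A`, `frac_C`, `frac_G`, `frac_T` (summing to 1),
#'   `pct_AT`, `pct_GC`, `pct_A` (percent scale) and `n_used` /
#'   `n_excluded` position counts.
#' @export
base_composition <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"), nchar(seq$sequence) > 0)
  ch <- .seq_chars(seq)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  n <- sum(counts)
  if (n == 0L) stop("sequence '", seq$id, "' has no unambiguous bases")
  frac <- counts / n
  list(frac_A = unname(frac["A"]), frac_C = unname(frac["C"]),
       frac_G = unname(frac["G"]), frac_T = unname(frac["T"]),
       pct_AT = 100 * unname(frac["A"] + frac["T"]),
       pct_GC = 100 * unname(frac["C"] + frac["G"]),
       pct_A  = 100 * unname(frac["A"]),
       n_used = n, n_excluded = length(ch) - n)
}

#' GC content at the three codon positions
#'
#' GC1 and GC2 are constrained by the encoded protein; GC3 is largely
#' synonymous and tracks the mutational/selective pressure on base
#' composition.  Codons containing N are excluded.
#'
#' @param seq a frame-validated [coding_sequence()].
#' @return Named numeric vector `c(gc1, gc2, gc3)`, percent scale.
#' @export
codon_position_gc <- function(seq) {
  codons <- iter_codons(seq)
  codons <- codons[!attr(codons, "flagged")]
  if (length(codons) == 0L) stop("no unambiguous codons in '", seq$id, "'")
  pos_gc <- vapply(1:3, function(p) {
    b <- substr(codons, p, p)
    100 * mean(b %in% c("G", "C"))
  }, numeric(1))
  c(gc1 = pos_gc[1], gc2 = pos_gc[2], gc3 = pos_gc[3])
}

.dinucs <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, paste0))  # AA CA GA TA AC ... column-major
}

#' Dinucleotide observed/expected ratios
#'
#' Overlapping dinucleotides are counted in a sliding window (no
#' wrap-around; windows containing N are skipped).  The expected frequency
#' of XpY under the zero-order model is the product of the mononucleotide
#' fractions, and the chi-square statistic compares observed window counts
#' with their expectation on 15 degrees of freedom.
#'
#' @param seq a [coding_sequence()] of length >= 2.
#' @return List with `obs_counts`, `obs_freq`, `exp_freq`, `ratio` (16
#'   values each, named `ApA` ... `TpT`), `chisq`, `df` (15) and `p_value`.
#' @export
dinucleotide_ratios <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"), nchar(seq$sequence) >= 2)
  ch <- .seq_chars(seq)
  L <- length(ch)
  first <- ch[-L]
  second <- ch[-1]
  keep <- first != "N" & second != "N"
  din <- paste0(first[keep], second[keep])
  lv <- .dinucs()
  obs <- table(factor(din, levels = lv))
  obs <- stats::setNames(as.integer(obs), lv)
  n_win <- sum(obs)
  if (n_win == 0L) stop("no dinucleotide windows free of N in '", seq$id, "'")
  comp <- base_composition(seq)
  frac <- c(A = comp$frac_A, C = comp$frac_C, G = comp$frac_G, T = comp$frac_T)
  exp_freq <- stats::setNames(
    frac[substr(lv, 1, 1)] * frac[substr(lv, 2, 2)], lv)
  obs_freq <- obs / n_win
  ratio <- ifelse(exp_freq > 0, obs_freq / exp_freq, NA_real_)
  exp_counts <- exp_freq * n_win
  use <- exp_counts > 0
  chisq <- sum((obs[use] - exp_counts[use])^2 / exp_counts[use])
  df <- 15L
  names(obs) <- names(obs_freq) <- names(exp_freq) <- names(ratio) <-
    sub("(.)(.)", "\\1p\\2", lv)
  list(obs_counts = obs, obs_freq = as.numeric(obs_freq) |>
         stats::setNames(names(obs)),
       exp_freq = as.numeric(exp_freq) |> stats::setNames(names(obs)),
       ratio = as.numeric(ratio) |> stats::setNames(names(obs)),
       n_windows = n_win, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Count polyadenylation signals
#'
#' Scans the positive strand for the canonical (AATAAA) and the most common
#' non-canonical (ATTAAA) polyadenylation hexamers.  Overlapping
#' occurrences are counted.  Premature polyA signals inside an AT-rich ORF
#' can terminate transcription early, which is why their count is part of
#' the standard composition report.
#'
#' @param seq a [coding_sequence()].
#' @param motifs character vector of motifs to scan for.
#' @return Integer count of motif occurrences.
#' @export
count_polya_signals <- function(seq, motifs = c("AATAAA", "ATTAAA")) {
  stopifnot(inherits(seq, "coding_sequence"))
  subject <- Biostrings::BString(seq$sequence)
  sum(vapply(motifs, function(m)
    Biostrings::countPattern(m, subject), integer(1)))
}

#' Amino-acid composition of a coding sequence
#'
#' @param seq a frame-validated [coding_sequence()].
#' @return Named integer vector of 20 counts (one-letter codes,
#'   alphabetical); codons containing N are excluded, stops never occur in
#'   a validated payload.
#' @export
aa_composition <- function(seq) {
  codons <- iter_codons(seq)
  codons <- codons[!attr(codons, "flagged")]
  aas <- translate_codons(codons)
  aas <- aas[!is.na(aas) & aas != "*"]
  lv <- sort(unique(unname(.code("genetic_code")[.code("sense_codons")])))
  tab <- table(factor(aas, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Full composition profile for one sequence
#'
#' Bundles [base_composition()], [codon_position_gc()],
#' [dinucleotide_ratios()], [count_polya_signals()] and [aa_composition()]
#' into the per-sequence row used by the composition report.
#'
#' @inheritParams codon_position_gc
#' @param motifs polyA motifs, see [count_polya_signals()].
#' @return Object of class `composition_profile` (a list).
#' @export
composition_profile <- function(seq, motifs = c("AATAAA", "ATTAAA")) {
  mono <- base_composition(seq)
  din <- dinucleotide_ratios(seq)
  structure(
    c(mono,
      list(gc = codon_position_gc(seq),
           dinucleotide = din,
           polya_count = count_polya_signals(seq, motifs),
           aa_counts = aa_composition(seq))),
    class = "composition_profile")
}
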