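#' Bundle a consensus with its aligned genomic copies
#'
#' The unit the mutation pipeline consumes: a family consensus (taken as
#' the ancestral state — the families analysed are young enough that this
#' is safe) plus genomic copies aligned to it.  All aligned strings,
#' consensus included, must have the same (gapped) length.  Per-copy
#' divergence is mismatches over compared columns, gap and N columns
#' excluded.
#'
#' @param consensus a [coding_sequence()] whose `sequence` may be gapped
#'   (`-`) to match the copy alignment, or an ungapped consensus when the
#'   copies carry no gaps.
#' @param copies named character vector (or list) of aligned copy
#'   sequences, same length as the gapped consensus.
#' @return Object of class `family_bundle` with elements `consensus`
#'   (the record), `consensus_aligned`, `copies`, `divergence` (named
#'   per-copy fractions).
#' @export
family_bundle <- function(consensus, copies) {
  stopifnot(inherits(consensus, "coding_sequence"))
  copies <- vapply(copies, toupper, character(1))
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    names(copies) <- paste0("copy", seq_along(copies))
  aligned <- consensus$sequence
  widths <- nchar(copies)
  if (any(widths != nchar(aligned)))
    stop("aligned length mismatch: consensus is ", nchar(aligned),
         " columns but copies span ", paste(unique(widths), collapse = ", "))
  cons_ch <- strsplit(aligned, "")[[1]]
  div <- vapply(copies, function(cp) {
    ch <- strsplit(cp, "")[[1]]
    ok <- cons_ch %in% c("A", "C", "G", "T") & ch %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    mean(cons_ch[ok] != ch[ok])
  }, numeric(1))
  structure(list(consensus = consensus, consensus_aligned = aligned,
                 copies = copies, divergence = div),
            class = "family_bundle")
}

#' @export
print.family_bundle <- function(x, ...) {
  cat(sprintf("<family_bundle> %s: %d copies, mean divergence %.3f\n",
              x$consensus$id, length(x$copies),
              mean(x$divergence, na.rm = TRUE)))
  invisible(x)
}

#' Read a family alignment FASTA into a bundle
#'
#' By convention the first record of the gapped alignment FASTA is the
#' family consensus; all later records are genomic copies.
#'
#' @param path gapped multi-FASTA; first record = consensus.
#' @return A [family_bundle()].
#' @export
read_family_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L)
    stop("family alignment '", path, "' needs a consensus plus >= 1 copy")
  seqs <- unname(toupper(as.character(set)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  bad <- gsub("[ACGTN-]", "", paste(seqs, collapse = ""))
  if (nzchar(bad))
    stop("alignment '", path, "' contains non-nucleotide characters")
  family_bundle(structure(list(id = ids[1], sequence = seqs[1],
                               clade = "unknown", host = "unknown",
                               orf_label = "unknown",
                               frame_validated = FALSE),
                          class = "coding_sequence"),
                stats::setNames(seqs[-1], ids[-1]))
}

#' Call substitutions of each copy against the consensus
#'
#' Substitutions only: alignment columns where either the consensus or the
#' copy carries a gap or an N are skipped, so indels never enter the
#' spectrum.  Positions are reported in ungapped consensus coordinates
#' (1-based).
#'
#' @param bundle a [family_bundle()].
#' @return Data frame with columns `copy`, `position`, `from`, `to`.
#' @export
call_variants <- function(bundle) {
  stopifnot(inherits(bundle, "family_bundle"))
  cons_ch <- strsplit(bundle$consensus_aligned, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  cons_ok <- cons_ch %in% acgt
  cons_pos <- cumsum(cons_ch != "-")  # ungapped consensus coordinate
  out <- lapply(names(bundle$copies), function(nm) {
    ch <- strsplit(bundle$copies[[nm]], "")[[1]]
    idx <- which(cons_ok & ch %in% acgt & ch != cons_ch)
    if (!length(idx))
      return(data.frame(copy = character(0), position = integer(0),
                        from = character(0), to = character(0)))
    data.frame(copy = nm, position = cons_pos[idx],
               from = cons_ch[idx], to = ch[idx])
  })
  do.call(rbind, out)
}

#' Keep only singleton variants
#'
#' A substitution shared by two or more copies (identical position, from
#' and to) was most likely inherited from a common progenitor rather than
#' acquired de novo, so the mutation spectrum is built from singletons:
#' triples observed in exactly one copy.  Two *different* substitutions at
#' the same position remain singletons.
#'
#' @param variants data frame from [call_variants()].
#' @return The singleton subset, same columns.
#' @export
filter_singletons <- function(variants) {
  stopifnot(all(c("copy", "position", "from", "to") %in% names(variants)))
  if (nrow(variants) == 0L) return(variants)
  key <- paste(variants$position, variants$from, variants$to, sep = ":")
  n_copies <- tapply(variants$copy, key, function(x) length(unique(x)))
  variants[n_copies[key] == 1L, , drop = FALSE]
}

#' Classify variants by CpG context on the consensus
#'
#' A C-to-anything substitution is CpG-context when the consensus carries G
#' at the next position; a G-to-anything substitution when the consensus
#' carries C at the previous position.  All other substitutions, and
#' positions whose relevant neighbor does not exist or is not the required
#' base, are non-CpG.  C and G in CpG context mutate at a rate 10-50 times
#' the non-CpG rate, which is why the spectrum is split by context.
#'
#' @param variants data frame with `position`, `from`, `to` (consensus
#'   coordinates).
#' @param consensus ungapped consensus sequence (character string) or a
#'   [coding_sequence()].
#' @return `variants` with an added factor column `context`
#'   (`"CpG"`/`"nonCpG"`).
#' @export
classify_cpg_context <- function(variants, consensus) {
  seq <- if (inherits(consensus, "coding_sequence")) consensus$sequence else consensus
  seq <- gsub("-", "", toupper(seq))
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  stopifnot(all(variants$position >= 1), all(variants$position <= L))
  nxt <- ifelse(variants$position < L, ch[pmin(variants$position + 1L, L)], "")
  prv <- ifelse(variants$position > 1, ch[pmax(variants$position - 1L, 1L)], "")
  is_cpg <- (variants$from == "C" & nxt == "G") |
            (variants$from == "G" & prv == "C")
  variants$context <- factor(ifelse(is_cpg, "CpG", "nonCpG"),
                             levels = c("CpG", "nonCpG"))
  variants
}

.mutation_types <- function() {
  b <- c("A", "C", "G", "T")
  pairs <- expand.grid(from = b, to = b, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  paste0(pairs$from, ">", pairs$to)
}

#' Tabulate a mutation spectrum from classified variants
#'
#' @param variants data frame with `from`, `to` and (optionally) `context`.
#' @return Data frame with one row per substitution type (12 rows):
#'   `type`, `from`, `to`, `count`, `count_cpg`, `count_noncpg`.
#' @export
count_spectrum <- function(variants) {
  types <- .mutation_types()
  key <- paste0(variants$from, ">", variants$to)
  count <- table(factor(key, levels = types))
  if ("context" %in% names(variants)) {
    cpg <- table(factor(key[variants$context == "CpG"], levels = types))
    noncpg <- table(factor(key[variants$context == "nonCpG"], levels = types))
  } else {
    cpg <- stats::setNames(rep(0L, length(types)), types)
    noncpg <- count
  }
  data.frame(type = types,
             from = substr(types, 1, 1), to = substr(types, 3, 3),
             count = as.integer(count),
             count_cpg = as.integer(cpg),
             count_noncpg = as.integer(noncpg))
}

#' Opportunity-normalized mutation percentages
#'
#' Each substitution count is divided by the number of source bases in the
#' ungapped consensus (its mutational opportunity), and the resulting rates
#' are rescaled to sum to 100.  Types whose source base is absent from the
#' consensus are undefined and excluded (with an attribute recording them).
#'
#' @param counts data frame from [count_spectrum()] (column `count` is
#'   normalized; pass a context subset to normalize that subset).
#' @param consensus ungapped consensus string or [coding_sequence()].
#' @return `counts` with added columns `rate` and `normalized_pct`
#'   (summing to 100 over defined types).
#' @export
normalize_spectrum <- function(counts, consensus) {
  seq <- if (inherits(consensus, "coding_sequence")) consensus$sequence else consensus
  seq <- gsub("-", "", toupper(seq))
  ch <- strsplit(seq, "")[[1]]
  base_n <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  opp <- base_n[counts$from]
  rate <- ifelse(opp > 0, counts$count / opp, NA_real_)
  excluded <- counts$type[is.na(rate)]
  tot <- sum(rate, na.rm = TRUE)
  counts$rate <- rate
  counts$normalized_pct <- if (tot > 0) 100 * rate / tot else rate * NA
  attr(counts, "excluded_types") <- excluded
  counts
}

#' Excess of GC-to-AT over AT-to-GC mutation rates
#'
#' The ratio of the pooled opportunity-normalized rates of the four
#' substitutions that move GC pairs toward AT (C>T, C>A, G>A, G>T) over the
#' four that move AT toward GC (T>C, A>G, A>C, T>G).  A ratio above 1 is the
#' universal AT-ward mutation pressure seen in retroelement copies.
#'
#' @param spectrum data frame from [normalize_spectrum()] (needs `type` and
#'   `rate`).
#' @return Ratio >= 0; `Inf` with a warning when no AT-to-GC mutations were
#'   observed.
#' @export
gc_to_at_excess <- function(spectrum) {
  stopifnot(all(c("type", "rate") %in% names(spectrum)))
  r <- stats::setNames(spectrum$rate, spectrum$type)
  num <- sum(r[c("C>T", "C>A", "G>A", "G>T")], na.rm = TRUE)
  den <- sum(r[c("T>C", "A>G", "A>C", "T>G")], na.rm = TRUE)
  if (den == 0) {
    warning("no AT-to-GC mutations observed; excess is infinite")
    return(Inf)
  }
  num / den
}

#' Drop families too diverged for reliable consensus-based calling
#'
#' Families whose mean copy divergence is at or above the threshold are
#' removed (the analysis restricts itself to young families, where the
#' consensus is a safe ancestral proxy).
#'
#' @param bundles list of [family_bundle()] objects.
#' @param max_divergence divergence threshold (default 0.05).
#' @return Filtered list, with attribute `"n_dropped"`.
#' @export
filter_families_by_divergence <- function(bundles, max_divergence = 0.05) {
  keep <- vapply(bundles, function(b)
    mean(b$divergence, na.rm = TRUE) < max_divergence, logical(1))
  structure(bundles[keep], n_dropped = sum(!keep))
}

#' Full singleton mutation spectrum of one family
#'
#' Runs the chain [call_variants()] -> [filter_singletons()] ->
#' [classify_cpg_context()] -> [count_spectrum()] -> [normalize_spectrum()]
#' and derives the GC-to-AT excess.
#'
#' @param bundle a [family_bundle()].
#' @param singletons_only logical; `FALSE` keeps shared variants too (for
#'   comparison of the two protocols).
#' @return Object of class `mutation_spectrum`: list with `spectrum` (the
#'   normalized 12-row data frame), `gc_to_at_excess`, `n_copies`,
#'   `n_singletons`, `n_variants`, `variants`.
#' @export
mutation_spectrum <- function(bundle, singletons_only = TRUE) {
  variants <- call_variants(bundle)
  n_all <- nrow(variants)
  if (singletons_only) variants <- filter_singletons(variants)
  cons <- gsub("-", "", bundle$consensus_aligned)
  variants <- classify_cpg_context(variants, cons)
  spec <- normalize_spectrum(count_spectrum(variants), cons)
  structure(list(spectrum = spec,
                 gc_to_at_excess = gc_to_at_excess(spec),
                 n_copies = length(bundle$copies),
                 n_singletons = nrow(variants),
                 n_variants = n_all,
                 variants = variants),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("<mutation_spectrum> %d copies, %d/%d singleton variants, GC->AT excess %.2f\n",
              x$n_copies, x$n_singletons, x$n_variants, x$gc_to_at_excess))
  invisible(x)
}

#' Pool several families into one spectrum
#'
#' Counts are summed across families and normalized by the summed
#' per-family opportunities (concatenated-consensus normalization).
#'
#' @param bundles list of [family_bundle()] objects.
#' @param singletons_only see [mutation_spectrum()].
#' @return A `mutation_spectrum` for the pooled data.
#' @export
pooled_mutation_spectrum <- function(bundles, singletons_only = TRUE) {
  stopifnot(length(bundles) > 0)
  per <- lapply(bundles, mutation_spectrum, singletons_only = singletons_only)
  combined_cons <- paste(vapply(bundles, function(b)
    gsub("-", "", b$consensus_aligned), character(1)), collapse = "")
  counts <- per[[1]]$spectrum[c("type", "from", "to")]
  counts$count <- Reduce(`+`, lapply(per, function(p) p$spectrum$count))
  counts$count_cpg <- Reduce(`+`, lapply(per, function(p) p$spectrum$count_cpg))
  counts$count_noncpg <- Reduce(`+`, lapply(per, function(p) p$spectrum$count_noncpg))
  spec <- normalize_spectrum(counts, combined_cons)
  structure(list(spectrum = spec,
                 gc_to_at_excess = gc_to_at_excess(spec),
                 n_copies = sum(vapply(per, `[[`, integer(1), "n_copies")),
                 n_singletons = sum(vapply(per, `[[`, numeric(1), "n_singletons")),
                 n_variants = sum(vapply(per, `[[`, numeric(1), "n_variants")),
                 variants = do.call(rbind, lapply(per, `[[`, "variants"))),
            class = "mutation_spectrum")
}
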