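# Brute-force reference implementations used as independent oracles.
# These deliberately use naive position-by-position loops so they share no
# code path with the package.

rand_seq_str <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# overlapping motif count by checking every start position
oracle_motif_count <- function(seqstr, motifs) {
  n <- nchar(seqstr)
  total <- 0L
  for (m in motifs) {
    k <- nchar(m)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      if (substr(seqstr, i, i + k - 1L) == m) total <- total + 1L
    }
  }
  total
}

# overlapping dinucleotide counts, windows containing N skipped
oracle_dinuc_counts <- function(seqstr) {
  b <- c("A", "C", "G", "T")
  lv <- as.vector(outer(b, b, function(x, y) paste0(x, "p", y)))
  out <- setNames(rep(0L, 16), lv)
  for (i in seq_len(nchar(seqstr) - 1L)) {
    x <- substr(seqstr, i, i)
    y <- substr(seqstr, i + 1L, i + 1L)
    if (x != "N" && y != "N") {
      key <- paste0(x, "p", y)
      out[key] <- out[key] + 1L
    }
  }
  out
}

# percent GC at each codon position, codons with N excluded
oracle_codon_gc <- function(seqstr) {
  n_cod <- nchar(seqstr) %/% 3L
  used <- 0L
  gc <- c(0L, 0L, 0L)
  for (j in seq_len(n_cod)) {
    cod <- substr(seqstr, 3L * j - 2L, 3L * j)
    if (grepl("N", cod)) next
    used <- used + 1L
    for (p in 1:3) {
      ch <- substr(cod, p, p)
      if (ch == "G" || ch == "C") gc[p] <- gc[p] + 1L
    }
  }
  100 * gc / used
}

# substitutions of one aligned copy vs an aligned consensus, by column
oracle_variants <- function(cons_aln, copy_aln) {
  pos <- 0L
  out <- list()
  for (i in seq_len(nchar(cons_aln))) {
    a <- substr(cons_aln, i, i)
    b <- substr(copy_aln, i, i)
    if (a != "-") pos <- pos + 1L
    if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") && a != b)
      out[[length(out) + 1L]] <- data.frame(position = pos, from = a, to = b)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(position = integer(0), from = character(0), to = character(0))
}

# translate-and-tally amino-acid counter using a literal codon table walk
oracle_aa_counts <- function(seqstr) {
  gc <- Biostrings::GENETIC_CODE
  out <- integer(0)
  for (j in seq_len(nchar(seqstr) %/% 3L)) {
    cod <- substr(seqstr, 3L * j - 2L, 3L * j)
    if (grepl("N", cod)) next
    aa <- gc[[cod]]
    if (aa == "*") next
    out[aa] <- if (is.na(out[aa])) 1L else out[aa] + 1L
  }
  out
}

# Wright's Nc computed straight from a codon-count vector, spelled out
oracle_nc <- function(counts) {
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[gcode != "*"]
  fam <- split(sense, gcode[sense])
  f_by_size <- list()
  for (aa in names(fam)) {
    cnt <- counts[fam[[aa]]]
    n <- sum(cnt)
    k <- length(fam[[aa]])
    if (n == 0 || k == 1) next
    f <- sum((cnt / n)^2)
    f_by_size[[as.character(k)]] <- c(f_by_size[[as.character(k)]], f)
  }
  2 + 9 / mean(f_by_size[["2"]]) + 1 / mean(f_by_size[["3"]]) +
    5 / mean(f_by_size[["4"]]) + 3 / mean(f_by_size[["6"]])
}

make_validated <- function(seqstr, id = "s", ...) {
  validate_orf(coding_sequence(id, seqstr, ...))
}

# a stop-free random coding sequence of n codons (per-codon rejection)
rand_cds <- function(n_codons, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  b <- names(freqs)
  draw <- function(n) paste0(sample(b, n, TRUE, freqs),
                             sample(b, n, TRUE, freqs),
                             sample(b, n, TRUE, freqs))
  codons <- draw(n_codons)
  repeat {
    bad <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(bad)) break
    codons[bad] <- draw(length(bad))
  }
  make_validated(paste(codons, collapse = ""))
}
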