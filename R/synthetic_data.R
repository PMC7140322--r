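#' Simulate a host CDS set with a chosen codon-usage profile
#'
#' Emulates a RefSeq-style host gene set: each gene starts with ATG, ends
#' with a stop codon and contains no internal stop; internal codons are
#' drawn per amino acid from the supplied conditional codon-usage profile.
#' Amino acids themselves are drawn from `aa_freqs` (uniform over the 20 by
#' default).
#'
#' @param codon_profile named numeric vector over (a subset of) the 61
#'   sense codons giving per-amino-acid conditional frequencies (each
#'   synonymous family must sum to 1), or a `codon_usage_table` whose
#'   `cond_freq` is used.
#' @param n_genes number of genes.
#' @param mean_length mean gene length in codons (internal codons; actual
#'   lengths are Poisson-dispersed around this, minimum 10).
#' @param seed integer seed.
#' @param aa_freqs optional named amino-acid frequencies.
#' @return List of frame-validated [coding_sequence()] records
#'   (`host = "synthetic_host"`).
#' @export
simulate_host_cds <- function(codon_profile, n_genes, mean_length = 300,
                              seed = NULL, aa_freqs = NULL) {
  if (inherits(codon_profile, "codon_usage_table"))
    codon_profile <- codon_profile$cond_freq
  fams <- codon_families()
  prof <- lapply(fams, function(codons) {
    p <- codon_profile[codons]
    p[is.na(p)] <- 0
    if (sum(p) <= 0) p <- rep(1, length(codons))
    names(p) <- codons
    p / sum(p)
  })
  ok <- vapply(prof, function(p) abs(sum(p) - 1) < 1e-6 && all(p >= 0),
               logical(1))
  if (!all(ok)) stop("invalid codon profile")
  aas <- names(fams)
  if (is.null(aa_freqs)) aa_freqs <- stats::setNames(rep(1, length(aas)), aas)
  aa_p <- aa_freqs[aas] / sum(aa_freqs[aas])
  .run_seeded(seed, {
    lapply(seq_len(n_genes), function(i) {
      len <- max(10L, stats::rpois(1, mean_length))
      aa_seq <- sample(aas, len, replace = TRUE, prob = aa_p)
      codons <- vapply(aa_seq, function(aa)
        sample(names(prof[[aa]]), 1, prob = prof[[aa]]), character(1))
      seqstr <- paste0("ATG", paste(codons, collapse = ""),
                       sample(stop_codons(), 1))
      validate_orf(coding_sequence(sprintf("gene%04d", i), seqstr,
                                   host = "synthetic_host"))
    })
  })
}

#' Simulate an element consensus with a target base composition
#'
#' Draws codons as three i.i.d. bases from `target_base_freqs`, rejecting
#' and redrawing stop codons, so the result is a valid ORF whose realized
#' composition converges on the target (within about 2 percentage points
#' for sequences of 1,000 codons or more; stop-codon rejection pulls
#' composition slightly away from extreme AT-rich targets).
#'
#' @param target_base_freqs named fractions `c(A=, C=, G=, T=)` summing
#'   to 1.
#' @param length_codons sequence length in codons.
#' @param seed integer seed.
#' @param id,clade,host,orf_label metadata for the record.
#' @return A frame-validated [coding_sequence()].
#' @export
simulate_element_consensus <- function(target_base_freqs, length_codons,
                                       seed = NULL, id = "consensus",
                                       clade = "synthetic", host = "synthetic",
                                       orf_label = "ORF2") {
  f <- target_base_freqs[c("A", "C", "G", "T")]
  stopifnot(!any(is.na(f)), abs(sum(f) - 1) < 1e-6, all(f >= 0))
  .run_seeded(seed, {
    bases <- names(f)
    draw <- function(n) sample(bases, n, replace = TRUE, prob = f)
    codons <- paste0(draw(length_codons), draw(length_codons), draw(length_codons))
    for (iter in 1:1000) {
      bad <- which(codons %in% stop_codons())
      if (!length(bad)) break
      codons[bad] <- paste0(draw(length(bad)), draw(length(bad)), draw(length(bad)))
    }
    if (any(codons %in% stop_codons()))
      stop("could not realize a stop-free sequence at this composition")
    validate_orf(coding_sequence(id, paste(codons, collapse = ""),
                                 clade = clade, host = host,
                                 orf_label = orf_label))
  })
}

# mutate a character vector of bases: per-site Bernoulli with probability
# p_site, substitution target drawn from the matrix row of the source base;
# returns list(seq =, events = data.frame(position, from, to))
.mutate_sites <- function(ch, p_site, substitution_matrix) {
  hit <- which(stats::runif(length(ch)) < p_site & ch %in% c("A", "C", "G", "T"))
  if (!length(hit))
    return(list(seq = ch, events = data.frame(position = integer(0),
                                              from = character(0),
                                              to = character(0))))
  from <- ch[hit]
  to <- vapply(from, function(b) {
    w <- substitution_matrix[b, ]
    w[b] <- 0
    sample(colnames(substitution_matrix), 1, prob = w)
  }, character(1))
  ch[hit] <- to
  list(seq = ch, events = data.frame(position = hit, from = from, to = to))
}

# per-site relative rate weights: cpg_multiplier for C followed by G and
# for G preceded by C, 1 elsewhere; evaluated on the current ancestral seq
.cpg_weights <- function(ch, cpg_multiplier) {
  L <- length(ch)
  w <- rep(1, L)
  if (cpg_multiplier != 1 && L >= 2) {
    is_cpg_c <- ch[-L] == "C" & ch[-1] == "G"
    w[which(is_cpg_c)] <- cpg_multiplier
    w[which(is_cpg_c) + 1L] <- cpg_multiplier
  }
  w
}

#' Default substitution-rate matrix (transition-biased)
#'
#' Row-stochastic off-diagonal weights with transitions twice as likely as
#' each transversion, the classic first-order approximation to vertebrate
#' nuclear mutation.
#'
#' @return 4x4 numeric matrix, rows = from-base, columns = to-base, zero
#'   diagonal, rows summing to 1.
#' @export
default_substitution_matrix <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(1, 4, 4, dimnames = list(b, b))
  diag(m) <- 0
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- 2
  m / rowSums(m)
}

#' Simulate a family of diverged genomic copies
#'
#' A star-tree copy process with an optional shared ancestral branch: a
#' fraction `shared_fraction` of the target divergence is applied once to
#' the consensus (those mutations are inherited by every copy, emulating
#' changes on the progenitor's branch), then each copy independently
#' accrues the remaining divergence.  Per-site rates are uniform except
#' that C/G in CpG context (evaluated on the current ancestral sequence at
#' injection time) are multiplied by `cpg_multiplier`; rates are rescaled
#' so the expected per-copy divergence equals `expected_divergence`.
#' Substitution targets follow `substitution_matrix`.  Copies may acquire
#' stop codons (pseudogenized copies are realistic); no indels are
#' simulated.
#'
#' @param consensus a [coding_sequence()] (ungapped).
#' @param n_copies number of copies (>= 2).
#' @param expected_divergence expected per-copy divergence from the
#'   consensus, in `[0, 0.5)`.
#' @param substitution_matrix 4x4 row-stochastic weights (zero diagonal);
#'   default [default_substitution_matrix()].
#' @param cpg_multiplier rate multiplier for CpG-context C/G (>= 1).
#' @param shared_fraction fraction of divergence placed on the shared
#'   ancestral branch, in `[0, 1)`.
#' @param seed integer seed.
#' @return A [family_bundle()] whose attribute `"injection_log"` is a data
#'   frame of every injected mutation (`copy`, `position`, `from`, `to`,
#'   `branch` = `"ancestral"`/`"copy"`), with `from` the base before the
#'   event on that branch.
#' @export
simulate_family <- function(consensus, n_copies,
                            expected_divergence,
                            substitution_matrix = default_substitution_matrix(),
                            cpg_multiplier = 1,
                            shared_fraction = 0,
                            seed = NULL) {
  stopifnot(inherits(consensus, "coding_sequence"), n_copies >= 2,
            expected_divergence >= 0, shared_fraction >= 0,
            shared_fraction < 1, cpg_multiplier >= 1)
  if (expected_divergence > 0.5)
    stop("expected_divergence > 0.5: the no-back-mutation model breaks down")
  m <- substitution_matrix[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  stopifnot(all(diag(m) == 0), all(m >= 0))
  cons_ch <- strsplit(consensus$sequence, "")[[1]]
  L <- length(cons_ch)
  .run_seeded(seed, {
    # shared ancestral branch
    w <- .cpg_weights(cons_ch, cpg_multiplier)
    d_shared <- shared_fraction * expected_divergence
    anc <- .mutate_sites(cons_ch, d_shared * w * L / sum(w), m)
    log_list <- list()
    if (nrow(anc$events))
      log_list[["ancestral"]] <- cbind(copy = "ancestral", anc$events,
                                       branch = "ancestral")
    # independent copy branches from the (possibly mutated) ancestor
    w2 <- .cpg_weights(anc$seq, cpg_multiplier)
    d_copy <- (1 - shared_fraction) * expected_divergence
    p_copy <- pmin(d_copy * w2 * L / sum(w2), 0.999)
    copies <- character(n_copies)
    for (k in seq_len(n_copies)) {
      nm <- sprintf("copy%02d", k)
      res <- .mutate_sites(anc$seq, p_copy, m)
      copies[k] <- paste(res$seq, collapse = "")
      if (nrow(res$events))
        log_list[[nm]] <- cbind(copy = nm, res$events, branch = "copy")
    }
    names(copies) <- sprintf("copy%02d", seq_len(n_copies))
    bundle <- family_bundle(consensus, copies)
    attr(bundle, "injection_log") <-
      if (length(log_list)) do.call(rbind, log_list)
      else data.frame(copy = character(0), position = integer(0),
                      from = character(0), to = character(0),
                      branch = character(0))
    rownames(attr(bundle, "injection_log")) <- NULL
    bundle
  })
}

#' Write a family bundle as a gapped alignment FASTA
#'
#' First record is the consensus, matching what [read_family_alignment()]
#' expects.
#'
#' @param bundle a [family_bundle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_alignment <- function(bundle, path) {
  set <- Biostrings::BStringSet(c(bundle$consensus_aligned, bundle$copies))
  names(set) <- c(bundle$consensus$id, names(bundle$copies))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
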