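#' Build a codon-usage table
#'
#' Counts over the 61 sense codons plus the per-amino-acid conditional
#' frequencies (each synonymous family sums to 1; families with zero counts
#' have `NA` conditional frequencies).  Input may be a validated
#' [coding_sequence()], a list of them (counts pooled), or a named integer
#' vector of codon counts.
#'
#' @param x input sequence(s) or named count vector.
#' @param source `"query_sequence"` or `"host_reference"`, a label only.
#' @return Object of class `codon_usage_table` with elements `counts`
#'   (61 named integers), `cond_freq` (61 named numerics) and `source`.
#' @export
codon_usage_table <- function(x, source = "query_sequence") {
  sense <- sense_codons()
  counts <- stats::setNames(integer(length(sense)), sense)
  add_seq <- function(s) {
    codons <- iter_codons(s)
    codons <- codons[!attr(codons, "flagged")]
    codons <- codons[codons %in% sense]
    tab <- table(factor(codons, levels = sense))
    counts <<- counts + as.integer(tab)
  }
  if (inherits(x, "coding_sequence")) {
    add_seq(x)
  } else if (is.list(x)) {
    stopifnot(length(x) > 0)
    lapply(x, add_seq)
  } else if (is.numeric(x)) {
    stopifnot(!is.null(names(x)), all(names(x) %in% sense))
    counts[names(x)] <- as.integer(x)
  } else {
    stop("cannot build a codon-usage table from class ", class(x)[1])
  }
  structure(list(counts = counts,
                 cond_freq = .cond_freq(counts),
                 source = source),
            class = "codon_usage_table")
}

# per-amino-acid conditional frequencies from a 61-count vector
.cond_freq <- function(counts) {
  fams <- codon_families()
  cf <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  for (codons in fams) {
    tot <- sum(counts[codons])
    if (tot > 0) cf[codons] <- counts[codons] / tot
  }
  cf
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> source=%s, %d codons counted, %d/%d families observed\n",
              x$source, sum(x$counts),
              sum(vapply(codon_families(), function(f) sum(x$counts[f]) > 0, logical(1))),
              length(codon_families())))
  invisible(x)
}

#' Pool a host reference codon-usage table from a CDS set
#'
#' Codon counts are pooled over all frame-validated genes (genome-wide
#' pooling, the convention of codon-adaptation reference sets).  Records
#' failing frame validation are dropped with a warning.  Per-gene base
#' composition, used for host-versus-element comparisons, is attached as
#' attribute `"gene_composition"` (a data frame).
#'
#' @param cds_set list of [coding_sequence()] records (validated or not;
#'   validation is applied here).
#' @return A `codon_usage_table` with `source = "host_reference"`.
#' @export
build_reference_table <- function(cds_set) {
  stopifnot(is.list(cds_set), length(cds_set) > 0)
  val <- lapply(cds_set, validate_orf)
  ok <- vapply(val, `[[`, logical(1), "frame_validated")
  if (!any(ok)) stop("no frame-validated CDS in the reference set")
  if (any(!ok))
    warning(sum(!ok), " reference CDS failed frame validation and were dropped")
  val <- val[ok]
  tab <- codon_usage_table(val, source = "host_reference")
  gene_comp <- do.call(rbind, lapply(val, function(s) {
    b <- base_composition(s)
    data.frame(id = s$id, pct_AT = b$pct_AT, pct_GC = b$pct_GC,
               pct_A = b$pct_A, length_nt = nchar(s$sequence))
  }))
  attr(tab, "gene_composition") <- gene_comp
  tab
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family, so within each family the values sum to the family size;
#' 1 everywhere means unbiased usage.  Single-codon families (Met, Trp)
#' are reported as 1 when observed.
#'
#' @param table a [codon_usage_table()].
#' @return Named numeric vector over the 61 sense codons; `NA` for codons
#'   whose family was never observed.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fams <- codon_families()
  out <- stats::setNames(rep(NA_real_, length(table$counts)), names(table$counts))
  for (codons in fams) {
    tot <- sum(table$counts[codons])
    if (tot > 0) out[codons] <- table$counts[codons] / (tot / length(codons))
  }
  out
}

# Wright's degeneracy classes: named list class-size -> amino acids
.degeneracy_classes <- function() {
  fs <- .code("family_size")
  split(names(fs), fs)
}

#' Wright's effective number of codons (Nc)
#'
#' Nc quantifies how far synonymous codon usage deviates from equal use:
#' 20 when every amino acid is encoded by a single codon, 61 when all
#' synonymous codons are used equally.  The estimator averages the family
#' "homozygosity" F within each degeneracy class (2-, 3-, 4- and 6-fold)
#' and returns `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clipped to `[20, 61]`.
#'
#' @param x a `codon_usage_table` or a validated [coding_sequence()].
#' @param sample_correction logical; `FALSE` (default) uses the
#'   frequency-based homozygosity `F = sum(p^2)` under which the 20/61
#'   identities hold exactly; `TRUE` uses Wright's finite-sample estimator
#'   `F = (n*sum(p^2) - 1)/(n - 1)` (families with n < 2 are skipped).
#' @return Nc, a number in `[20, 61]`.
#' @export
effective_number_of_codons <- function(x, sample_correction = FALSE) {
  tab <- if (inherits(x, "codon_usage_table")) x else codon_usage_table(x)
  if (sum(tab$counts) == 0) stop("empty codon-usage table")
  fams <- codon_families()
  fs <- .code("family_size")
  f_hat <- vapply(names(fams), function(aa) {
    cnt <- tab$counts[fams[[aa]]]
    n <- sum(cnt)
    if (n == 0) return(NA_real_)
    p <- cnt / n
    if (sample_correction) {
      if (n < 2) return(NA_real_)
      (n * sum(p^2) - 1) / (n - 1)
    } else {
      sum(p^2)
    }
  }, numeric(1))
  class_mean <- function(k) {
    aas <- names(fs)[fs == k]
    v <- f_hat[aas]
    if (all(is.na(v))) {
      # degeneracy class unobserved: borrow the mean homozygosity of all
      # observed multi-codon families
      multi <- f_hat[names(fs)[fs > 1]]
      mean(multi, na.rm = TRUE)
    } else {
      mean(v, na.rm = TRUE)
    }
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(nc, 20), 61)
}

# Apply the zero-reference pseudo-count rule: within every family that the
# query uses, reference codons with zero count get +`pseudocount`, and the
# family's conditional frequencies are recomputed.
.reference_with_pseudocounts <- function(query_counts, reference,
                                         pseudocount = 0.5) {
  counts <- as.numeric(reference$counts)
  names(counts) <- names(reference$counts)
  fams <- codon_families()
  for (codons in fams) {
    if (sum(query_counts[codons]) == 0) next
    if (sum(counts[codons]) == 0) {
      # family entirely absent from reference: uniform pseudo-counts
      counts[codons] <- pseudocount
    } else if (any(counts[codons][query_counts[codons] > 0] == 0)) {
      counts[codons[counts[codons] == 0]] <- pseudocount
    }
  }
  list(counts = counts, cond_freq = .cond_freq(counts))
}

#' Codon Adaptation Index
#'
#' CAI is the geometric mean, over the query's codon occurrences, of the
#' relative adaptiveness `w = f_ref(codon) / max f_ref(synonym)` computed
#' from the reference set's conditional codon frequencies.  Single-codon
#' families (Met, Trp) are excluded, as are stops.  CAI = 1 means the query
#' always uses the reference's most common synonym.
#'
#' @param query a `codon_usage_table` or validated [coding_sequence()].
#' @param reference host reference `codon_usage_table`.
#' @param pseudocount added to zero-count reference codons within families
#'   the query uses (avoids `w = 0`); set to 0 to disable.
#' @return CAI in (0, 1].
#' @export
cai <- function(query, reference, pseudocount = 0.5) {
  qtab <- if (inherits(query, "codon_usage_table")) query else codon_usage_table(query)
  stopifnot(inherits(reference, "codon_usage_table"))
  ref <- .reference_with_pseudocounts(qtab$counts, reference, pseudocount)
  fams <- codon_families()
  fs <- .code("family_size")
  multi <- unlist(fams[names(fs)[fs > 1]], use.names = FALSE)
  w <- stats::setNames(rep(NA_real_, length(qtab$counts)), names(qtab$counts))
  for (aa in names(fams)) {
    if (fs[[aa]] < 2) next
    codons <- fams[[aa]]
    f <- ref$cond_freq[codons]
    if (all(is.na(f))) next
    w[codons] <- f / max(f, na.rm = TRUE)
  }
  cnt <- qtab$counts[multi]
  wv <- w[multi]
  use <- cnt > 0 & !is.na(wv) & wv > 0
  if (sum(cnt[use]) == 0)
    stop("query has no codon occurrences in degenerate families")
  exp(sum(cnt[use] * log(wv[use])) / sum(cnt[use]))
}

#' Relative Codon Deoptimization Index
#'
#' RCDI is the mean, over the query's codon occurrences, of the ratio
#' between the query's and the reference's conditional codon frequencies.
#' It equals 1 when the query's synonymous codon usage is identical to the
#' reference's and grows as usage is deoptimized away from the host.
#'
#' @inheritParams cai
#' @return RCDI >= 0 (1 = identical usage).
#' @export
rcdi <- function(query, reference, pseudocount = 0.5) {
  qtab <- if (inherits(query, "codon_usage_table")) query else codon_usage_table(query)
  stopifnot(inherits(reference, "codon_usage_table"))
  ref <- .reference_with_pseudocounts(qtab$counts, reference, pseudocount)
  cnt <- qtab$counts
  use <- cnt > 0
  if (!any(use)) stop("empty query codon-usage table")
  q <- qtab$cond_freq[use]
  r <- ref$cond_freq[use]
  if (any(is.na(r) | r == 0))
    stop("reference family absent for a codon used by the query")
  sum(cnt[use] * (q / r)) / sum(cnt)
}

# codon sampling distribution implied by a base composition: probability
# of each sense codon proportional to the product of its three base
# frequencies, stops excluded and renormalized
.codon_probs_from_composition <- function(frac) {
  sense <- sense_codons()
  p <- vapply(sense, function(cd) {
    b <- strsplit(cd, "")[[1]]
    prod(frac[b])
  }, numeric(1))
  if (sum(p) <= 0)
    stop("degenerate base composition: no sense codon has positive probability")
  p / sum(p)
}

.run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Expected CAI under random codon usage at the query's base composition
#'
#' Generates random coding sequences of the query's codon length, drawing
#' each codon with probability proportional to the product of the query's
#' mononucleotide frequencies (stop codons excluded, renormalized), and
#' summarizes the CAI distribution of the replicates.  eCAI close to the
#' observed CAI indicates no synonymous bias beyond base composition.
#'
#' @param query a validated [coding_sequence()].
#' @param reference host reference `codon_usage_table`.
#' @param n_random number of random replicates (>= 100).
#' @param seed integer seed; replicate streams are reproducible.
#' @param summary `"mean"` (default) or `"q95"` (95th percentile).
#' @param pseudocount see [cai()].
#' @return eCAI, a number in (0, 1].
#' @export
expected_cai <- function(query, reference, n_random = 500, seed = NULL,
                         summary = c("mean", "q95"), pseudocount = 0.5) {
  summary <- match.arg(summary)
  stopifnot(n_random >= 100)
  comp <- base_composition(query)
  frac <- c(A = comp$frac_A, C = comp$frac_C, G = comp$frac_G, T = comp$frac_T)
  p <- .codon_probs_from_composition(frac)
  n_codons <- length(iter_codons(query))
  sense <- sense_codons()
  vals <- .run_seeded(seed, {
    draws <- stats::rmultinom(n_random, n_codons, p)  # 61 x n_random
    rownames(draws) <- sense
    apply(draws, 2, function(cnt)
      cai(codon_usage_table(stats::setNames(cnt, sense)), reference,
          pseudocount = pseudocount))
  })
  if (summary == "mean") mean(vals) else unname(stats::quantile(vals, 0.95))
}

#' Expected RCDI under composition-driven synonymous codon choice
#'
#' Each replicate keeps the query's amino-acid sequence and redraws every
#' codon among its synonyms with probability proportional to the product of
#' the query's mononucleotide frequencies; the mean RCDI of the replicates
#' estimates the RCDI expected from base composition alone.
#'
#' @inheritParams expected_cai
#' @return eRCDI >= 0.
#' @export
expected_rcdi <- function(query, reference, n_random = 500, seed = NULL,
                          pseudocount = 0.5) {
  stopifnot(n_random >= 100)
  comp <- base_composition(query)
  frac <- c(A = comp$frac_A, C = comp$frac_C, G = comp$frac_G, T = comp$frac_T)
  codon_p <- .codon_probs_from_composition(frac)
  aa_counts <- aa_composition(query)
  fams <- codon_families()
  sense <- sense_codons()
  vals <- .run_seeded(seed, {
    counts <- matrix(0L, nrow = length(sense), ncol = n_random,
                     dimnames = list(sense, NULL))
    for (aa in names(aa_counts)) {
      n_aa <- aa_counts[[aa]]
      if (n_aa == 0) next
      codons <- fams[[aa]]
      p_aa <- codon_p[codons]
      if (sum(p_aa) <= 0) p_aa <- rep(1, length(codons))
      counts[codons, ] <- counts[codons, , drop = FALSE] +
        stats::rmultinom(n_random, n_aa, p_aa)
    }
    apply(counts, 2, function(cnt)
      rcdi(codon_usage_table(stats::setNames(cnt, sense)), reference,
           pseudocount = pseudocount))
  })
  mean(vals)
}
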