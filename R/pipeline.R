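#' Per-family composition report with group aggregation
#'
#' One row per consensus with the composition columns of the standard
#' family table (%AT, %GC, %A, GC1-3, polyA count) plus the 16
#' dinucleotide observed/expected ratios, aggregated as unweighted
#' mean +/- sd by (clade, host).
#'
#' @param consensi list of frame-validated [coding_sequence()] records.
#' @param motifs polyA motifs, see [count_polya_signals()].
#' @return List with `per_sequence` and `by_group` data frames.
#' @export
run_composition <- function(consensi, motifs = c("AATAAA", "ATTAAA")) {
  if (length(consensi) == 0) {
    empty <- data.frame(id = character(0), clade = character(0),
                        host = character(0), orf = character(0))
    return(list(per_sequence = empty, by_group = empty))
  }
  rows <- lapply(consensi, function(s) {
    p <- composition_profile(s, motifs)
    ratios <- as.list(p$dinucleotide$ratio)
    names(ratios) <- paste0("ratio_", names(ratios))
    cbind(data.frame(id = s$id, clade = s$clade, host = s$host,
                     orf = s$orf_label, length_nt = nchar(s$sequence),
                     pct_AT = p$pct_AT, pct_GC = p$pct_GC, pct_A = p$pct_A,
                     gc1 = p$gc["gc1"], gc2 = p$gc["gc2"], gc3 = p$gc["gc3"],
                     polya = p$polya_count,
                     dinuc_chisq = p$dinucleotide$chisq,
                     dinuc_p = p$dinucleotide$p_value),
          as.data.frame(ratios))
  })
  per_seq <- do.call(rbind, rows)
  rownames(per_seq) <- NULL
  num_cols <- c("pct_AT", "pct_GC", "pct_A", "gc1", "gc2", "gc3", "polya")
  by_group <- .aggregate_mean_sd(per_seq, num_cols)
  list(per_sequence = per_seq, by_group = by_group)
}

# unweighted mean +/- sd per (clade, host) for the given columns
.aggregate_mean_sd <- function(df, cols) {
  key <- interaction(df$clade, df$host, drop = TRUE, sep = "/")
  groups <- split(df, key)
  out <- lapply(groups, function(g) {
    row <- data.frame(clade = g$clade[1], host = g$host[1], n = nrow(g))
    for (cl in cols) {
      row[[paste0(cl, "_mean")]] <- mean(g[[cl]])
      row[[paste0(cl, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[cl]]) else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$clade, res$host), , drop = FALSE]
}

#' Per-family codon-usage report
#'
#' Nc, CAI/eCAI and RCDI/eRCDI per consensus against a host reference
#' table, plus (clade, host) aggregation and the paired z comparison of
#' observed versus expected RCDI.
#'
#' @param consensi list of frame-validated [coding_sequence()] records.
#' @param reference a host reference [codon_usage_table()].
#' @param n_random replicates for eCAI/eRCDI.
#' @param seed integer seed (per-sequence streams derived from it).
#' @param ecai_summary `"mean"` or `"q95"`, see [expected_cai()].
#' @return List with `per_sequence`, `by_group` and `rcdi_z` (data frames).
#' @export
run_codon_usage <- function(consensi, reference, n_random = 500, seed = 1,
                            ecai_summary = "mean") {
  stopifnot(length(consensi) > 0)
  rows <- lapply(seq_along(consensi), function(i) {
    s <- consensi[[i]]
    tab <- codon_usage_table(s)
    data.frame(id = s$id, clade = s$clade, host = s$host, orf = s$orf_label,
               nc = effective_number_of_codons(tab),
               cai = cai(tab, reference),
               ecai = expected_cai(s, reference, n_random = n_random,
                                   seed = seed + i, summary = ecai_summary),
               rcdi = rcdi(tab, reference),
               ercdi = expected_rcdi(s, reference, n_random = n_random,
                                     seed = seed + i))
  })
  per_seq <- do.call(rbind, rows)
  rownames(per_seq) <- NULL
  by_group <- .aggregate_mean_sd(per_seq, c("nc", "cai", "ecai", "rcdi", "ercdi"))
  rcdi_z <- if (nrow(per_seq) >= 2 && stats::sd(per_seq$rcdi - per_seq$ercdi) > 0)
    paired_z_test(per_seq$rcdi, per_seq$ercdi) else NULL
  list(per_sequence = per_seq, by_group = by_group, rcdi_z = rcdi_z)
}

#' Mutation-spectrum report over a set of families
#'
#' Applies the copy-count and divergence filters, then computes per-family
#' and pooled singleton spectra.
#'
#' @param bundles list of [family_bundle()] objects.
#' @param min_copies minimum copies per family (default 8).
#' @param max_divergence mean-divergence threshold (default 0.05).
#' @param singletons_only see [mutation_spectrum()].
#' @return List with `per_family` (data frame of normalized spectra, one
#'   block of 12 rows per family), `pooled` (a `mutation_spectrum`),
#'   `n_families_used`, `n_families_dropped`.
#' @export
run_mutation <- function(bundles, min_copies = 8, max_divergence = 0.05,
                         singletons_only = TRUE) {
  enough <- vapply(bundles, function(b)
    length(b$copies) >= min_copies, logical(1))
  kept <- filter_families_by_divergence(bundles[enough], max_divergence)
  n_dropped <- attr(kept, "n_dropped") + sum(!enough)
  if (length(kept) == 0)
    stop("no families pass the copy-count and divergence filters")
  per_family <- do.call(rbind, lapply(kept, function(b) {
    ms <- mutation_spectrum(b, singletons_only = singletons_only)
    cbind(family = b$consensus$id, ms$spectrum,
          gc_to_at_excess = ms$gc_to_at_excess,
          n_singletons = ms$n_singletons)
  }))
  rownames(per_family) <- NULL
  list(per_family = per_family,
       pooled = pooled_mutation_spectrum(kept, singletons_only = singletons_only),
       n_families_used = length(kept),
       n_families_dropped = n_dropped)
}

#' Paired ORF1 versus ORF2 composition comparison
#'
#' Families contributing both ORFs (same id after stripping a trailing
#' `_ORF1`/`_ORF2` suffix, or explicitly paired via the `family` argument)
#' are compared on %AT with a paired t-test (when >= 2 pairs).
#'
#' @param consensi list of frame-validated [coding_sequence()] records with
#'   `orf_label` set to `"ORF1"` or `"ORF2"`.
#' @param family optional character vector of family keys, one per record;
#'   by default the id with a trailing `_ORF1/2` stripped.
#' @return List with `pairs` (per-family %AT for both ORFs and the
#'   difference ORF2 - ORF1) and `t_test` (`NULL` with fewer than 2 pairs).
#' @export
run_orf_compare <- function(consensi, family = NULL) {
  orf <- vapply(consensi, `[[`, character(1), "orf_label")
  if (is.null(family))
    family <- sub("_ORF[12]$", "", vapply(consensi, `[[`, character(1), "id"))
  at <- vapply(consensi, function(s) base_composition(s)$pct_AT, numeric(1))
  d1 <- data.frame(family = family, orf = orf, pct_AT = at)
  wide <- merge(d1[d1$orf == "ORF1", c("family", "pct_AT")],
                d1[d1$orf == "ORF2", c("family", "pct_AT")],
                by = "family", suffixes = c("_orf1", "_orf2"))
  if (nrow(wide) == 0) {
    warning("no families with both ORFs")
    return(list(pairs = wide, t_test = NULL))
  }
  wide$difference <- wide$pct_AT_orf2 - wide$pct_AT_orf1
  t_test <- NULL
  if (nrow(wide) >= 2 && stats::sd(wide$difference) > 0) {
    tt <- stats::t.test(wide$pct_AT_orf2, wide$pct_AT_orf1, paired = TRUE)
    t_test <- data.frame(test = "paired_t", statistic = unname(tt$statistic),
                         df = unname(tt$parameter), p_value = tt$p.value,
                         mean_difference = mean(wide$difference),
                         n = nrow(wide))
  }
  list(pairs = wide, t_test = t_test)
}

#' Write a report table as TSV with a commented header
#'
#' @param df data frame.
#' @param path output path.
#' @param header named character/numeric vector written as `# key: value`
#'   lines (record the seed and key parameters here).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
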