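#!/usr/bin/env Rscript
# Stage 5: the formal statistical comparisons over the stage 2-3 tables.
#
# Normality screening per group, ANOVA of %AT among clades within host and
# among hosts within clade, element-vs-host-gene t-tests, and the two
# regressions (polyA ~ %AT, RCDI ~ GC3).  One row per test in
# results/statistical_comparisons.tsv.

suppressPackageStartupMessages(library(retrocomp))

comp <- read.delim("results/composition_per_family.tsv", comment.char = "#")
cu <- read.delim("results/codon_usage_per_family.tsv", comment.char = "#")

rows <- list()
add <- function(label, df) {
  df$comparison <- label
  rows[[length(rows) + 1]] <<- df[c("comparison", setdiff(names(df), "comparison"))]
}

# normality screening of %AT: per clade/host group where n allows, and
# always for the host gene sets (the group comparisons assume roughly
# normal within-group distributions)
for (key in unique(paste(comp$clade, comp$host))) {
  vals <- comp$pct_AT[paste(comp$clade, comp$host) == key]
  if (length(vals) >= 5) add(paste("KS normality %AT", key), normality_check(vals))
}
for (h in unique(comp$host)) {
  genes <- read_cds_fasta(sprintf("results/simdata/host_cds_%s.fa", h))
  gene_at <- attr(build_reference_table(genes), "gene_composition")$pct_AT
  add(paste("KS normality %AT host genes", h), normality_check(gene_at))
}

# clades within host, hosts within clade
for (h in unique(comp$host)) {
  sub <- comp[comp$host == h, ]
  add(paste("%AT among clades in", h),
      compare_groups(sub$pct_AT, sub$clade, "anova"))
}
for (cl in unique(comp$clade)) {
  sub <- comp[comp$clade == cl, ]
  add(paste("%AT between hosts for", cl),
      compare_groups(sub$pct_AT, sub$host, "t_test"))
}

# element vs host-gene composition per host
for (h in unique(comp$host)) {
  genes <- read_cds_fasta(sprintf("results/simdata/host_cds_%s.fa", h))
  ref <- build_reference_table(genes)
  gene_at <- attr(ref, "gene_composition")$pct_AT
  el_at <- comp$pct_AT[comp$host == h & comp$clade == "L1like"]
  add(paste("L1like vs host genes %AT in", h),
      compare_groups(c(el_at, gene_at),
                     rep(c("element", "host"), c(length(el_at), length(gene_at))),
                     "t_test"))
}

# the two regressions
add("polyA ~ %AT", regress(comp$pct_AT, comp$polya))
m <- merge(cu, comp[c("id", "gc3")], by = "id")
add("RCDI ~ GC3", regress(m$gc3, m$rcdi))
add("observed vs expected RCDI (paired z)", paired_z_test(m$rcdi, m$ercdi))

out <- do.call(rbind, lapply(rows, function(df) {
  # regression rows carry slope rather than a named statistic
  if (is.null(df$test)) df$test <- "ols"
  if (is.null(df$statistic)) df$statistic <- df$slope
  base <- data.frame(comparison = df$comparison,
                     test = df$test,
                     statistic = df$statistic,
                     p_value = df$p_value)
  base$detail <- paste(vapply(setdiff(names(df),
                                      c("comparison", "test", "statistic", "p_value")),
                              function(cn) sprintf("%s=%s", cn, signif(df[[cn]], 4)),
                              character(1)), collapse = "; ")
  base
}))
write_report_tsv(out, "results/statistical_comparisons.tsv",
                 c(stage = "05_stats"))
message("comparisons written:")
for (i in seq_len(nrow(out)))
  message(sprintf("  %-42s %-12s stat %9.3f  p %.3g",
                  out$comparison[i], out$test[i], out$statistic[i],
                  out$p_value[i]))
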