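#!/usr/bin/env Rscript
# Stage 1: build the synthetic study set with known ground truth.
#
# Emulates the structure of a vertebrate retroelement survey: consensus
# ORF2 sequences for AT-rich ("L1-like", A-biased), balanced ("Rex1-like")
# and GC-rich ("L2-like") clades in two hosts, a host gene set with a
# GC-leaning codon-usage profile per host, and, for a subset of families,
# genomic copies diverged under a transition-biased substitution model
# with CpG hypermutability and a shared ancestral branch.
#
# Writes FASTA inputs under results/simdata/ that the later stages read
# back through the package's own parsers, exactly as a real dataset would
# enter the pipeline.

suppressPackageStartupMessages(library(retrocomp))

seed <- 20260401
set.seed(seed)
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clades <- list(
  L1like   = list(at = 0.65, a_share = 0.62),  # AT-rich, A-biased strand
  Rex1like = list(at = 0.50, a_share = 0.52),
  L2like   = list(at = 0.44, a_share = 0.48)
)
hosts <- c("lizardlike", "fishlike")
n_fam_per_group <- 4
len_codons <- 800

consensi <- list()
k <- 0
for (host in hosts) for (cl in names(clades)) {
  cfg <- clades[[cl]]
  for (i in seq_len(n_fam_per_group)) {
    k <- k + 1
    at <- cfg$at + stats::runif(1, -0.02, 0.02)
    f <- c(A = at * cfg$a_share, C = (1 - at) / 2,
           G = (1 - at) / 2, T = at * (1 - cfg$a_share))
    f <- f / sum(f)
    consensi[[k]] <- simulate_element_consensus(
      f, len_codons, seed = seed + k,
      id = sprintf("%s_%s_fam%02d", cl, host, i),
      clade = cl, host = host, orf_label = "ORF2")
  }
}
write_cds_fasta(consensi, file.path(out, "element_consensi.fa"))
message(length(consensi), " element consensi written")

# paired ORF1 records for the L1-like families: same bias direction but
# weaker, mirroring the ORF1 < ORF2 AT gradient seen in bicistronic clades
orf1 <- list()
for (cs in consensi) {
  if (cs$clade != "L1like") next
  b <- base_composition(cs)
  at1 <- (b$pct_AT - 4) / 100                     # ~4 points less AT
  f1 <- c(A = at1 * 0.58, C = (1 - at1) / 2, G = (1 - at1) / 2,
          T = at1 * 0.42)
  orf1[[length(orf1) + 1]] <- simulate_element_consensus(
    f1 / sum(f1), 350, seed = seed + 5000 + length(orf1),
    id = sub("$", "_ORF1", cs$id), clade = cs$clade, host = cs$host,
    orf_label = "ORF1")
}
# matching ORF2 ids for the pairing key
orf2 <- lapply(consensi[vapply(consensi, `[[`, "", "clade") == "L1like"],
               function(cs) { cs$id <- paste0(cs$id, "_ORF2"); cs })
write_cds_fasta(c(orf1, orf2), file.path(out, "orf_pairs.fa"))

# host gene sets: GC-leaning codon profile, stronger in the fish-like host
for (host in hosts) {
  wexp <- if (host == "lizardlike") 1.5 else 2.0
  prof <- vapply(sense_codons(), function(cod)
    wexp^(sum(strsplit(cod, "")[[1]] %in% c("G", "C"))), numeric(1))
  genes <- simulate_host_cds(prof, n_genes = 150, mean_length = 350,
                             seed = seed + match(host, hosts))
  write_cds_fasta(genes, file.path(out, sprintf("host_cds_%s.fa", host)))
}
message("host CDS sets written")

# copy families for the mutation-spectrum stage: one per clade/host from
# the first consensus of each group, 10 copies, 2% divergence, CpG x10,
# 20% shared ancestral mutations
dir.create(file.path(out, "families"), showWarnings = FALSE)
fam_idx <- 0
truth <- list()
for (cs in consensi) {
  if (!grepl("fam01$", cs$id)) next
  fam_idx <- fam_idx + 1
  fam <- simulate_family(cs, n_copies = 10, expected_divergence = 0.02,
                         cpg_multiplier = 10, shared_fraction = 0.2,
                         seed = seed + 700 + fam_idx)
  write_family_alignment(fam, file.path(out, "families",
                                        paste0(cs$id, ".aln.fa")))
  log <- attr(fam, "injection_log")
  truth[[cs$id]] <- data.frame(family = cs$id, n_injected = nrow(log),
                               n_ancestral = sum(log$branch == "ancestral"))
}
write_report_tsv(do.call(rbind, truth), file.path(out, "injection_truth.tsv"),
                 c(seed = seed))
message(fam_idx, " copy families written; stage 1 done")
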