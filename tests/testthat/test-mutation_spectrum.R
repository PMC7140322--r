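simple_bundle <- function(cons, copies) {
  family_bundle(coding_sequence("fam", cons), copies)
}

test_that("variant calling reports substitutions in consensus coordinates", {
  b <- simple_bundle("ACGT", c(c1 = "ACGT"))
  expect_equal(nrow(call_variants(b)), 0)
  b2 <- simple_bundle("ACGT", c(c1 = "ATGT"))
  v <- call_variants(b2)
  expect_equal(v$position, 2L)   # 1-based: second base
  expect_equal(v$from, "C")
  expect_equal(v$to, "T")
  # gap and N columns are skipped, coordinates follow the ungapped consensus
  cons_rec <- coding_sequence("fam", "ACGT")
  cons_rec$sequence <- "AC-GT"
  b3 <- family_bundle(cons_rec, c(c1 = "ACAGA", c2 = "NCTGT"))
  v3 <- call_variants(b3)
  expect_equal(v3$position[v3$copy == "c1"], 4L)  # T->A at ungapped pos 4...
  expect_equal(v3$to[v3$copy == "c1"], "A")
  expect_equal(nrow(v3[v3$copy == "c2", ]), 0)    # N col and match only
  expect_error(simple_bundle("ACGT", c(c1 = "ACGTT")), "length mismatch")
})

test_that("variant calls match the column-walking oracle on random alignments", {
  set.seed(101)
  for (i in 1:30) {
    cons <- rand_seq_str(60, c(A = .3, C = .2, G = .2, T = .25, N = .05))
    copy <- rand_seq_str(60, c(A = .3, C = .2, G = .2, T = .25, N = .05))
    b <- simple_bundle(cons, c(c1 = copy))
    got <- call_variants(b)
    want <- oracle_variants(cons, copy)
    expect_equal(got$position, want$position)
    expect_equal(got$from, want$from)
    expect_equal(got$to, want$to)
  }
})

test_that("singleton filtering keeps exactly-once triples", {
  v <- data.frame(copy = c("a", "b", "c"),
                  position = c(10L, 10L, 4L),
                  from = c("C", "C", "G"),
                  to = c("T", "T", "A"))
  s <- filter_singletons(v)
  expect_equal(nrow(s), 1)
  expect_equal(s$from, "G")
  # all-unique input is unchanged
  v2 <- data.frame(copy = c("a", "b"), position = c(1L, 2L),
                   from = c("A", "C"), to = c("G", "T"))
  expect_equal(nrow(filter_singletons(v2)), 2)
  # two different substitutions at one position remain singletons
  v3 <- data.frame(copy = c("a", "b"), position = c(5L, 5L),
                   from = c("C", "C"), to = c("T", "A"))
  expect_equal(nrow(filter_singletons(v3)), 2)
})

test_that("shared ancestral mutations are removed by the singleton filter", {
  cons <- simulate_element_consensus(c(A = .3, C = .2, G = .2, T = .3),
                                     400, seed = 5)
  fam <- simulate_family(cons, n_copies = 10, expected_divergence = 0.03,
                         shared_fraction = 0.4, seed = 6)
  log <- attr(fam, "injection_log")
  anc <- log[log$branch == "ancestral", ]
  expect_gt(nrow(anc), 0)
  singles <- filter_singletons(call_variants(fam))
  # no ancestral (position, from, to) survives: inherited by all 10 copies
  anc_keys <- paste(anc$position, anc$from, anc$to)
  single_keys <- paste(singles$position, singles$from, singles$to)
  expect_length(intersect(anc_keys, single_keys), 0)
  # dropping the filter biases the spectrum toward ancestral-branch types
  all_v <- call_variants(fam)
  expect_gt(nrow(all_v), nrow(singles))
})

test_that("CpG context classification matches a dinucleotide scan", {
  v <- data.frame(position = 2L, from = "C", to = "T")
  expect_equal(as.character(classify_cpg_context(v, "ACGT")$context), "CpG")
  expect_equal(as.character(classify_cpg_context(v, "ACTT")$context), "nonCpG")
  vg <- data.frame(position = 3L, from = "G", to = "A")
  expect_equal(as.character(classify_cpg_context(vg, "TTGC")$context), "nonCpG")
  expect_equal(as.character(classify_cpg_context(vg, "TCGC")$context), "CpG")
  # edges: missing neighbor is non-CpG
  edge <- data.frame(position = c(1L, 4L), from = c("G", "C"), to = c("A", "T"))
  ctx <- classify_cpg_context(edge, "GTAC")
  expect_equal(as.character(ctx$context), c("nonCpG", "nonCpG"))
  # oracle: brute-force scan on random consensi
  set.seed(57)
  for (i in 1:20) {
    cons <- rand_seq_str(50)
    pos <- sample(50, 10)
    ch <- strsplit(cons, "")[[1]]
    v <- data.frame(position = pos, from = ch[pos],
                    to = "A")
    v <- v[v$from %in% c("C", "G"), , drop = FALSE]
    if (!nrow(v)) next
    got <- classify_cpg_context(v, cons)
    for (j in seq_len(nrow(v))) {
      p <- v$position[j]
      want <- if (v$from[j] == "C" && p < 50 && ch[p + 1] == "G") "CpG"
        else if (v$from[j] == "G" && p > 1 && ch[p - 1] == "C") "CpG"
        else "nonCpG"
      expect_equal(as.character(got$context[j]), want)
    }
  }
})

test_that("normalization divides by source-base opportunity and sums to 100", {
  # counts {C>T: 2} on 10 C and {A>G: 1} on 20 A -> rates .2/.05 -> 80/20
  cons <- paste0(strrep("C", 10), strrep("A", 20))
  v <- data.frame(copy = c("x", "x", "y"), position = c(1L, 2L, 11L),
                  from = c("C", "C", "A"), to = c("T", "T", "G"))
  spec <- normalize_spectrum(count_spectrum(v), cons)
  expect_equal(spec$rate[spec$type == "C>T"], 0.2)
  expect_equal(spec$rate[spec$type == "A>G"], 0.05)
  expect_equal(spec$normalized_pct[spec$type == "C>T"], 80)
  expect_equal(spec$normalized_pct[spec$type == "A>G"], 20)
  expect_equal(sum(spec$normalized_pct, na.rm = TRUE), 100, tolerance = 1e-6)
  # absent source base: G>* types undefined and reported
  expect_true(all(c("G>A", "G>C", "G>T") %in% attr(spec, "excluded_types")))
  # equal counts on a uniform consensus -> all normalized_pct equal
  cons_u <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  types <- expand.grid(from = c("A", "C", "G", "T"), to = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  types <- types[types$from != types$to, ]
  ch <- strsplit(cons_u, "")[[1]]
  v_u <- data.frame(copy = paste0("c", seq_len(nrow(types))),
                    position = vapply(types$from, function(f)
                      which(ch == f)[1], integer(1)),
                    from = types$from, to = types$to)
  spec_u <- normalize_spectrum(count_spectrum(v_u), cons_u)
  expect_equal(spec_u$normalized_pct, rep(100 / 12, 12), tolerance = 1e-9)
})

test_that("GC-to-AT excess has the symmetry and homogeneity properties", {
  sym <- data.frame(type = c("C>T", "C>A", "G>A", "G>T",
                             "T>C", "A>G", "A>C", "T>G"),
                    rate = rep(0.01, 8))
  expect_equal(gc_to_at_excess(sym), 1)
  dbl <- sym
  dbl$rate[1:4] <- dbl$rate[1:4] * 2
  expect_equal(gc_to_at_excess(dbl), 2)
  none <- data.frame(type = c("C>T", "T>C"), rate = c(0.1, 0))
  expect_warning(ex <- gc_to_at_excess(none), "infinite")
  expect_identical(ex, Inf)
})

test_that("divergence filter drops diverged families like a brute-force pass", {
  cons <- simulate_element_consensus(c(A = .25, C = .25, G = .25, T = .25),
                                     200, seed = 1)
  divs <- c(0.03, 0.07, 0.01, 0.049, 0.12)
  bundles <- lapply(seq_along(divs), function(i)
    simulate_family(cons, n_copies = 4, expected_divergence = divs[i],
                    seed = 100 + i))
  kept <- filter_families_by_divergence(bundles, 0.05)
  want <- vapply(bundles, function(b) mean(b$divergence) < 0.05, logical(1))
  expect_length(kept, sum(want))
  expect_equal(attr(kept, "n_dropped"), sum(!want))
})

test_that("spectrum is invariant under copy-order permutation", {
  cons <- simulate_element_consensus(c(A = .3, C = .2, G = .2, T = .3),
                                     300, seed = 8)
  fam <- simulate_family(cons, n_copies = 6, expected_divergence = 0.03, seed = 9)
  perm <- fam
  set.seed(10)
  perm$copies <- perm$copies[sample(length(perm$copies))]
  s1 <- mutation_spectrum(fam)
  s2 <- mutation_spectrum(perm)
  expect_equal(s1$spectrum$count, s2$spectrum$count)
  expect_equal(s1$gc_to_at_excess, s2$gc_to_at_excess)
})
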