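toy_two_codon <- function(counts_phe = c(TTT = 8, TTC = 2)) {
  # reference using only a two-fold family keeps closed forms simple
  codon_usage_table(counts_phe, source = "host_reference")
}

test_that("RSCU family sums equal family sizes and match the formula", {
  tab <- codon_usage_table(c(TTT = 5, TTC = 5, GCT = 4, GCC = 0, GCA = 0, GCG = 0))
  r <- rscu(tab)
  expect_equal(unname(r["TTT"]), 1)
  expect_equal(unname(r["TTC"]), 1)
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), c(4, 0, 0, 0))
  # property: family sums equal family size on random tables
  set.seed(13)
  for (i in 1:10) {
    cs <- rand_cds(200)
    r <- rscu(codon_usage_table(cs))
    for (codons in codon_families()) {
      vals <- r[codons]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(codons), tolerance = 1e-9)
    }
  }
})

test_that("conditional frequencies sum to 1 within observed families", {
  set.seed(17)
  tab <- codon_usage_table(rand_cds(150))
  for (codons in codon_families()) {
    cf <- tab$cond_freq[codons]
    if (all(is.na(cf))) next
    expect_equal(sum(cf), 1, tolerance = 1e-9)
  }
})

test_that("Nc hits the definitional extremes and matches the direct oracle", {
  fams <- codon_families()
  one_per <- unlist(lapply(fams, `[`, 1))
  seq20 <- make_validated(paste(rep(one_per, 3), collapse = ""))
  expect_equal(effective_number_of_codons(seq20), 20, tolerance = 1e-12)
  uniform <- codon_usage_table(setNames(rep(7L, 61), sense_codons()))
  expect_equal(effective_number_of_codons(uniform), 61, tolerance = 1e-12)
  # random sequences against the spelled-out class formula
  set.seed(29)
  for (i in 1:10) {
    cs <- rand_cds(200)
    tab <- codon_usage_table(cs)
    expect_equal(effective_number_of_codons(tab),
                 min(max(oracle_nc(tab$counts), 20), 61), tolerance = 1e-9)
  }
  # invariant to duplicating the sequence
  cs <- rand_cds(120)
  dup <- make_validated(paste0(cs$sequence, cs$sequence))
  expect_equal(effective_number_of_codons(cs),
               effective_number_of_codons(dup), tolerance = 1e-9)
})

test_that("Nc sample correction shifts the estimate but keeps the range", {
  set.seed(41)
  cs <- rand_cds(80)
  nc_f <- effective_number_of_codons(cs, sample_correction = FALSE)
  nc_c <- effective_number_of_codons(cs, sample_correction = TRUE)
  expect_true(nc_f >= 20 && nc_f <= 61)
  expect_true(nc_c >= 20 && nc_c <= 61)
})

test_that("CAI closed forms and order/monotonicity properties hold", {
  ref <- toy_two_codon(c(TTT = 8, TTC = 2))  # cond_freq 0.8 / 0.2
  q_second <- codon_usage_table(c(TTC = 10))
  expect_equal(cai(q_second, ref), 0.2 / 0.8, tolerance = 1e-12)
  q_first <- codon_usage_table(c(TTT = 10))
  expect_equal(cai(q_first, ref), 1, tolerance = 1e-12)
  # CAI of any query against itself-as-reference is <= 1
  set.seed(37)
  cs <- rand_cds(150)
  self_ref <- codon_usage_table(cs, source = "host_reference")
  expect_lte(cai(cs, self_ref), 1)
  # invariance to codon order: a shuffled sequence has identical CAI
  cods <- iter_codons(cs)
  shuf <- make_validated(paste(sample(cods), collapse = ""))
  expect_equal(cai(cs, self_ref), cai(shuf, self_ref), tolerance = 1e-12)
  # replacing one most-frequent codon by the rarest synonym lowers CAI
  host <- simulate_host_cds(setNames(rep(1, 61), sense_codons()),
                            n_genes = 20, mean_length = 200, seed = 99)
  ref2 <- build_reference_table(host)
  lys <- codon_families()[["K"]]
  best <- lys[which.max(ref2$cond_freq[lys])]
  worst <- lys[which.min(ref2$cond_freq[lys])]
  q_best <- codon_usage_table(setNames(c(10L), best))
  q_mix <- codon_usage_table(setNames(c(9L, 1L), c(best, worst)))
  expect_lt(cai(q_mix, ref2), cai(q_best, ref2))
})

test_that("RCDI closed forms, identity and deoptimization direction hold", {
  ref <- toy_two_codon(c(TTT = 5, TTC = 5))   # cond_freq 0.5 / 0.5
  q <- codon_usage_table(c(TTT = 10))          # cond_freq 1 / 0
  expect_equal(rcdi(q, ref), (1 / 10) * 10 * (1 / 0.5), tolerance = 1e-12)
  # query identical to reference -> exactly 1
  set.seed(43)
  host <- simulate_host_cds(setNames(rep(1, 61), sense_codons()),
                            n_genes = 15, mean_length = 150, seed = 43)
  ref2 <- build_reference_table(host)
  concat <- make_validated(paste(vapply(host, `[[`, "", "sequence"), collapse = ""))
  expect_equal(rcdi(concat, ref2), 1, tolerance = 1e-12)
})

test_that("AT-rich queries against a GC-preferring reference are deoptimized", {
  # RCDI > 1 and increasing as query GC3 falls, the sign structure expected
  # for AT-rich elements scored against host genes
  gc_weight <- function(cod) 3^(sum(strsplit(cod, "")[[1]] %in% c("G", "C")))
  prof <- vapply(sense_codons(), gc_weight, numeric(1))
  host <- simulate_host_cds(prof, n_genes = 40, mean_length = 200, seed = 7)
  ref <- build_reference_table(host)
  set.seed(7)
  at_levels <- c(0.35, 0.5, 0.65)
  res <- vapply(at_levels, function(at) {
    f <- c(A = at * 0.55, C = (1 - at) / 2, G = (1 - at) / 2, T = at * 0.45)
    q <- simulate_element_consensus(f, 400)
    c(rcdi = rcdi(codon_usage_table(q), ref),
      gc3 = unname(codon_position_gc(q)["gc3"]))
  }, numeric(2))
  expect_true(all(res["rcdi", at_levels > 0.4] > 1))
  # higher AT (lower GC3) -> larger RCDI
  ord <- order(res["gc3", ])
  expect_true(all(diff(res["rcdi", ord]) < 0))
})

test_that("eCAI is seeded-reproducible and tracks the analytic expectation", {
  host <- simulate_host_cds(setNames(rep(1, 61), sense_codons()),
                            n_genes = 25, mean_length = 150, seed = 3)
  ref <- build_reference_table(host)
  q <- simulate_element_consensus(c(A = .25, C = .25, G = .25, T = .25),
                                  300, seed = 9)
  e1 <- expected_cai(q, ref, n_random = 200, seed = 101)
  e2 <- expected_cai(q, ref, n_random = 200, seed = 101)
  expect_identical(e1, e2)
  e3 <- expected_cai(q, ref, n_random = 200, seed = 102)
  expect_false(identical(e1, e3))
  expect_true(e1 > 0 && e1 <= 1)
  # q95 summary dominates the mean
  expect_gte(expected_cai(q, ref, n_random = 200, seed = 101, summary = "q95"), e1)
  # Monte-Carlo mean approaches exp(E[log w]) under the codon-sampling law
  # (direct expectation over the 61 codons, long-sequence limit)
  comp <- base_composition(q)
  frac <- c(A = comp$frac_A, C = comp$frac_C, G = comp$frac_G, T = comp$frac_T)
  p <- vapply(sense_codons(), function(cd)
    prod(frac[strsplit(cd, "")[[1]]]), numeric(1))
  p <- p / sum(p)
  fams <- codon_families()
  w <- setNames(rep(NA_real_, 61), sense_codons())
  multi <- character(0)
  for (aa in names(fams)) {
    codons <- fams[[aa]]
    if (length(codons) < 2) next
    multi <- c(multi, codons)
    f <- ref$cond_freq[codons]
    w[codons] <- f / max(f)
  }
  elogw <- sum(p[multi] * log(w[multi])) / sum(p[multi])
  big <- expected_cai(q, ref, n_random = 400, seed = 55)
  expect_equal(big, exp(elogw), tolerance = 0.02)
})

test_that("eRCDI is reproducible, degenerate-safe and matches enumeration", {
  host <- simulate_host_cds(setNames(rep(1, 61), sense_codons()),
                            n_genes = 25, mean_length = 150, seed = 3)
  ref <- build_reference_table(host)
  # query using only single-synonym families has no randomness: eRCDI = RCDI
  mw_only <- make_validated(strrep("ATGTGG", 30))
  expect_equal(expected_rcdi(mw_only, ref, n_random = 100, seed = 1),
               rcdi(codon_usage_table(mw_only), ref), tolerance = 1e-12)
  q <- simulate_element_consensus(c(A = .3, C = .2, G = .2, T = .3), 250, seed = 21)
  e1 <- expected_rcdi(q, ref, n_random = 150, seed = 77)
  expect_identical(e1, expected_rcdi(q, ref, n_random = 150, seed = 77))
  expect_gt(e1, 0)
})

test_that("reference tables pool counts and scale-invariantly define frequencies", {
  g <- make_validated("ATGAAATTTTGA", id = "g1")
  tab1 <- build_reference_table(list(g))
  expect_equal(sum(tab1$counts), 3)  # ATG AAA TTT (stop trimmed)
  expect_equal(unname(tab1$counts["AAA"]), 1L)
  tab2 <- build_reference_table(list(g, g))
  expect_equal(tab2$counts, tab1$counts * 2L)
  expect_equal(tab2$cond_freq, tab1$cond_freq)
  expect_s3_class(attr(tab1, "gene_composition"), "data.frame")
  # generator round trip: pooled conditional frequencies recover the profile
  gc_weight <- function(cod) 2^(sum(strsplit(cod, "")[[1]] %in% c("G", "C")))
  prof_raw <- vapply(sense_codons(), gc_weight, numeric(1))
  prof <- unlist(lapply(codon_families(), function(cs) {
    p <- prof_raw[cs] / sum(prof_raw[cs]); setNames(p, cs)
  }))
  names(prof) <- sub("^.*\\.", "", names(prof))
  host <- simulate_host_cds(prof, n_genes = 50, mean_length = 300, seed = 31)
  ref <- build_reference_table(host)
  for (codons in codon_families()) {
    n_fam <- sum(ref$counts[codons])
    if (n_fam < 50 || length(codons) < 2) next
    for (cd in codons) {
      p0 <- prof[cd]
      se <- sqrt(p0 * (1 - p0) / n_fam)
      expect_lt(abs(ref$cond_freq[cd] - p0), 4 * se + 1e-9)
    }
  }
})
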