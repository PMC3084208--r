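test_that("synonymous changes partition by codon preference", {
  pref <- preferred_codon_table()
  # both preferred (not possible one-step for most AAs, but definitionally):
  # both unpreferred Leu codons
  expect_equal(classify_synonymous("CTA", "CTC", pref), "syn_no_change")
  # preferred -> unpreferred and back
  expect_equal(classify_synonymous("CTG", "CTA", pref), "syn_pref_to_unpref")
  expect_equal(classify_synonymous("CTA", "CTG", pref), "syn_unpref_to_pref")
  # nonsynonymous pairs are an error routed by the caller
  expect_error(classify_synonymous("ATG", "ACG", pref), "nonsynonymous")
  expect_error(classify_synonymous("AAA", "AAA", pref), "identical")

  # full sweep: every one-step synonymous codon pair gets exactly one class
  B <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(B, B, B), 1, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  n_pairs <- 0L
  for (c1 in codons) for (pos in 1:3) for (b in setdiff(B,
                                             substr(c1, pos, pos))) {
    c2 <- c1; substr(c2, pos, pos) <- b
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    if (gc[[c1]] != gc[[c2]]) next
    cls <- classify_synonymous(c1, c2, pref)
    expect_true(cls %in% c("syn_no_change", "syn_pref_to_unpref",
                           "syn_unpref_to_pref"))
    n_pairs <- n_pairs + 1L
  }
  expect_gt(n_pairs, 100L)
})

test_that("MK tables apply the common-polymorphism cutoff", {
  v <- data.frame(
    class = c("affinity_increasing", "affinity_increasing",
              "affinity_increasing", "syn_no_change"),
    kind = c("fixed", "segregating", "segregating", "segregating"),
    derived_count = c(162L, 10L, 30L, 40L),
    sample_size = c(162L, 150L, 150L, 150L))
  t <- build_mk_table(v)
  inc <- t[t$class == "affinity_increasing", ]
  # 10/150 = 0.067 excluded; 30/150 = 0.20 counted
  expect_equal(inc$fixed, 1L)
  expect_equal(inc$poly, 1L)
  ref <- t[t$class == "syn_no_change", ]
  expect_equal(ref$fixed, 0L)
  expect_true(ref$r_undefined == FALSE)
  # boundary: exactly 0.15 is common
  v2 <- data.frame(class = "spacer", kind = "segregating",
                   derived_count = 15L, sample_size = 100L)
  t_b <- build_mk_table(v2)
  expect_equal(t_b$poly[t_b$class == "spacer"], 1L)
  # empty classes are kept as zero rows
  t3 <- build_mk_table(v[0, ], classes = c("spacer", "syn_no_change"))
  expect_equal(t3$fixed, c(0L, 0L))
  expect_true(all(t3$r_undefined))
})

test_that("mk_test is a two-sided Fisher exact test with stable symmetry", {
  v <- data.frame(class = c("a", "a", "b", "b"),
                  kind = c("fixed", "segregating", "fixed", "segregating"),
                  derived_count = c(10L, 50L, 10L, 50L),
                  sample_size = c(10L, 100L, 10L, 100L))
  # identical rows give p = 1 (counts are per-class aggregates)
  t <- build_mk_table(v, reference_class = "b")
  expect_equal(mk_test(t, "a")$p.value, 1)

  # (20,2) vs (10,40): equals the frozen exact hypergeometric enumeration
  t2 <- build_mk_table(data.frame(
    class = c(rep("a", 22), rep("b", 50)),
    kind = c(rep("fixed", 20), rep("segregating", 2),
             rep("fixed", 10), rep("segregating", 40)),
    derived_count = 50L, sample_size = 100L), reference_class = "b")
  res <- mk_test(t2, "a")
  expect_equal(res$table["test", ], c(fixed = 20L, poly = 2L))
  expect_equal(res$p.value, 1.47805276253e-08, tolerance = 1e-9)
  # row swap leaves the two-sided p unchanged
  t2s <- t2; t2s$class <- rev(t2s$class)
  expect_equal(mk_test(t2s, "a")$p.value, res$p.value)

  # zero margin warns and returns 1
  t0 <- build_mk_table(data.frame(class = character(), kind = character(),
                                  derived_count = integer(),
                                  sample_size = integer()),
                       classes = c("a", "b"), reference_class = "b")
  expect_warning(p0 <- mk_test(t0, "a")$p.value, "degenerate")
  expect_equal(p0, 1)
})

test_that("stratified MK tables sum exactly to the pooled table", {
  set.seed(3)
  v <- data.frame(
    class = sample(c("affinity_increasing", "affinity_decreasing",
                     "spacer"), 200, TRUE),
    kind = sample(c("fixed", "segregating"), 200, TRUE),
    derived_count = sample(1:150, 200, TRUE),
    sample_size = 150L,
    anc_score = runif(200, -2, 8))
  pooled <- build_mk_table(v, classes = sort(unique(v$class)))
  bins <- mk_table_by_ancestral_strength(v, breaks = c(-Inf, 0, 2, 4, Inf),
                                         classes = sort(unique(v$class)))
  summed <- Reduce(function(a, b) {
    a$fixed <- a$fixed + b$fixed; a$poly <- a$poly + b$poly; a
  }, bins$tables)
  expect_equal(summed$fixed, pooled$fixed)
  expect_equal(summed$poly, pooled$poly)
  # a single all-encompassing bin is the pooled table
  one <- mk_table_by_ancestral_strength(v, breaks = c(-Inf, Inf),
                                        classes = sort(unique(v$class)))
  expect_equal(one$tables[[1]]$fixed, pooled$fixed)
  expect_equal(one$tables[[1]]$poly, pooled$poly)
})

test_that("mutational input test reproduces its defining arithmetic", {
  # observed (12, 33) with input probabilities (0.105, 0.895):
  # expectations 4.7 and 40.3 at one decimal, small simulated p
  res <- mutational_input_test(c(12, 33), c(0.105, 0.895), reps = 10000,
                               seed = 5)
  expect_equal(round(res$expected, 1), c(4.7, 40.3))
  expect_lt(res$p.value, 0.05)
  manual_chi <- (12 - 4.725)^2 / 4.725 + (33 - 40.275)^2 / 40.275
  expect_equal(res$chisq, manual_chi)

  # observed equal to expected: chi-square 0, p ~ 1
  res0 <- mutational_input_test(c(10, 90), c(0.1, 0.9), reps = 2000,
                                seed = 6)
  expect_equal(res0$chisq, 0)
  expect_gt(res0$p.value, 0.99)

  # Monte-Carlo consistency: reps = 1e4 vs 1e5 agree within 3 MC SEs
  r1 <- mutational_input_test(c(12, 33), c(0.105, 0.895), reps = 10000,
                              seed = 11)
  r2 <- mutational_input_test(c(12, 33), c(0.105, 0.895), reps = 100000,
                              seed = 12)
  se <- sqrt(r2$p.value * (1 - r2$p.value) / 10000)
  expect_lt(abs(r1$p.value - r2$p.value), 3 * se + 1e-4)

  # degenerate null: all mass in one class
  null <- simulate_table1_null(50, c(1, 0), reps = 100, seed = 1)
  expect_true(all(null == 0))
})
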