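test_that("simulated PWMs are deterministic and concentration-controlled", {
  a <- simulate_pwm(8, 0.3, seed = 2)
  b <- simulate_pwm(8, 0.3, seed = 2)
  expect_identical(a$probs, b$probs)
  # enormous concentration: columns near uniform, consensus score near 0
  flat <- simulate_pwm(8, 1e5, seed = 3)
  expect_lt(max(abs(flat$probs - 0.25)), 0.02)
  expect_lt(abs(score_sequence(flat, pwm_consensus(flat))), 0.5)
  # informative motifs score their consensus positively (property over seeds)
  ok <- vapply(1:100, function(s) {
    p <- simulate_pwm(8, 0.1, seed = s)
    score_sequence(p, pwm_consensus(p)) > 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("PRF machinery reduces to neutral theory at gamma = 0", {
  n <- 30
  expect_equal(prf_sfs_weights(n, 0), 1 / (seq_len(n - 1) / n))
  # continuity near zero
  expect_equal(prf_sfs_weights(n, 1e-9), prf_sfs_weights(n, 0),
               tolerance = 1e-6)
  expect_equal(fixation_weight(0), 1)
  expect_equal(fixation_weight(1e-10), 1)
  # positive selection raises, negative lowers, the fixation weight
  expect_gt(fixation_weight(2), 1)
  expect_lt(fixation_weight(-2), 1)
  # selected spectra shift mass as expected: positive gamma flattens
  w_pos <- prf_sfs_weights(n, 5); w_neu <- prf_sfs_weights(n, 0)
  p_pos <- w_pos / sum(w_pos); p_neu <- w_neu / sum(w_neu)
  i <- seq_len(n - 1)
  expect_gt(sum(i * p_pos), sum(i * p_neu))
})

test_that("datasets are reproducible and structurally complete", {
  cfg <- sim_config(seed = 19, n_crm = 3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$crms[[1]]$species_seqs, d2$crms[[1]]$species_seqs)
  expect_identical(d1$truth, d2$truth)
  expect_equal(length(d1$crms), 3L)
  expect_equal(nrow(d1$footprints), 12L)
  expect_equal(length(d1$crms[[1]]$mel_haplotypes), 162L)
  expect_equal(length(d1$crms[[1]]$sim_haplotypes), 6L)
  # every truth row is traceable and well-formed
  expect_true(all(d1$truth$lineage %in% c("mel", "sim")))
  expect_true(all(d1$truth$kind %in% c("fixed", "segregating")))
  seg <- d1$truth[d1$truth$kind == "segregating", ]
  expect_true(all(seg$derived_count >= 1 &
                    seg$derived_count < seg$sample_size))
})

test_that("pre-filter segregating frequencies match the configured
           spectrum", {
  # neutral config: mel derived counts should follow the 1/i spectrum
  d <- simulate_dataset(sim_config(seed = 23, n_crm = 30, theta = 0.04,
                                   branch_scale = 0.005))
  seg <- d$truth[d$truth$kind == "segregating" & d$truth$lineage == "mel", ]
  expect_gt(nrow(seg), 300)
  n <- 162
  obs <- tabulate(seg$derived_count, nbins = n - 1)
  p <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  # pool into coarse bins to keep expected counts reasonable
  bins <- list(1, 2, 3:5, 6:10, 11:30, 31:161)
  ob <- vapply(bins, function(b) sum(obs[b]), numeric(1))
  pb <- vapply(bins, function(b) sum(p[b]), numeric(1))
  gof <- suppressWarnings(stats::chisq.test(ob, p = pb))
  expect_gt(gof$p.value, 1e-4)
})

test_that("the dataset ascertainment filter reproduces the analytic
           expectations", {
  # f_true = 1, neutral: every footprint whose assayed allele is weak is
  # dropped, so surviving decreasing-class mel variants in detected
  # footprints are biased against high frequencies
  cfg <- sim_config(seed = 31, n_crm = 40, theta = 0.03, f_true = 1,
                    branch_scale = 0.005)
  d <- simulate_dataset(cfg)
  tr <- d$truth
  core <- tr[tr$site_id != "spacer" & tr$lineage == "mel" &
               tr$kind == "segregating" & tr$class == "decreasing", ]
  expect_gt(nrow(core), 30)
  # survival frequency among detected footprints falls with derived count:
  # mean derived frequency of surviving sites < mean of all sites
  expect_lt(mean(core$derived_count[core$detected]),
            mean(core$derived_count))
})

test_that("written datasets read back and rerun identically", {
  d <- simulate_dataset(sim_config(seed = 37, n_crm = 2))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_setequal(names(back$crms), names(d$crms))
  expect_identical(back$crms[["crm001"]]$species_seqs[["mel"]],
                   d$crms[["crm001"]]$species_seqs[["mel"]])
  expect_equal(back$mutation_matrix, d$mutation_matrix)
  # PWM probabilities round trip through the text format
  expect_equal(back$pwms[["TF1"]]$probs, d$pwms[["TF1"]]$probs,
               tolerance = 1e-5)
  # footprint coordinates survive the BED round trip
  det <- d$footprints[d$footprints$detected, ]
  expect_equal(back$footprints$start, det$start)
  expect_equal(back$footprints$end, det$end)
  r1 <- suppressWarnings(run_pipeline(d, mk_reps = 200, seed = 2))
  r2 <- suppressWarnings(run_pipeline(back, mk_reps = 200, seed = 2))
  expect_equal(r1$turnover_rates, r2$turnover_rates)
  expect_equal(r1$mk$mel$fixed, r2$mk$mel$fixed)
})
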