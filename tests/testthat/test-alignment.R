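test_that("FASTA round trip reproduces a CRM alignment byte-identically", {
  crm <- make_crm(random_seq(30, 1), n_mel = 4, n_sim = 3)
  crm$mel_haplotypes[2] <- mutate_at(crm$mel_haplotypes[2], 7, "N")
  crm$sim_haplotypes[1] <- mutate_at(crm$sim_haplotypes[1], 9, "N")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_crm_alignment(crm, f)
  back <- read_crm_alignment(f, crm_id = crm$crm_id)
  expect_identical(back$species_seqs[sort(names(back$species_seqs))],
                   crm$species_seqs[sort(names(crm$species_seqs))])
  expect_identical(back$mel_haplotypes, crm$mel_haplotypes)
  expect_identical(back$sim_haplotypes, crm$sim_haplotypes)
  # second round trip is exactly stable
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_crm_alignment(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("alignment invariants are enforced at construction", {
  expect_error(crm_alignment("x", c(mel = "ACGT", sim = "ACG")), "length")
  expect_error(crm_alignment("x", c(sim = "ACGT")), "mel")
  expect_warning(crm_alignment("x", c(mel = "ACGT", sim = "ACGT")),
                 "missing species")
})

test_that("MAF blocks stitch to the equivalent hand-built FASTA", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "##maf version=1",
    "a score=1.0",
    "s mel.chr2L 0 4 + 100 ACGT",
    "s sim.chr2L 0 4 + 100 ACGA",
    "s yak.chr2L 0 4 + 100 ACGG",
    "",
    "a score=2.0",
    "s mel.chr2L 4 4 + 100 TTAA",
    "s sim.chr2L 4 4 + 100 TTAC",
    "s sec.chr2L 0 4 + 100 TTAA"), maf)
  crm <- suppressWarnings(read_maf_alignment(maf, crm_id = "m1"))
  # hand stitch: block1 + block2, absent species padded with N
  expect_identical(crm$species_seqs[["mel"]], "ACGTTTAA")
  expect_identical(crm$species_seqs[["sim"]], "ACGATTAC")
  expect_identical(crm$species_seqs[["yak"]], "ACGGNNNN")
  expect_identical(crm$species_seqs[["sec"]], "NNNNTTAA")
})

test_that("footprint tables convert BED coordinates and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# crm tf start end id",
               "crm1\tTF1\t10\t18\ts1",
               "crm1\tTF2\t0\t8\ts2"), f)
  fp <- read_footprints(f)
  expect_equal(fp$start, c(11L, 1L))
  expect_equal(fp$end, c(18L, 8L))
})

test_that("extract_tfbs recovers a planted core and applies the filters", {
  p <- random_pwm(8, seed = 9, concentration = 0.2)
  cons <- pwm_consensus(p)
  seq <- paste0(random_seq(12, 21), cons, random_seq(12, 22))
  crm <- make_crm(seq, n_mel = 6, n_sim = 4)
  fp <- data.frame(crm_id = "crmT", tf_name = "rTF", start = 13L,
                   end = 20L, site_id = "s1", stringsAsFactors = FALSE)
  t <- extract_tfbs(crm, fp, p)
  expect_true(t$pass_filters)
  expect_equal(t$core_start, 13L)
  expect_identical(t$species_cores[["mel"]], cons)
  expect_equal(length(t$mel_hap_cores), 6L)

  # a gap inside the sim core fails the indel filter
  crm_gap <- crm
  crm_gap$species_seqs[["sim"]] <- mutate_at(seq, 16, "-")
  t2 <- extract_tfbs(crm_gap, fp, p)
  expect_false(t2$pass_filters)
  expect_equal(t2$fail_reason, "indel")

  # a gap in a mel haplotype also fails (polymorphic indel)
  crm_hgap <- crm
  crm_hgap$mel_haplotypes[3] <- mutate_at(seq, 15, "-")
  t3 <- extract_tfbs(crm_hgap, fp, p)
  expect_false(t3$pass_filters)
  expect_equal(t3$fail_reason, "indel")

  # filter monotonicity: gaps can only flip pass -> fail, never fail -> pass
  expect_true(t$pass_filters && !t2$pass_filters && !t3$pass_filters)

  # footprint at the CRM boundary fails with reason "edge"
  fp_edge <- data.frame(crm_id = "crmT", tf_name = "rTF", start = 30L,
                        end = 40L, site_id = "s2", stringsAsFactors = FALSE)
  expect_equal(extract_tfbs(crm, fp_edge, p)$fail_reason, "edge")
})

test_that("call_variants recovers planted SNPs and applies sim filters", {
  base <- strrep("A", 10)
  mel_haps <- rep(base, 8)
  # plant: column 3 segregating in mel (2 of 8 carry G)
  mel_haps[1] <- mutate_at(mel_haps[1], 3, "G")
  mel_haps[2] <- mutate_at(mel_haps[2], 3, "G")
  # column 5: fixed difference (all sim T)
  sim_haps <- rep(mutate_at(base, 5, "T"), 6)
  # column 7: sim variant with only one non-missing allele
  sim_haps <- vapply(sim_haps, mutate_at, character(1), 7, "N",
                     USE.NAMES = FALSE)
  sim_haps[1] <- mutate_at(sim_haps[1], 7, "C")
  # column 9: tri-allelic
  mel_haps[3] <- mutate_at(mel_haps[3], 9, "C")
  mel_haps[4] <- mutate_at(mel_haps[4], 9, "G")
  sp <- c(mel = base, sim = mutate_at(base, 5, "T"), sec = base,
          yak = base, ere = base)
  v <- call_variants(mel_haps, sim_haps, sp, site_id = "t")
  v_ok <- v[v$flag == "ok", ]
  expect_setequal(v_ok$column, c(3, 5))
  expect_equal(v_ok$mel_G[v_ok$column == 3], 2L)
  expect_equal(v_ok$mel_n[v_ok$column == 3], 8L)
  expect_equal(v_ok$sim_T[v_ok$column == 5], 6L)
  expect_equal(v$flag[v$column == 7], "sim_low_coverage")
  expect_equal(v$flag[v$column == 9], "triallelic")
  # every variant maps back to exactly one column
  expect_false(any(duplicated(v$column)))
})

test_that("identical cores yield no variant sites and spacers partition", {
  seq <- random_seq(40, 31)
  crm <- make_crm(seq, n_mel = 5, n_sim = 4)
  p <- random_pwm(6, 32)
  fp <- data.frame(crm_id = "crmT", tf_name = "rTF", start = 10L, end = 15L,
                   site_id = "s1", stringsAsFactors = FALSE)
  t <- extract_tfbs(crm, fp, p)
  expect_true(t$pass_filters)
  expect_equal(nrow(tfbs_variants(t)), 0L)
  sp_cols <- spacer_columns(crm, list(t))
  expect_equal(sort(c(sp_cols, t$core_columns)), 1:40)
})
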