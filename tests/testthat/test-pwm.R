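test_that("PWM construction and file reading normalize counts correctly", {
  # normalization identities
  p <- pwm(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(p$probs[, 1]), c(1, 0, 0, 0))
  p <- pwm(matrix(c(1, 1, 1, 1), 4, 1), pseudocount = 0)
  expect_equal(unname(p$probs[, 1]), rep(0.25, 4))

  # pseudocount arithmetic on a 4x2 count matrix: (count + 0.5)/(colsum + 2)
  counts <- matrix(c(3, 1, 0, 2, 5, 0, 0, 1), 4, 2)
  p <- pwm(counts, pseudocount = 0.5)
  expect_equal(p$probs, sweep(counts + 0.5, 2, colSums(counts) + 2, "/"),
               ignore_attr = TRUE)

  # JASPAR-style 4-row file with base labels and brackets
  f <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c(">toyTF", "A [ 3 5 ]", "C [ 1 0 ]", "G [ 0 0 ]",
               "T [ 2 1 ]"), f)
  p <- read_pwm(f, pseudocount = 0.5)
  expect_equal(p$tf_name, "toyTF")
  expect_equal(unname(p$probs[, 1]), (c(3, 1, 0, 2) + 0.5) / 8)

  # patser-style column matrix (L rows x 4 columns, header of base labels)
  f2 <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c("A C G T", "3 1 0 2", "5 0 0 1", "1 1 1 1"), f2)
  p2 <- read_pwm(f2, pseudocount = 0.5)
  expect_equal(ncol(p2$probs), 3L)
  expect_equal(unname(p2$probs[, 1]), (c(3, 1, 0, 2) + 0.5) / 8)

  # malformed input names the offending line
  f3 <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c("1 2 3 4", "1 2 x 4"), f3)
  expect_error(read_pwm(f3), "line 2")
  f4 <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c("1 2", "1 2", "1 2"), f4)
  expect_error(read_pwm(f4), "malformed")
})

test_that("PWM invariants hold after construction", {
  for (seed in 1:5) {
    p <- random_pwm(6, seed)
    expect_equal(colSums(p$probs), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(p$probs > 0))
    expect_equal(sum(p$background), 1, tolerance = 1e-9)
  }
})

test_that("score_sequence matches closed forms and per-position sums", {
  # near-degenerate columns: score of consensus ~ L * log2(4)
  p <- pwm(matrix(c(1, 0, 0, 0), 4, 4), pseudocount = 1e-9)
  expect_equal(score_sequence(p, "AAAA"), 4 * log2(4), tolerance = 1e-6)

  # probs equal to background give score 0 for any sequence
  p0 <- pwm(matrix(0.25, 4, 5), pseudocount = 0)
  expect_equal(score_sequence(p0, "ACGTA"), 0)

  # random PWM: equals independent per-position log-ratio sum
  p <- random_pwm(6, seed = 42)
  s <- "ACGTTG"
  ch <- strsplit(s, "")[[1]]
  manual <- sum(sapply(1:6, function(k) {
    b <- match(ch[k], c("A", "C", "G", "T"))
    log2(p$probs[b, k] / p$background[b])
  }))
  expect_equal(score_sequence(p, s), manual)

  # additivity over a split motif
  pL <- pwm(p$probs[, 1:3], pseudocount = 0)
  pR <- pwm(p$probs[, 4:6], pseudocount = 0)
  expect_equal(score_sequence(p, s),
               score_sequence(pL, "ACG") + score_sequence(pR, "TTG"))

  # ambiguity codes are a distinct, catchable error
  expect_error(score_sequence(p, "ACGTNN"),
               class = "tfbs_ambiguous_sequence")
  expect_error(score_sequence(p, "ACG"), "length")
})

test_that("best_match agrees with an exhaustive two-strand scan", {
  for (seed in c(3, 11, 27)) {
    p <- random_pwm(7, seed)
    region <- random_seq(40, seed + 100)
    got <- best_match(p, region)
    want <- scan_oracle(p, region)
    expect_equal(got$score, want$score)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("best_match finds planted consensus sites on both strands", {
  p <- random_pwm(8, seed = 5, concentration = 0.2)
  cons <- pwm_consensus(p)
  set.seed(99)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                            collapse = "")
  region_f <- paste0(flank(), cons, flank())
  bf <- best_match(p, region_f)
  expect_equal(bf$offset, 6L)
  expect_equal(bf$sequence, cons)

  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
  region_r <- paste0(flank(), rc, flank())
  br <- best_match(p, region_r)
  expect_equal(br$strand, "-")
  expect_equal(br$sequence, cons)
  expect_equal(br$score, bf$score)

  # palindromic motif scores both strands equally: plus strand wins the tie
  pal <- pwm(matrix(0.25, 4, 4), pseudocount = 0)
  tie <- best_match(pal, "ACGT")
  expect_equal(tie$strand, "+")
  expect_equal(tie$offset, 1L)
  expect_error(best_match(p, "ACG"), "shorter")
})

test_that("delta_score has the stated closed form and consistency", {
  # column p(A)=0.5, p(C)=0.25, uniform background: A->C is -1 bit
  p <- pwm(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1), pseudocount = 0)
  expect_equal(delta_score(p, 1, "A", "C"), -1)
  expect_equal(delta_score(p, 1, "G", "G"), 0)

  # antisymmetry and site-level consistency on random PWMs
  for (seed in 1:4) {
    p <- random_pwm(5, seed + 200)
    s <- random_seq(5, seed + 300)
    for (k in 1:5) {
      from <- substr(s, k, k)
      for (to in setdiff(c("A", "C", "G", "T"), from)) {
        d <- delta_score(p, k, from, to)
        expect_equal(delta_score(p, k, to, from), -d)
        s2 <- mutate_at(s, k, to)
        expect_equal(score_sequence(p, s2) - score_sequence(p, s), d)
      }
    }
  }
  expect_error(delta_score(random_pwm(4, 1), 9, "A", "C"), "outside")
})

test_that("classify_mutation applies the one-bit threshold with a closed
           boundary", {
  expect_equal(classify_mutation(1.5), "increasing")
  expect_equal(classify_mutation(-0.5), "uncertain")
  expect_equal(classify_mutation(c(1, -1)), c("increasing", "decreasing"))
  expect_equal(classify_mutation(0.999), "uncertain")
  # tau = 0: every nonzero delta is classified
  d <- c(-2, -1e-9, 1e-9, 3)
  expect_false(any(classify_mutation(d, tau = 0) == "uncertain"))
  expect_error(classify_mutation(1, tau = -1), "non-negative")
})

test_that("mutational_probabilities match exhaustive enumeration", {
  # 1-bp site, uniform rates, tau = 0: one increasing vs two decreasing
  p1 <- pwm(matrix(c(0.5, 0.3, 0.15, 0.05), 4, 1), pseudocount = 0)
  # ancestral C: C->A increases, C->G and C->T decrease
  out <- mutational_probabilities(list(x = p1),
                                  data.frame(tf = "x", sequence = "C"),
                                  tau = 0)
  expect_equal(as.numeric(out), c(1 / 3, 2 / 3, 0))

  # enormous tau: everything uncertain
  out <- mutational_probabilities(list(x = p1),
                                  data.frame(tf = "x", sequence = "C"),
                                  tau = 1e6)
  expect_equal(as.numeric(out), c(0, 0, 1))

  # 20 random sites vs an independent brute-force enumeration, exact match
  set.seed(77)
  pwms <- list(a = random_pwm(6, 501), b = random_pwm(9, 502))
  sites <- data.frame(
    tf = sample(c("a", "b"), 20, TRUE), stringsAsFactors = FALSE)
  sites$sequence <- vapply(sites$tf, function(tf)
    random_seq(ncol(pwms[[tf]]$probs), sample.int(1e6, 1)), character(1))
  m <- matrix(runif(16, 0.2, 2), 4, 4,
              dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(m) <- 0
  got <- mutational_probabilities(pwms, sites, m = m, tau = 1)
  # oracle: loop over every site, position, and target base
  B <- c("A", "C", "G", "T")
  acc <- c(increase = 0, decrease = 0, uncertain = 0); npos <- 0
  for (s in seq_len(nrow(sites))) {
    p <- pwms[[sites$tf[s]]]
    ch <- strsplit(sites$sequence[s], "")[[1]]
    for (k in seq_along(ch)) {
      b <- ch[k]
      w <- c(); cls <- c()
      for (to in setdiff(B, b)) {
        d <- log2(p$probs[match(to, B), k] / p$background[match(to, B)]) -
          log2(p$probs[match(b, B), k] / p$background[match(b, B)])
        w <- c(w, m[b, to])
        cls <- c(cls, if (d >= 1) "increase" else if (d <= -1) "decrease"
                      else "uncertain")
      }
      for (nm in names(acc)) acc[nm] <- acc[nm] + sum(w[cls == nm]) / sum(w)
      npos <- npos + 1
    }
  }
  expect_equal(as.numeric(got), as.numeric(acc / npos))
  expect_equal(sum(got), 1, tolerance = 1e-9)
  expect_equal(attr(got, "n_positions"), npos)
})
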