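#' Site frequency spectrum container
#'
#' Counts of segregating sites by derived-allele count in a sample of
#' fixed size `n` (classes 1..n-1).  Counts may be fractional when built
#' by expectation-mode projection.
#'
#' @param counts numeric vector of length `n - 1` (class i = derived
#'   count i).
#' @param n projected sample size.
#' @param class_label optional functional class label.
#' @return object of class `sfs`.
#' @export
sfs <- function(counts, n, class_label = NA_character_) {
  stopifnot(n >= 2, length(counts) == n - 1L, all(counts >= 0))
  structure(list(n = as.integer(n), counts = as.numeric(counts),
                 class_label = class_label), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("SFS (n =", x$n, if (!is.na(x$class_label))
        paste0(", class ", x$class_label) else "", "): ",
      format(sum(x$counts), digits = 4), "segregating sites\n")
  invisible(x)
}

#' Project one variable site to a smaller sample size
#'
#' Downsamples a site with derived count `d` out of `c` covered alleles to
#' a target sample size `t`.  Mode "expect" returns the deterministic
#' hypergeometric distribution over projected derived counts 0..t (summing
#' to 1); mode "sample" returns a single hypergeometric draw, emulating
#' choosing `t` alleles at random.
#'
#' @param d derived count, strictly between 0 and `c`.
#' @param c covered (non-missing) allele count, at least `t`.
#' @param t target sample size (default 150).
#' @param mode "expect" or "sample".
#' @return mode "expect": numeric vector of length `t + 1` over projected
#'   counts 0..t; mode "sample": a single integer draw.
#' @export
project_site <- function(d, c, t = 150L, mode = c("expect", "sample")) {
  mode <- match.arg(mode)
  if (d <= 0 || d >= c) stop("d must be strictly between 0 and c")
  if (c < t) stop("coverage ", c, " below target ", t,
                  "; drop the site instead")
  if (mode == "expect") {
    stats::dhyper(0:t, m = d, n = c - d, k = t)
  } else {
    stats::rhyper(1, m = d, n = c - d, k = t)
  }
}

#' Build a projected site frequency spectrum from variants
#'
#' Accumulates segregating variants into an SFS at a common sample size,
#' projecting sites with coverage above the target down with
#' [project_site()] and dropping (and counting) sites with coverage below
#' it.  In expectation mode, projected mass falling on the monomorphic
#' classes (0 and t) is recorded but not part of the spectrum.
#'
#' @param derived_counts,sample_sizes integer vectors (one entry per
#'   segregating site).
#' @param target projected sample size (default 150).
#' @param mode "expect" (deterministic fractional counts) or "sample".
#' @param class_label carried into the result.
#' @return an `sfs` with attributes `n_dropped_low_coverage` and
#'   `lost_monomorphic_mass`.
#' @export
build_sfs <- function(derived_counts, sample_sizes, target = 150L,
                      mode = c("expect", "sample"),
                      class_label = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(derived_counts) == length(sample_sizes))
  counts <- numeric(target - 1L)
  dropped <- 0L; lost <- 0
  for (j in seq_along(derived_counts)) {
    d <- derived_counts[j]; cv <- sample_sizes[j]
    if (cv < target) { dropped <- dropped + 1L; next }
    if (d <= 0 || d >= cv) next               # not segregating
    if (mode == "expect") {
      pm <- project_site(d, cv, target, "expect")
      counts <- counts + pm[2:target]          # classes 1..t-1
      lost <- lost + pm[1] + pm[target + 1L]
    } else {
      x <- project_site(d, cv, target, "sample")
      if (x >= 1 && x <= target - 1L) counts[x] <- counts[x] + 1
      else lost <- lost + 1
    }
  }
  out <- sfs(counts, target, class_label)
  attr(out, "n_dropped_low_coverage") <- dropped
  attr(out, "lost_monomorphic_mass") <- lost
  out
}

#' Tajima's D from a site frequency spectrum
#'
#' The normalized difference between mean pairwise diversity and
#' Watterson's estimator, computed from the unfolded spectrum with the
#' standard variance constants.  Negative values indicate an excess of
#' rare variants (purifying selection, growth, or a sweep).
#'
#' @param x an `sfs` (fractional counts allowed; the total segregating
#'   count S is the sum of the spectrum).
#' @return Tajima's D (scalar); error when the spectrum is empty.
#' @export
tajimas_d <- function(x) {
  stopifnot(inherits(x, "sfs"))
  n <- x$n
  S <- sum(x$counts)
  if (S <= 0) stop("Tajima's D undefined for an empty spectrum")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_hat <- sum(x$counts * i * (n - i)) / choose(n, 2)
  theta_w <- S / a1
  (pi_hat - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Compare an observed spectrum with an expected one
#'
#' Pools frequency classes and tests the observed class counts against the
#' expected probabilities: a two-sided exact binomial test when pooling
#' yields two bins (e.g. low-frequency classes versus the rest), a
#' chi-square test with a simulated null when more, and p = 1 for a single
#' bin.
#'
#' @param x an `sfs` (counts are rounded to integers for testing).
#' @param expected probability vector over classes 1..n-1 (sums to 1).
#' @param pooling list of integer vectors of derived-count classes, one
#'   per bin (default: singletons versus the rest).
#' @param chisq_reps replicates for the simulated chi-square null.
#' @return list with `observed` (per-bin counts), `expected`
#'   (probabilities), `p.value`, `method`.
#' @export
compare_sfs <- function(x, expected, pooling = NULL, chisq_reps = 10000L) {
  stopifnot(inherits(x, "sfs"))
  if (abs(sum(expected) - 1) > 1e-6) stop("expected must sum to 1")
  if (length(expected) != x$n - 1L)
    stop("expected has wrong length for n = ", x$n)
  if (sum(x$counts) <= 0) stop("empty observed spectrum")
  if (is.null(pooling))
    pooling <- list(low = 1L, rest = 2:(x$n - 1L))
  obs <- vapply(pooling, function(idx) sum(x$counts[idx]), numeric(1))
  exp_p <- vapply(pooling, function(idx) sum(expected[idx]), numeric(1))
  obs_i <- round(obs)
  if (length(pooling) == 1L)
    return(list(observed = obs_i, expected = exp_p, p.value = 1,
                method = "degenerate single bin"))
  if (length(pooling) == 2L) {
    ht <- stats::binom.test(obs_i[1L], sum(obs_i), p = exp_p[1L],
                            alternative = "two.sided")
    return(list(observed = obs_i, expected = exp_p, p.value = ht$p.value,
                method = "exact binomial"))
  }
  ht <- stats::chisq.test(obs_i, p = exp_p, simulate.p.value = TRUE,
                          B = chisq_reps)
  list(observed = obs_i, expected = exp_p, p.value = ht$p.value,
       method = "chi-square, simulated null")
}
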