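#' Footprint detection probability under single-allele ascertainment
#'
#' Footprints were discovered in a single reference (mel) assay, modelled
#' as sampling one haplotype uniformly at random; the weaker-affinity
#' allele of a mutation escapes detection with probability `f`.  For a
#' derived count `i` out of `n`:
#' affinity-decreasing mutations (derived allele is the weak one) are
#' detected with probability `1 - f * i/n`; affinity-increasing mutations
#' (ancestral allele is the weak one) with probability `1 - f * (n-i)/n`.
#' Substitutions are the `i = n` case: `1 - f` for decreasing, 1 for
#' increasing.
#'
#' @param i derived-allele count(s), 0..n (vectorized).
#' @param n haplotype sample size (>= 2).
#' @param f probability in `[0, 1]` that the weak allele is undetectable.
#' @param direction "decreasing" or "increasing".
#' @return detection probability in `[0, 1]`.
#' @export
detection_prob <- function(i, n, f, direction = c("decreasing",
                                                  "increasing")) {
  direction <- match.arg(direction)
  stopifnot(n >= 2, f >= 0, f <= 1, all(i >= 0), all(i <= n))
  weak_freq <- if (direction == "decreasing") i / n else (n - i) / n
  1 - f * weak_freq
}

#' Neutral site-frequency spectrum under ascertainment
#'
#' The expected neutral spectrum over derived counts `1..n-1`, weighting
#' the standard neutral spectrum (proportional to 1/i) by the detection
#' probability of each frequency class and renormalizing to sum to 1.
#' With `f = 0` this recovers the standard 1/i spectrum exactly.
#'
#' @inheritParams detection_prob
#' @return numeric vector of length `n - 1` summing to 1.
#' @export
expected_sfs <- function(n, f, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  i <- seq_len(n - 1L)
  w <- (1 / i) * detection_prob(i, n, f, direction)
  tot <- sum(w)
  if (tot <= 0) stop("all frequency classes undetectable")
  w / tot
}

#' Expected neutral fixed-to-common-polymorphism ratio under ascertainment
#'
#' The neutral expectation of the MK ratio r (fixed over common
#' polymorphic counts) as a function of the ascertainment parameter `f`,
#' anchored at an observed neutral-class ratio at `f = 0` (calibrated from
#' the synonymous no-change class).  Fixed differences are weighted by the
#' detection probability at `i = n`; common polymorphisms by the summed
#' 1/i-weighted detection probabilities over classes at or above the
#' frequency cutoff:
#' `reference_r * (w_fix(f)/w_fix(0)) / (w_poly(f)/w_poly(0))`.
#' Decreasing direction: the ratio falls with f (substitutions are lost
#' faster than common polymorphism); increasing: it rises.
#'
#' @param f ascertainment parameter in `[0, 1]` (vectorized).
#' @param direction "decreasing" or "increasing".
#' @param n haplotype sample size.
#' @param freq_cutoff common-polymorphism frequency cutoff (default 0.15).
#' @param reference_r observed neutral-reference ratio at `f = 0`.
#' @return expected ratio(s), same length as `f`.
#' @export
expected_r_neutral <- function(f, direction = c("decreasing", "increasing"),
                               n, freq_cutoff = 0.15, reference_r = 1) {
  direction <- match.arg(direction)
  i <- seq_len(n - 1L)
  common <- i / n >= freq_cutoff
  if (!any(common)) stop("frequency cutoff leaves no polymorphic classes")
  one <- function(fv) {
    w_fix <- detection_prob(n, n, fv, direction)
    w_poly <- sum((1 / i[common]) *
                    detection_prob(i[common], n, fv, direction))
    c(w_fix, w_poly)
  }
  w0 <- one(0)
  vapply(f, function(fv) {
    w <- one(fv)
    reference_r * (w[1] / w0[1]) / (w[2] / w0[2])
  }, numeric(1))
}

#' Estimate the ascertainment parameter f from footprint scores
#'
#' Conservative estimator: per TF, the detection limit is the lowest PWM
#' score among its footprint sites; `f` is the fraction of observed
#' variants whose weaker (lower-scoring) allele falls below that limit.
#' The pooled estimate is the variant-count-weighted mean over TFs.
#'
#' @param footprint_scores data.frame with columns `tf` and `score`
#'   (per-footprint mel PWM scores).
#' @param weak_scores data.frame with columns `tf` and `score` (per
#'   observed variant, the full-site PWM score of its lower-scoring
#'   allele).
#' @return data.frame per TF (tf, detection_limit, n_variants, f) with
#'   attribute `pooled_f`; TFs without variants are excluded from pooling
#'   and get `NA` f.
#' @export
estimate_f <- function(footprint_scores, weak_scores) {
  stopifnot(nrow(footprint_scores) >= 1L)
  tfs <- unique(footprint_scores$tf)
  rows <- lapply(tfs, function(tf) {
    lim <- min(footprint_scores$score[footprint_scores$tf == tf])
    ws <- weak_scores$score[weak_scores$tf == tf]
    data.frame(tf = tf, detection_limit = lim,
               n_variants = length(ws),
               f = if (length(ws)) mean(ws < lim) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  with_v <- out$n_variants > 0
  attr(out, "pooled_f") <-
    if (any(with_v))
      sum(out$f[with_v] * out$n_variants[with_v]) / sum(out$n_variants[with_v])
    else NA_real_
  out
}

#' Tabulate expected spectra and ratio curves over a grid of f
#'
#' Convenience driver for ascertainment figures: the expected neutral SFS
#' and expected neutral r for each value of `f` in a grid, per direction.
#'
#' @param n haplotype sample size.
#' @param f_grid numeric vector of f values.
#' @param freq_cutoff common-polymorphism cutoff for the r curve.
#' @param reference_r neutral-reference ratio at f = 0.
#' @return list with `sfs` (data.frame: direction, f, i, probability) and
#'   `r_curve` (data.frame: direction, f, expected_r).
#' @export
ascertainment_curves <- function(n, f_grid = seq(0, 1, by = 0.1),
                                 freq_cutoff = 0.15, reference_r = 1) {
  sfs <- do.call(rbind, lapply(c("decreasing", "increasing"), function(d)
    do.call(rbind, lapply(f_grid, function(fv)
      data.frame(direction = d, f = fv, i = seq_len(n - 1L),
                 probability = expected_sfs(n, fv, d))))))
  r_curve <- do.call(rbind, lapply(c("decreasing", "increasing"), function(d)
    data.frame(direction = d, f = f_grid,
               expected_r = expected_r_neutral(f_grid, d, n, freq_cutoff,
                                               reference_r))))
  list(sfs = sfs, r_curve = r_curve)
}
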