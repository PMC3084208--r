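#' Binding-site presence call
#'
#' A sequence is called a binding site when its PWM score is at least the
#' cutoff (boundary inclusive).  With the default cutoff of 0 bits this
#' corresponds to the sequence being more likely under the motif model than
#' under the background model.
#'
#' @param score PWM score(s) in bits (vectorized).
#' @param cutoff score cutoff in bits.
#' @return logical vector.
#' @export
presence_call <- function(score, cutoff = 0) score >= cutoff

#' TF-specific empirical score cutoff
#'
#' Ranks a TF's footprint-site scores in descending order and returns the
#' value at the 80% quantile of that ranking, i.e. the value at rank
#' `ceiling(q * n)` from the top.  Equivalently the (1-q) lower quantile of
#' the scores.  The convention (rank `ceiling(q*n)` descending) is exposed
#' so it can be overridden.
#'
#' @param scores numeric footprint-site scores for one TF.
#' @param q quantile on the descending ranking (default 0.8).
#' @return scalar cutoff.
#' @export
tf_quantile_cutoff <- function(scores, q = 0.8) {
  stopifnot(length(scores) >= 1L, q > 0, q <= 1)
  sort(scores, decreasing = TRUE)[ceiling(q * length(scores))]
}

#' Classify a turnover event from three presence calls
#'
#' Maps the presence/absence pattern in (mel, ancestor, sim) onto a
#' turnover event.  Gains and losses are lineage-polarized against the
#' inferred mel-sim ancestor; the two patterns that imply parallel gain or
#' parallel loss are labelled "complex" and counted, never merged.
#'
#' @param mel,anc,sim logical presence calls (vectorized).
#' @return character vector in c("conserved", "absent", "gain_mel",
#'   "loss_mel", "gain_sim", "loss_sim", "complex").
#' @export
classify_event <- function(mel, anc, sim) {
  key <- paste0(as.integer(mel), as.integer(anc), as.integer(sim))
  map <- c("111" = "conserved", "000" = "absent",
           "100" = "gain_mel", "011" = "loss_mel",
           "001" = "gain_sim", "110" = "loss_sim",
           "101" = "complex",  "010" = "complex")
  unname(map[key])
}

#' Presence calls and turnover events for a score table
#'
#' Scores each TFBS core in mel, the inferred ancestor, and sim must be
#' supplied per site; cutoffs are either a fixed score (default 0 bits) or
#' TF-specific empirical cutoffs computed from the mel footprint scores
#' ([tf_quantile_cutoff()]).
#'
#' @param scores data.frame with columns `site_id`, `tf_name`,
#'   `score_mel`, `score_anc`, `score_sim`.
#' @param cutoff_mode "score_gt_zero" (fixed cutoff) or "tf_quantile80".
#' @param cutoff fixed cutoff used in "score_gt_zero" mode.
#' @param q descending-rank quantile used in "tf_quantile80" mode.
#' @return the input with appended `cutoff`, `call_mel`, `call_anc`,
#'   `call_sim`, `event` columns.
#' @export
call_presence <- function(scores,
                          cutoff_mode = c("score_gt_zero", "tf_quantile80"),
                          cutoff = 0, q = 0.8) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (cutoff_mode == "score_gt_zero") {
    scores$cutoff <- cutoff
  } else {
    cuts <- tapply(scores$score_mel, scores$tf_name, tf_quantile_cutoff, q = q)
    scores$cutoff <- as.numeric(cuts[scores$tf_name])
  }
  scores$call_mel <- presence_call(scores$score_mel, scores$cutoff)
  scores$call_anc <- presence_call(scores$score_anc, scores$cutoff)
  scores$call_sim <- presence_call(scores$score_sim, scores$cutoff)
  scores$event <- classify_event(scores$call_mel, scores$call_anc,
                                 scores$call_sim)
  scores
}

#' Turnover rates from classified events
#'
#' Per-event percentages over all sites, plus the total turnover rate
#' (all gains and losses combined).
#'
#' @param events character vector of events from [classify_event()].
#' @return named numeric vector of percentages (one per event class,
#'   classes with zero counts included) plus `total_turnover`.
#' @export
turnover_rates <- function(events) {
  stopifnot(length(events) >= 1L)
  lv <- c("conserved", "absent", "gain_mel", "loss_mel",
          "gain_sim", "loss_sim", "complex")
  counts <- table(factor(events, levels = lv))
  pct <- 100 * as.numeric(counts) / length(events)
  names(pct) <- lv
  c(pct, total_turnover = sum(pct[c("gain_mel", "loss_mel",
                                    "gain_sim", "loss_sim")]))
}

#' Per-TF divergence heterogeneity test
#'
#' Tests whether binding-site divergence rates differ among TFs.  The
#' pooled maximum-likelihood mean rate is `sum(diffs)/sum(sites)`; each TF
#' is tested against it with a two-sided exact binomial test, and rejection
#' is assessed at a Bonferroni-corrected level `alpha / n_TF`.  No
#' rejections means pooling observations across TFs is defensible.
#'
#' @param diffs named integer vector: per-TF count of diverged nucleotides.
#' @param sites named integer vector: per-TF count of binding-site
#'   nucleotides (same names/order as `diffs`).
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with columns tf, diffs, sites, rate, p_value,
#'   significant; attributes `pooled_rate` and `alpha_adjusted`.
#' @export
divergence_heterogeneity <- function(diffs, sites, alpha = 0.05) {
  stopifnot(length(diffs) == length(sites), all(sites > 0))
  pooled <- sum(diffs) / sum(sites)
  p <- vapply(seq_along(diffs), function(i)
    stats::binom.test(diffs[i], sites[i], p = pooled,
                      alternative = "two.sided")$p.value, numeric(1))
  adj <- alpha / length(diffs)
  out <- data.frame(tf = if (is.null(names(diffs)))
                           as.character(seq_along(diffs)) else names(diffs),
                    diffs = as.integer(diffs), sites = as.integer(sites),
                    rate = diffs / sites, p_value = p,
                    significant = p < adj, stringsAsFactors = FALSE)
  attr(out, "pooled_rate") <- pooled
  attr(out, "alpha_adjusted") <- adj
  rownames(out) <- NULL
  out
}

#' Score the three lineages of an extracted TFBS
#'
#' Scores the mel core, the sim core, and the inferred ancestral core of a
#' passing TFBS alignment, on the strand chosen by the mel motif search
#' (the core columns are fixed; the ancestor is not re-searched).  The
#' ancestral core is reconstructed column-wise with [infer_ancestor()];
#' sites with any ambiguous ancestral column get `NA` ancestor score.
#'
#' @param tfbs a passing `tfbs_alignment`.
#' @param pwm the TF's `pwm`.
#' @return one-row data.frame: site_id, tf_name, score_mel, score_anc,
#'   score_sim (NA where the sequence is unscoreable).
#' @export
score_tfbs_lineages <- function(tfbs, pwm) {
  stopifnot(isTRUE(tfbs$pass_filters))
  orient <- function(s) if (tfbs$strand == "+") s else revcomp(s)
  safe_score <- function(s) {
    if (is.na(s) || grepl("[^ACGT]", s)) return(NA_real_)
    score_sequence(pwm, orient(s))
  }
  sp <- tfbs$species_cores
  anc_chars <- vapply(seq_len(pwm_length(pwm)), function(k) {
    st <- vapply(SPECIES, function(x) {
      s <- sp[[x]]
      if (is.null(s) || is.na(s)) NA_character_ else substr(s, k, k)
    }, character(1))
    a <- infer_ancestor(st)
    if (identical(a, "ambiguous")) "N" else a
  }, character(1))
  anc <- paste(anc_chars, collapse = "")
  data.frame(site_id = tfbs$site_id, tf_name = tfbs$tf_name,
             score_mel = safe_score(sp[["mel"]]),
             score_anc = safe_score(anc),
             score_sim = safe_score(if ("sim" %in% names(sp)) sp[["sim"]]
                                    else NA_character_),
             stringsAsFactors = FALSE)
}
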