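#' Infer the mel-sim ancestral base by parsimony
#'
#' Maximum-parsimony (unit-cost) ancestral state reconstruction on the
#' fixed species topology `((mel,(sim,sec)),(yak,ere))`, evaluated at the
#' mel-sim common ancestor (the node joining mel with the sim/sec clade).
#' Implemented as Sankoff dynamic programming re-rooted at that node, which
#' yields the exact set of most-parsimonious states; when that set contains
#' more than one base the site is reported `"ambiguous"` and should be
#' dropped (and counted) by the caller.  Missing states (`NA` or non-ACGT)
#' are uninformative; if all three outgroups (sec, yak, ere) are missing
#' the result is `"ambiguous"`.
#'
#' @param states named character vector or list of per-species bases; names
#'   among mel, sim, sec, yak, ere.  Order is irrelevant.
#' @return single character: one of "A","C","G","T" or "ambiguous".
#' @export
infer_ancestor <- function(states) {
  states <- unlist(states)[SPECIES]
  names(states) <- SPECIES
  obs <- toupper(as.character(states))
  names(obs) <- SPECIES
  obs[!(obs %in% BASES)] <- NA_character_
  if (all(is.na(obs[c("sec", "yak", "ere")]))) return("ambiguous")
  leaf_cost <- function(b) {
    if (is.na(b)) rep(0, 4) else ifelse(BASES == b, 0, Inf)
  }
  # min over child states of (child cost + 1 if state changes)
  up <- function(cost) pmin(cost, min(cost) + 1)
  cost_sim <- leaf_cost(obs[["sim"]]); cost_sec <- leaf_cost(obs[["sec"]])
  cost_yak <- leaf_cost(obs[["yak"]]); cost_ere <- leaf_cost(obs[["ere"]])
  cost_mel <- leaf_cost(obs[["mel"]])
  cost_C <- up(cost_sim) + up(cost_sec)      # (sim,sec) ancestor
  cost_B <- up(cost_yak) + up(cost_ere)      # (yak,ere) ancestor
  cost_A <- up(cost_mel) + up(cost_C) + up(cost_B)  # mel-sim ancestor
  best <- BASES[cost_A <= min(cost_A) + 1e-9]
  if (length(best) != 1L) "ambiguous" else best
}

#' Polarize a variant site onto a lineage
#'
#' Given a biallelic variant site and the inferred mel-sim ancestral base,
#' determines the derived allele, the lineage (mel or sim) on which it
#' arose, whether it is fixed or segregating, and its derived-allele count
#' out of the non-missing sample.  Sites whose derived allele is observed
#' in both lineages, or whose ancestral allele is absent from both samples,
#' are returned `"unpolarized"` and must be dropped (and counted) by the
#' caller.
#'
#' @param v one-row data.frame as produced by [call_variants()] (flag must
#'   be "ok").
#' @param ancestor ancestral base from [infer_ancestor()].
#' @return list with `lineage` ("mel", "sim", or "unpolarized"),
#'   `ancestral_base`, `derived_base`, `derived_count`, `sample_size`,
#'   `kind` ("fixed" or "segregating"), `reason` (why unpolarized, else NA).
#' @export
polarize_variant <- function(v, ancestor) {
  unpol <- function(reason)
    list(lineage = "unpolarized", ancestral_base = ancestor,
         derived_base = NA_character_, derived_count = NA_integer_,
         sample_size = NA_integer_, kind = NA_character_, reason = reason)
  if (identical(ancestor, "ambiguous")) return(unpol("ambiguous_ancestor"))
  mel_counts <- as.integer(v[paste0("mel_", BASES)])
  sim_counts <- as.integer(v[paste0("sim_", BASES)])
  names(mel_counts) <- names(sim_counts) <- BASES
  obs <- BASES[(mel_counts + sim_counts) > 0]
  if (length(obs) != 2L) return(unpol("not_biallelic"))
  if (!(ancestor %in% obs)) return(unpol("ancestor_absent"))
  derived <- setdiff(obs, ancestor)
  in_mel <- mel_counts[derived] > 0
  in_sim <- sim_counts[derived] > 0
  if (in_mel && in_sim) return(unpol("derived_in_both"))
  lineage <- if (in_mel) "mel" else "sim"
  counts <- if (in_mel) mel_counts else sim_counts
  n <- sum(counts)
  dc <- counts[[derived]]
  kind <- if (dc == n) "fixed" else "segregating"
  list(lineage = lineage, ancestral_base = ancestor, derived_base = derived,
       derived_count = dc, sample_size = n, kind = kind,
       reason = NA_character_)
}

#' Polarize a variant table
#'
#' Vectorized driver: for each "ok" row of a variant table, infers the
#' ancestral base from the species-state columns and polarizes the variant.
#' Rows that cannot be polarized are kept with lineage "unpolarized" and a
#' machine-readable reason, so exclusions are countable.
#'
#' @param variants data.frame from [call_variants()].
#' @return the input with appended columns `ancestral_base`,
#'   `derived_base`, `lineage`, `derived_count`, `sample_size`, `kind`,
#'   `reason`.
#' @export
polarize_variants <- function(variants) {
  n <- nrow(variants)
  anc <- character(n); lineage <- character(n)
  derived <- character(n); dc <- integer(n); ss <- integer(n)
  kind <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (v$flag != "ok") {
      anc[i] <- NA_character_; lineage[i] <- "unpolarized"
      derived[i] <- NA_character_; dc[i] <- NA_integer_
      ss[i] <- NA_integer_; kind[i] <- NA_character_; reason[i] <- v$flag
      next
    }
    a <- infer_ancestor(c(mel = v$mel_state, sim = v$sim_state,
                          sec = v$sec_state, yak = v$yak_state,
                          ere = v$ere_state))
    p <- polarize_variant(v, a)
    anc[i] <- if (identical(a, "ambiguous")) NA_character_ else a
    lineage[i] <- p$lineage; derived[i] <- p$derived_base
    dc[i] <- p$derived_count; ss[i] <- p$sample_size
    kind[i] <- p$kind; reason[i] <- p$reason
  }
  variants$ancestral_base <- anc
  variants$derived_base <- derived
  variants$lineage <- lineage
  variants$derived_count <- dc
  variants$sample_size <- ss
  variants$kind <- kind
  variants$reason <- reason
  variants
}
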