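MK_CLASSES <- c("affinity_increasing", "affinity_decreasing",
                "nonsynonymous", "syn_no_change", "syn_pref_to_unpref",
                "syn_unpref_to_pref", "spacer")

#' Default preferred-codon table for Drosophila melanogaster
#'
#' One preferred (major) codon per amino acid with synonymous
#' alternatives, following standard D. melanogaster codon-usage studies
#' (C/G-ending major codons).  Used to split synonymous changes into
#' no-change, preferred-to-unpreferred and unpreferred-to-preferred
#' classes; the no-change class is the neutral reference of the
#' generalized MK test.  Swap in your own table to change the definition.
#'
#' @return named character vector mapping amino acid (one-letter code) to
#'   its preferred codon.
#' @export
preferred_codon_table <- function() {
  c(F = "TTC", L = "CTG", I = "ATC", V = "GTG", S = "AGC", P = "CCC",
    T = "ACC", A = "GCC", Y = "TAC", H = "CAC", Q = "CAG", N = "AAC",
    K = "AAG", D = "GAC", E = "GAG", C = "TGC", R = "CGC", G = "GGC")
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

#' Classify a synonymous codon change by codon preference
#'
#' Synonymous one-step codon changes are split by their predicted effect on
#' codon-usage bias: changes between two preferred or two unpreferred
#' codons are "syn_no_change" (the neutral reference class), otherwise
#' "syn_pref_to_unpref" or "syn_unpref_to_pref".
#'
#' @param codon_from,codon_to three-letter codons encoding the same amino
#'   acid and differing at exactly one position.
#' @param preferred preferred-codon table ([preferred_codon_table()]).
#' @return one of "syn_no_change", "syn_pref_to_unpref",
#'   "syn_unpref_to_pref".
#' @export
classify_synonymous <- function(codon_from, codon_to,
                                preferred = preferred_codon_table()) {
  codon_from <- toupper(codon_from); codon_to <- toupper(codon_to)
  aa1 <- codon_aa(codon_from); aa2 <- codon_aa(codon_to)
  if (aa1 != aa2)
    stop("nonsynonymous codon pair ", codon_from, "->", codon_to,
         " (", aa1, "->", aa2, "); route to the nonsynonymous class")
  if (codon_from == codon_to) stop("codons are identical")
  p1 <- codon_from %in% preferred
  p2 <- codon_to %in% preferred
  if (p1 == p2) "syn_no_change"
  else if (p1) "syn_pref_to_unpref"
  else "syn_unpref_to_pref"
}

#' Build a generalized McDonald-Kreitman table
#'
#' Counts, per functional class, the fixed differences and the common
#' polymorphisms on one lineage.  A segregating variant is "common" when
#' its derived-allele frequency among non-missing alleles is at least
#' `freq_cutoff` (default 0.15, which purges most weakly deleterious
#' variants); rarer polymorphisms are excluded from the table.
#'
#' @param variants data.frame with columns `class` (a functional class
#'   label), `kind` ("fixed"/"segregating"), `derived_count`,
#'   `sample_size`; all rows must already be restricted to one lineage.
#' @param freq_cutoff common-polymorphism derived-allele-frequency cutoff.
#' @param reference_class the neutral reference class label.
#' @param classes class labels to tabulate (default: the observed labels,
#'   plus the reference class); absent classes get zero rows.
#' @return data.frame of class `mk_table` with columns class, fixed, poly,
#'   r (fixed/poly; NA when poly is 0, flagged via the `r_undefined`
#'   column); attributes `reference_class`, `freq_cutoff`.
#' @export
build_mk_table <- function(variants, freq_cutoff = 0.15,
                           reference_class = "syn_no_change",
                           classes = NULL) {
  if (is.null(classes))
    classes <- union(unique(variants$class), reference_class)
  keep_poly <- variants$kind == "segregating" &
    variants$derived_count / variants$sample_size >= freq_cutoff
  keep_fix <- variants$kind == "fixed"
  fixed <- vapply(classes, function(cl)
    sum(keep_fix & variants$class == cl), numeric(1))
  poly <- vapply(classes, function(cl)
    sum(keep_poly & variants$class == cl), numeric(1))
  out <- data.frame(class = classes, fixed = as.integer(fixed),
                    poly = as.integer(poly),
                    r = ifelse(poly > 0, fixed / poly, NA_real_),
                    r_undefined = poly == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference_class") <- reference_class
  attr(out, "freq_cutoff") <- freq_cutoff
  class(out) <- c("mk_table", "data.frame")
  out
}

#' @export
print.mk_table <- function(x, ...) {
  cat("Generalized MK table (common-polymorphism cutoff ",
      attr(x, "freq_cutoff"), ", reference: ",
      attr(x, "reference_class"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Generalized MK test of one class against the neutral reference
#'
#' Two-sided Fisher exact test on the 2x2 table of (fixed, common
#' polymorphic) counts for the test class versus the neutral reference
#' class.  An all-zero margin gives p = 1 with a warning.
#'
#' @param table an `mk_table`.
#' @param test_class class label to test.
#' @param reference_class reference label (default: the table's own).
#' @return list with `table` (the 2x2 matrix), `p.value`, `test_class`,
#'   `reference_class`.
#' @export
mk_test <- function(table, test_class,
                    reference_class = attr(table, "reference_class")) {
  get_row <- function(cl) {
    i <- match(cl, table$class)
    if (is.na(i)) stop("class ", cl, " not in table")
    c(fixed = table$fixed[i], poly = table$poly[i])
  }
  m <- rbind(test = get_row(test_class), reference = get_row(reference_class))
  if (any(colSums(m) == 0) || any(rowSums(m) == 0)) {
    warning("degenerate MK 2x2 table (zero margin); p = 1")
    p <- 1
  } else {
    p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  list(table = m, p.value = p, test_class = test_class,
       reference_class = reference_class)
}

#' Chi-square null sample for the mutational-input test
#'
#' Draws `reps` multinomial samples of size `n` from `probs` and returns
#' the chi-square statistic of each against its expectation; the null
#' sample consumed by [mutational_input_test()].
#'
#' @param n number of observations per draw.
#' @param probs class probabilities (summing to 1).
#' @param reps number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of length `reps`.
#' @export
simulate_table1_null <- function(n, probs, reps = 10000L, seed = NULL) {
  stopifnot(abs(sum(probs) - 1) < 1e-9, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(reps, size = n, prob = probs)
  expected <- n * probs
  pos <- expected > 0
  colSums((draws[pos, , drop = FALSE] - expected[pos])^2 / expected[pos])
}

#' Mutational-input test for affinity-class polymorphism counts
#'
#' Tests whether the observed counts of affinity-increasing and
#' affinity-decreasing polymorphisms are compatible with the mutational
#' input, i.e. with the probabilities that a random new mutation falls in
#' either class ([mutational_probabilities()], renormalized over the two
#' classified classes).  Because expected counts can be small, the
#' chi-square p-value is estimated by Monte-Carlo simulation (multinomial
#' draws under the null) with the standard (1 + k) / (reps + 1) correction.
#'
#' @param observed length-2 counts c(increase, decrease).
#' @param probs length-2 mutational-input probabilities for the two
#'   classes (renormalized internally).
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed optional RNG seed.
#' @return list of class `mutational_input_test`: `observed`, `probs`,
#'   `expected`, `chisq`, `p.value`, `reps`.
#' @export
mutational_input_test <- function(observed, probs, reps = 10000L,
                                  seed = NULL) {
  stopifnot(length(observed) == 2L, length(probs) == 2L,
            all(observed >= 0), all(probs >= 0), sum(probs) > 0)
  probs <- probs / sum(probs)
  n <- sum(observed)
  expected <- n * probs
  if (any(probs == 0 & observed > 0)) {
    warning("observation in a zero-probability class; p at the Monte-Carlo ",
            "resolution floor")
    chisq <- Inf
  } else {
    pos <- expected > 0
    chisq <- sum((observed[pos] - expected[pos])^2 / expected[pos])
  }
  null <- simulate_table1_null(n, probs, reps = reps, seed = seed)
  p <- (1 + sum(null >= chisq - 1e-12)) / (reps + 1)
  structure(list(observed = observed, probs = probs, expected = expected,
                 chisq = chisq, p.value = p, reps = reps),
            class = "mutational_input_test")
}

#' @export
print.mutational_input_test <- function(x, ...) {
  cat("Mutational-input chi-square test (", x$reps, " simulations)\n",
      sep = "")
  df <- data.frame(class = c("increase", "decrease"),
                   prob = round(x$probs, 3), observed = x$observed,
                   expected = round(x$expected, 1))
  print(df, row.names = FALSE)
  cat(sprintf("chi-square = %.3f, simulated p = %.4g\n", x$chisq, x$p.value))
  invisible(x)
}

#' MK tables stratified by ancestral binding strength
#'
#' Splits variants into bins of predicted ancestral PWM score and builds
#' one MK table per bin; used to ask whether an excess of substitutions is
#' confined to weak ancestral sites (where ascertainment acts most
#' strongly) or extends to strong sites.
#'
#' @param variants as for [build_mk_table()], with an extra `anc_score`
#'   column (bits).
#' @param breaks bin edges passed to [cut()] (right-open, include lowest).
#' @param ... forwarded to [build_mk_table()].
#' @return list with `tables` (named list of `mk_table`, one per bin) and
#'   `summary` (data.frame bin x class of fixed, poly, r, with zero-poly
#'   bins flagged).
#' @export
mk_table_by_ancestral_strength <- function(variants, breaks, ...) {
  bins <- cut(variants$anc_score, breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  tabs <- lapply(levels(bins), function(b)
    build_mk_table(variants[!is.na(bins) & bins == b, , drop = FALSE], ...))
  names(tabs) <- levels(bins)
  summ <- do.call(rbind, lapply(levels(bins), function(b) {
    t <- tabs[[b]]
    if (!nrow(t)) return(NULL)
    data.frame(bin = b, t, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(tables = tabs, summary = summ)
}
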