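BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' Construct a position weight matrix (PWM) object.  A PWM holds, for each
#' motif position, the probability of observing each nucleotide, together
#' with a background nucleotide distribution.  Scores are log2 likelihood
#' ratios of motif versus background, so a score of 0 means a sequence is
#' equally likely under either model.
#'
#' @param probs 4 x L numeric matrix of per-position nucleotide
#'   probabilities or counts; rows in A, C, G, T order.
#' @param tf_name transcription factor name.
#' @param background length-4 probability vector (A, C, G, T).  Default
#'   uniform.
#' @param pseudocount non-negative scalar added to every cell before
#'   normalization.  The default adds 0.01 only when the matrix contains
#'   zeros, so that log-ratios stay finite.
#' @return an object of class `pwm` with elements `tf_name`, `probs`
#'   (columns renormalized to sum to 1), `background`, `pseudocount`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0, 2, 2, 2, 2), nrow = 4)
#' p <- pwm(m, tf_name = "toy")
#' score_sequence(p, "AA")
#' @export
pwm <- function(probs, tf_name = "TF", background = rep(0.25, 4),
                pseudocount = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L)
    stop("PWM matrix must have 4 rows (A, C, G, T); got ", nrow(probs))
  if (any(probs < 0))
    stop("PWM matrix entries must be non-negative")
  if (is.null(pseudocount))
    pseudocount <- if (any(probs == 0)) 0.01 else 0
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  probs <- probs + pseudocount
  cs <- colSums(probs)
  if (any(cs <= 0)) stop("PWM column with zero total; use a pseudocount")
  probs <- sweep(probs, 2, cs, "/")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive values")
  background <- background / sum(background)
  rownames(probs) <- BASES
  structure(list(tf_name = tf_name, probs = probs,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM for", x$tf_name, "- length", ncol(x$probs), "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm` object.
#' @export
pwm_length <- function(x) ncol(x$probs)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' Read a PWM from a plain-text matrix file
#'
#' Two dialects are auto-detected: JASPAR-style (4 rows = A, C, G, T, with
#' optional leading base labels and brackets, one column per motif position)
#' and patser/TRANSFAC-style column matrices (one row per motif position,
#' 4 columns = A, C, G, T, optional header line of base labels).  Counts are
#' converted to probabilities after adding `pseudocount` to every cell.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a `pwm` object.
#' @export
read_pwm <- function(path, tf_name = NULL, background = rep(0.25, 4),
                     pseudocount = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  header <- grepl("^>", lines)
  if (is.null(tf_name)) {
    tf_name <- if (any(header)) sub("^>\\s*", "", lines[which(header)[1L]])
               else sub("\\.[^.]*$", "", basename(path))
  }
  lines <- lines[!header & nzchar(lines)]
  # header line of bare base labels (patser column style)
  if (length(lines)) {
    toks1 <- strsplit(gsub("[][]", " ", lines[1L]), "[,\\s]+",
                      perl = TRUE)[[1L]]
    toks1 <- toupper(toks1[nzchar(toks1)])
    if (length(toks1) && all(toks1 %in% BASES)) lines <- lines[-1L]
  }
  rows <- lapply(seq_along(lines), function(i) {
    ln <- gsub("[][]", " ", lines[i])
    toks <- strsplit(ln, "[,\\s]+", perl = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    label <- NA_character_
    if (length(toks) && toupper(toks[1L]) %in% BASES &&
        is.na(suppressWarnings(as.numeric(toks[1L])))) {
      label <- toupper(toks[1L])
      toks <- toks[-1L]
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("malformed PWM matrix at line ", i, ": ", lines[i])
    list(label = label, vals = vals)
  })
  labels <- vapply(rows, `[[`, character(1), "label")
  vals <- lapply(rows, `[[`, "vals")
  nv <- lengths(vals)
  if (length(unique(nv)) != 1L)
    stop("malformed PWM matrix: ragged rows (", paste(nv, collapse = ","), ")")
  mat <- do.call(rbind, vals)
  if (nrow(mat) == 4L && all(!is.na(labels[seq_len(4L)]))) {
    rownames(mat) <- labels
    mat <- mat[BASES, , drop = FALSE]        # JASPAR rows, possibly reordered
  } else if (nrow(mat) == 4L && ncol(mat) != 4L) {
    # unlabeled 4-row matrix: assume A,C,G,T rows
  } else if (ncol(mat) == 4L) {
    mat <- t(mat)                            # patser column matrix
  } else if (nrow(mat) != 4L) {
    stop("malformed PWM matrix: expected 4 rows or 4 columns, got ",
         nrow(mat), " x ", ncol(mat))
  }
  if (any(mat < 0)) {
    bad <- which(apply(mat, 2, function(cc) any(cc < 0)))[1L]
    stop("malformed PWM matrix: negative entry in motif column ", bad)
  }
  pwm(mat, tf_name = tf_name, background = background,
      pseudocount = pseudocount)
}

#' Read a 4 x 4 relative mutation-rate matrix
#'
#' Expects a TSV with header row and column of base labels A, C, G, T.
#' The diagonal is forced to zero; rates are relative (only ratios matter).
#'
#' @param path file path.
#' @return 4 x 4 numeric matrix with A,C,G,T dimnames, zero diagonal.
#' @export
read_mutation_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- toupper(rownames(m)); colnames(m) <- toupper(colnames(m))
  if (!setequal(rownames(m), BASES) || !setequal(colnames(m), BASES))
    stop("mutation matrix must have A,C,G,T rows and columns")
  m <- m[BASES, BASES]
  diag(m) <- 0
  validate_mutation_matrix(m)
  m
}

validate_mutation_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != 4L))
    stop("mutation matrix must be 4 x 4")
  if (any(m < 0)) stop("mutation rates must be non-negative")
  if (any(diag(m) != 0)) stop("mutation matrix diagonal must be zero")
  if (any(rowSums(m) <= 0))
    stop("every base needs at least one positive mutation rate")
  invisible(m)
}

seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1L]], BASES)
  idx
}

#' Score a sequence against a PWM
#'
#' Returns the log2 likelihood ratio of `seq` under the motif model versus
#' the background model, summed over positions:
#' sum_k log2(probs[b_k, k] / background[b_k]).
#'
#' @param pwm a `pwm` object.
#' @param seq DNA string whose length equals the motif length.
#' @return score in bits.
#' @export
score_sequence <- function(pwm, seq) {
  idx <- seq_to_idx(seq)
  L <- pwm_length(pwm)
  if (length(idx) != L)
    stop("sequence length ", length(idx), " does not match motif length ", L)
  if (anyNA(idx))
    stop2("tfbs_ambiguous_sequence",
          "sequence contains non-ACGT characters: ", seq)
  sum(log2(pwm$probs[cbind(idx, seq_len(L))] / pwm$background[idx]))
}

stop2 <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find the best-scoring motif match in a region
#'
#' Scans every window of motif length on both strands and returns the
#' maximal-score match.  Ties are broken deterministically: lowest offset
#' first, then the plus strand.  Windows containing non-ACGT characters are
#' skipped.
#'
#' @param pwm a `pwm` object.
#' @param region DNA string, length >= motif length.
#' @return list of class `scored_site`: `sequence` (match in motif
#'   orientation), `score` (bits), `offset` (1-based start of the window on
#'   the forward strand of `region`), `strand` ("+" or "-").
#' @export
best_match <- function(pwm, region) {
  L <- pwm_length(pwm)
  idx <- seq_to_idx(region)
  n <- length(idx)
  if (n < L)
    stop("region of length ", n, " is shorter than the motif (", L, ")")
  lpr_fwd <- log2(pwm$probs / pwm$background)         # 4 x L
  # minus strand: score of revcomp(window) under the motif equals scoring the
  # forward window with the complemented, position-reversed matrix
  lpr_rev <- lpr_fwd[4:1, L:1, drop = FALSE]
  n_off <- n - L + 1L
  best <- NULL
  for (o in seq_len(n_off)) {
    w <- idx[o:(o + L - 1L)]
    if (anyNA(w)) next
    for (st in c("+", "-")) {
      lpr <- if (st == "+") lpr_fwd else lpr_rev
      sc <- sum(lpr[cbind(w, seq_len(L))])
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(offset = o, strand = st, score = sc)
    }
  }
  if (is.null(best))
    stop2("tfbs_ambiguous_sequence",
          "no scoreable window (ambiguity codes throughout region)")
  win <- substr(region, best$offset, best$offset + L - 1L)
  seq <- if (best$strand == "+") toupper(win) else revcomp(win)
  structure(list(sequence = seq, score = best$score,
                 offset = best$offset, strand = best$strand),
            class = "scored_site")
}

#' @export
print.scored_site <- function(x, ...) {
  cat(sprintf("%s  %.3f bits  offset %d  strand %s\n",
              x$sequence, x$score, x$offset, x$strand))
  invisible(x)
}

#' PWM score change of a point mutation
#'
#' The score difference caused by mutating position `position` of the motif
#' from `from_base` to `to_base`:
#' log2(probs[to,k]/bg[to]) - log2(probs[from,k]/bg[from]).
#' Independent of the rest of the sequence; positive values predict
#' increased binding affinity.
#'
#' @param pwm a `pwm` object.
#' @param position 1-based motif position.
#' @param from_base,to_base single characters in A, C, G, T.
#' @return score difference in bits (exactly 0 when the bases are equal).
#' @export
delta_score <- function(pwm, position, from_base, to_base) {
  L <- pwm_length(pwm)
  if (position < 1L || position > L)
    stop("position ", position, " outside motif of length ", L)
  fi <- match(toupper(from_base), BASES)
  ti <- match(toupper(to_base), BASES)
  if (is.na(fi) || is.na(ti))
    stop2("tfbs_ambiguous_sequence", "bases must be one of A, C, G, T")
  if (fi == ti) return(0)
  unname(log2(pwm$probs[ti, position] / pwm$background[ti]) -
           log2(pwm$probs[fi, position] / pwm$background[fi]))
}

#' Classify a mutation by predicted affinity change
#'
#' A mutation is called affinity-increasing when its score change is at
#' least `tau` bits, affinity-decreasing when at most `-tau`, and uncertain
#' otherwise.  The default threshold of one bit corresponds to a two-fold
#' change in the motif-versus-background likelihood ratio; values exactly at
#' the boundary are classified, not uncertain.
#'
#' @param delta score change(s) in bits (vectorized).
#' @param tau non-negative classification threshold in bits.
#' @return character vector in `c("increasing", "decreasing", "uncertain")`.
#' @export
classify_mutation <- function(delta, tau = 1) {
  if (tau < 0) stop("tau must be non-negative")
  out <- rep("uncertain", length(delta))
  out[delta >= tau & delta > 0] <- "increasing"
  out[delta <= -tau & delta < 0] <- "decreasing"
  out
}

#' Mutational-input probabilities of affinity classes
#'
#' The probability that a random new mutation falling in a binding site is
#' affinity-increasing, affinity-decreasing, or uncertain, given the
#' ancestral site sequences and a relative mutation-rate matrix.  At each
#' site position with ancestral base b, each of the three possible mutations
#' b -> b' is weighted by its relative rate m[b, b'] and classified by its
#' PWM score change; per-position class probabilities (class weight divided
#' by total weight) are then averaged over every position of every site.
#'
#' @param pwms named list of `pwm` objects, keyed by TF name.
#' @param sites data.frame with columns `tf` and `sequence` (ancestral core
#'   sequences; each must match its TF's motif length).
#' @param m 4 x 4 relative mutation-rate matrix (A,C,G,T order, zero
#'   diagonal); default uniform rates.
#' @param tau classification threshold in bits.
#' @return named numeric vector `c(increase, decrease, uncertain)` summing
#'   to 1, with attributes `n_positions` (positions used) and `n_excluded`
#'   (positions skipped for ambiguity codes).
#' @export
mutational_probabilities <- function(pwms, sites, m = NULL, tau = 1) {
  if (is.null(m)) {
    m <- matrix(1, 4, 4, dimnames = list(BASES, BASES)); diag(m) <- 0
  }
  validate_mutation_matrix(m)
  tot <- c(increase = 0, decrease = 0, uncertain = 0)
  n_pos <- 0L; n_excl <- 0L
  for (s in seq_len(nrow(sites))) {
    p <- pwms[[sites$tf[s]]]
    if (is.null(p)) stop("no PWM for TF ", sites$tf[s])
    idx <- seq_to_idx(sites$sequence[s])
    if (length(idx) != pwm_length(p))
      stop("site ", s, " length does not match the ", p$tf_name, " motif")
    for (k in seq_along(idx)) {
      b <- idx[k]
      if (is.na(b)) { n_excl <- n_excl + 1L; next }
      w <- m[b, -b]
      targets <- BASES[-b]
      cls <- classify_mutation(
        vapply(targets, function(tb) delta_score(p, k, BASES[b], tb),
               numeric(1)), tau)
      wsum <- sum(w)
      tot["increase"] <- tot["increase"] + sum(w[cls == "increasing"]) / wsum
      tot["decrease"] <- tot["decrease"] + sum(w[cls == "decreasing"]) / wsum
      tot["uncertain"] <- tot["uncertain"] + sum(w[cls == "uncertain"]) / wsum
      n_pos <- n_pos + 1L
    }
  }
  if (n_pos == 0L) stop("no usable site positions")
  out <- tot / n_pos
  if (n_excl > 0L)
    message(n_excl, " position(s) with ambiguity codes excluded")
  structure(out, n_positions = n_pos, n_excluded = n_excl)
}
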