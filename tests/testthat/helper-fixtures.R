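# shared fixture builders; everything is generated in code under fixed seeds

random_pwm <- function(L, seed, concentration = 0.5, tf_name = "rTF") {
  set.seed(seed)
  cols <- replicate(L, {
    g <- rgamma(4, shape = concentration)
    g / sum(g)
  })
  pwm(cols, tf_name = tf_name, pseudocount = 1e-3)
}

random_seq <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# brute-force best-window scan used as the independent oracle for best_match
scan_oracle <- function(pwm, region) {
  L <- ncol(pwm$probs)
  n <- nchar(region)
  best <- NULL
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  naive_score <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(sapply(seq_along(ch), function(k) {
      b <- match(ch[k], c("A", "C", "G", "T"))
      log2(pwm$probs[b, k] / pwm$background[b])
    }))
  }
  for (o in seq_len(n - L + 1)) {
    w <- substr(region, o, o + L - 1)
    if (grepl("[^ACGT]", w)) next
    for (st in c("+", "-")) {
      s <- if (st == "+") w else rc(w)
      sc <- naive_score(s)
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(offset = o, strand = st, score = sc)
    }
  }
  best
}

# minimal aligned CRM: 5 identical species sequences + haplotype copies,
# which tests then perturb
make_crm <- function(seq, n_mel = 8, n_sim = 6, crm_id = "crmT",
                     mel = seq, sim = seq, sec = seq, yak = seq, ere = seq,
                     mel_haps = NULL, sim_haps = NULL) {
  crm_alignment(crm_id,
                c(mel = mel, sim = sim, sec = sec, yak = yak, ere = ere),
                mel_haplotypes = if (is.null(mel_haps)) rep(mel, n_mel)
                                 else mel_haps,
                sim_haplotypes = if (is.null(sim_haps)) rep(sim, n_sim)
                                 else sim_haps)
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# brute-force minimum-mutation parsimony over all internal labelings of
# ((mel,(sim,sec)),(yak,ere)); returns the MPR state set at the mel-sim
# ancestor (node joining mel with the sim/sec clade)
sankoff_oracle <- function(states) {
  B <- c("A", "C", "G", "T")
  obs <- states[c("mel", "sim", "sec", "yak", "ere")]
  leaf_cost <- function(node_state, b)
    if (is.na(b) || !(b %in% B)) 0 else as.integer(node_state != b)
  best_cost <- Inf
  best_states <- character()
  for (root in B) for (nA in B) for (nC in B) for (nB in B) {
    cost <- (root != nA) + (root != nB) + (nA != nC) +
      leaf_cost(nA, obs[["mel"]]) + leaf_cost(nC, obs[["sim"]]) +
      leaf_cost(nC, obs[["sec"]]) + leaf_cost(nB, obs[["yak"]]) +
      leaf_cost(nB, obs[["ere"]])
    if (cost < best_cost - 1e-9) {
      best_cost <- cost; best_states <- nA
    } else if (cost <= best_cost + 1e-9) {
      best_states <- union(best_states, nA)
    }
  }
  sort(best_states)
}
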