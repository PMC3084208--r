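#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults emulate the
#' structure of the study system: 162 mel haplotypes with variable
#' coverage, 6 sim haplotypes with missing data, a 5-taxon divergence
#' scaffold, footprint cores drawn from motif models, and single-allele
#' footprint ascertainment with parameter `f_true`.
#'
#' @param seed RNG seed for the whole dataset.
#' @param n_crm number of CRMs.
#' @param n_tfbs_per_crm footprint cores per CRM.
#' @param n_tf number of transcription factors (cores are assigned
#'   round-robin).
#' @param motif_length core motif length in bp.
#' @param spacer_length spacer length between cores in bp.
#' @param pwm_concentration Dirichlet-style concentration of simulated
#'   motif columns; lower is more informative.
#' @param theta population mutation parameter per site (Watterson scale).
#' @param branch_scale per-site substitution probability unit for the tree
#'   branches (short branches keep polarization near-exact).
#' @param gamma_inc,gamma_dec scaled selection coefficients applied to
#'   affinity-increasing / affinity-decreasing mutations on the mel and
#'   sim tip branches and to their segregating frequencies; 0 is neutral.
#' @param f_true ascertainment parameter: probability that the weak allele
#'   escapes footprint detection.
#' @param n_mel,n_sim haplotype sample sizes.
#' @param sim_missing_rate per-base missing-data probability in sim
#'   haplotypes.
#' @param mel_coverage_fun function(k) returning k per-site coverages
#'   (<= n_mel); the default keeps most sites at coverage >= 150 of 162.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_crm = 10L, n_tfbs_per_crm = 4L,
                       n_tf = 3L, motif_length = 8L, spacer_length = 20L,
                       pwm_concentration = 0.3, theta = 0.02,
                       branch_scale = 0.02, gamma_inc = 0, gamma_dec = 0,
                       f_true = 0, n_mel = 162L, n_sim = 6L,
                       sim_missing_rate = 0.1,
                       mel_coverage_fun = NULL) {
  if (is.null(mel_coverage_fun))
    mel_coverage_fun <- function(k) n_mel - stats::rbinom(k, 40L, 0.15)
  stopifnot(theta >= 0, branch_scale >= 0, f_true >= 0, f_true <= 1,
            n_mel >= 2, n_sim >= 2, sim_missing_rate >= 0,
            sim_missing_rate < 1)
  structure(list(seed = seed, n_crm = n_crm,
                 n_tfbs_per_crm = n_tfbs_per_crm, n_tf = n_tf,
                 motif_length = motif_length, spacer_length = spacer_length,
                 pwm_concentration = pwm_concentration, theta = theta,
                 branch_scale = branch_scale, gamma_inc = gamma_inc,
                 gamma_dec = gamma_dec, f_true = f_true, n_mel = n_mel,
                 n_sim = n_sim, sim_missing_rate = sim_missing_rate,
                 mel_coverage_fun = mel_coverage_fun),
            class = "sim_config")
}

#' Simulate a position weight matrix
#'
#' Motif columns are drawn from a symmetric Dirichlet-style scheme
#' (normalized gamma draws) with the given concentration; low
#' concentrations yield informative columns with a clear consensus.
#'
#' @param length motif length (>= 4).
#' @param concentration symmetric concentration parameter (> 0).
#' @param seed optional RNG seed.
#' @param tf_name name for the PWM.
#' @return a `pwm`; its consensus is available via [pwm_consensus()].
#' @export
simulate_pwm <- function(length, concentration = 0.3, seed = NULL,
                         tf_name = "simTF") {
  stopifnot(length >= 4, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  cols <- vapply(seq_len(length), function(k) {
    g <- stats::rgamma(4, shape = concentration, rate = 1)
    g / sum(g)
  }, numeric(4))
  pwm(cols, tf_name = tf_name, pseudocount = 1e-3)
}

#' Relative fixation weight of a selected mutation
#'
#' Kimura scaling of the fixation probability of a new semidominant
#' mutation with scaled selection coefficient gamma, relative to a neutral
#' one: `2*gamma / (1 - exp(-2*gamma))`, with limit 1 at gamma = 0.
#'
#' @param gamma scaled selection coefficient (vectorized).
#' @return relative fixation weight(s).
#' @export
fixation_weight <- function(gamma) {
  ifelse(abs(gamma) < 1e-8, 1, 2 * gamma / (1 - exp(-2 * gamma)))
}

#' Selected site-frequency-spectrum weights (Poisson Random Field)
#'
#' Standard-theory equilibrium density of derived-allele frequencies for
#' mutations with scaled selection coefficient gamma, evaluated on the
#' sample grid i/n for i = 1..n-1: proportional to
#' `(1 - exp(-2*gamma*(1-q))) / ((1 - exp(-2*gamma)) * q * (1-q))`,
#' which reduces to the neutral 1/q at gamma = 0.
#'
#' @param n sample size.
#' @param gamma scaled selection coefficient.
#' @return unnormalized weight vector over i = 1..n-1.
#' @export
prf_sfs_weights <- function(n, gamma) {
  q <- seq_len(n - 1L) / n
  if (abs(gamma) < 1e-8) return(1 / q)
  (1 - exp(-2 * gamma * (1 - q))) / ((1 - exp(-2 * gamma)) * q * (1 - q))
}

#' Forward-simulate neutral segregating sites through the footprint
#' ascertainment filter
#'
#' Generates derived-allele counts from the neutral spectrum
#' (proportional to 1/i), then applies the single-allele footprint assay:
#' one haplotype is sampled uniformly; when it carries the weak allele
#' (the derived allele for affinity-decreasing mutations, the ancestral
#' allele for affinity-increasing ones), the site's footprint escapes
#' detection with probability `f` and the site is dropped.  The surviving
#' counts validate [expected_sfs()] by forward simulation; the same filter
#' is what [simulate_dataset()] applies to its footprints.
#'
#' @param n_sites number of segregating sites to generate (pre-filter).
#' @param n haplotype sample size.
#' @param f ascertainment parameter in `[0, 1]`.
#' @param direction "decreasing" or "increasing".
#' @param seed optional RNG seed.
#' @return integer vector of surviving derived counts (length <=
#'   `n_sites`).
#' @export
simulate_ascertained_sfs <- function(n_sites, n, f,
                                     direction = c("decreasing",
                                                   "increasing"),
                                     seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(n - 1L, n_sites, replace = TRUE,
                  prob = 1 / seq_len(n - 1L))
  assay_derived <- stats::runif(n_sites) < i / n
  assay_weak <- if (direction == "decreasing") assay_derived else !assay_derived
  dropped <- assay_weak & (stats::runif(n_sites) < f)
  i[!dropped]
}

uniform_mutation_matrix <- function() {
  m <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  m
}

# class-dependent gamma for a mutation at a core position
.mutation_gamma <- function(cls, gamma_inc, gamma_dec) {
  switch(cls, increasing = gamma_inc, decreasing = gamma_dec, 0)
}

# evolve a sequence (character vector) along one branch.  `p_sub` is the
# neutral per-site substitution probability; on selective branches
# (mel/sim tips) the rate of each core-position mutation is scaled by the
# relative fixation weight of its affinity class, so positive gamma
# inflates and negative gamma depresses class-specific divergence.
.evolve_branch <- function(chars, p_sub, m, core_map, pwms, selective,
                           gamma_inc, gamma_dec, tau) {
  changes <- list()
  u <- stats::runif(length(chars))
  for (pos in seq_along(chars)) {
    b <- chars[pos]
    bi <- match(b, BASES)
    w <- m[bi, -bi]
    targets <- BASES[-bi]
    info <- core_map[[pos]]
    cls <- rep("noncore", 3L)
    dlt <- rep(NA_real_, 3L)
    fw <- rep(1, 3L)
    if (!is.null(info)) {
      dlt <- vapply(targets, function(tb)
        delta_score(pwms[[info$tf]], info$motif_pos, b, tb), numeric(1))
      cls <- classify_mutation(dlt, tau)
      if (selective)
        fw <- vapply(cls, function(cl)
          fixation_weight(.mutation_gamma(cl, gamma_inc, gamma_dec)),
          numeric(1))
    }
    wn <- w / sum(w)
    rate <- min(1, p_sub * sum(wn * fw))
    if (u[pos] >= rate) next
    pick <- sample.int(3L, 1L, prob = w * fw)
    chars[pos] <- targets[pick]
    changes[[length(changes) + 1L]] <-
      list(pos = pos, from = b, to = targets[pick], class = cls[pick],
           delta = dlt[pick])
  }
  list(chars = chars, changes = changes)
}

#' Simulate a complete truth-annotated CRM dataset
#'
#' Generates ancestral CRM sequences with embedded motif-consistent cores,
#' evolves them along the fixed 5-taxon scaffold
#' `((mel,(sim,sec)),(yak,ere))` with class-dependent fixation weighting
#' of core mutations on the mel and sim tip branches, plants segregating
#' mutations whose derived-allele frequencies follow the neutral or
#' selected (Poisson-Random-Field) spectrum of their affinity class,
#' applies mel coverage variation and sim missing data, and finally
#' applies the single-haplotype footprint ascertainment filter with
#' parameter `f_true`.  Everything is recorded pre-filter in the truth
#' table.
#'
#' Branch lengths (units of `branch_scale` substitutions/site): root to
#' the mel-sim ancestor 1.0; ancestor to mel 1.0; ancestor to the sim/sec
#' node 0.3; that node to sim 0.7 and to sec 0.9; root to the yak/ere node
#' 1.0; that node to yak and ere 1.5 each.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `crms` (list of `crm_alignment`),
#'   `footprints` (data.frame: crm_id, tf_name, start, end, site_id,
#'   core_start, detected), `pwms` (named list), `truth` (one row per
#'   planted mutation), `mutation_matrix`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tau <- 1
  m <- uniform_mutation_matrix()
  tf_names <- paste0("TF", seq_len(cfg$n_tf))
  pwms <- lapply(tf_names, function(nm)
    simulate_pwm(cfg$motif_length, cfg$pwm_concentration, tf_name = nm))
  names(pwms) <- tf_names

  crms <- list(); fp_rows <- list(); truth_rows <- list()
  unit <- cfg$branch_scale
  br <- c(root_A = 1.0, A_mel = 1.0, A_C = 0.3, C_sim = 0.7, C_sec = 0.9,
          root_B = 1.0, B_yak = 1.5, B_ere = 1.5) * unit
  selective <- function(chars, p)        # mel/sim tip branches
    .evolve_branch(chars, p, m, core_map, pwms, TRUE,
                   cfg$gamma_inc, cfg$gamma_dec, tau)
  neutral <- function(chars, p)
    .evolve_branch(chars, p, m, core_map, pwms, FALSE, 0, 0, tau)

  for (ci in seq_len(cfg$n_crm)) {
    crm_id <- sprintf("crm%03d", ci)
    # --- layout: spacer core spacer core ... spacer -------------------
    L_core <- cfg$motif_length
    core_starts <- cfg$spacer_length +
      (seq_len(cfg$n_tfbs_per_crm) - 1L) * (L_core + cfg$spacer_length) + 1L
    crm_len <- cfg$n_tfbs_per_crm * (L_core + cfg$spacer_length) +
      cfg$spacer_length
    core_tf <- tf_names[((seq_len(cfg$n_tfbs_per_crm) - 1L) %% cfg$n_tf) + 1L]
    root <- sample(BASES, crm_len, replace = TRUE)
    core_map <- vector("list", crm_len)
    for (k in seq_len(cfg$n_tfbs_per_crm)) {
      p <- pwms[[core_tf[k]]]
      for (j in seq_len(L_core)) {
        pos <- core_starts[k] + j - 1L
        root[pos] <- sample(BASES, 1L, prob = p$probs[, j])
        core_map[[pos]] <- list(tf = core_tf[k], motif_pos = j,
                                site = sprintf("%s_s%02d", crm_id, k))
      }
    }
    # --- divergence along the scaffold --------------------------------
    A <- neutral(root, br[["root_A"]])$chars        # mel-sim ancestor
    mel_ev <- selective(A, br[["A_mel"]])
    C <- neutral(A, br[["A_C"]])$chars
    sim_ev <- selective(C, br[["C_sim"]])
    sec <- neutral(C, br[["C_sec"]])$chars
    B <- neutral(root, br[["root_B"]])$chars
    yak <- neutral(B, br[["B_yak"]])$chars
    ere <- neutral(B, br[["B_ere"]])$chars
    mel <- mel_ev$chars
    sim <- sim_ev$chars
    # fixed-difference truth: compare tip against the mel-sim ancestor A
    fixed_truth <- function(tip, lineage, n_hap) {
      idx <- which(tip != A)
      lapply(idx, function(pos) {
        info <- core_map[[pos]]
        dlt <- if (is.null(info)) NA_real_ else
          delta_score(pwms[[info$tf]], info$motif_pos, A[pos], tip[pos])
        cls <- if (is.null(info)) "spacer" else classify_mutation(dlt, tau)
        list(pos = pos, lineage = lineage, kind = "fixed",
             anc = A[pos], der = tip[pos], delta = dlt, class = cls,
             count = n_hap, n = n_hap,
             site = if (is.null(info)) NA_character_ else info$site,
             tf = if (is.null(info)) NA_character_ else info$tf)
      })
    }
    muts <- c(fixed_truth(mel, "mel", cfg$n_mel),
              fixed_truth(sim, "sim", cfg$n_sim))
    # --- segregating mutations ----------------------------------------
    hap_mel <- matrix(rep(mel, each = cfg$n_mel), nrow = cfg$n_mel)
    hap_sim <- matrix(rep(sim, each = cfg$n_sim), nrow = cfg$n_sim)
    used <- vapply(muts, `[[`, numeric(1), "pos")
    for (lineage in c("mel", "sim")) {
      n_hap <- if (lineage == "mel") cfg$n_mel else cfg$n_sim
      tip <- if (lineage == "mel") mel else sim
      a_n <- sum(1 / seq_len(n_hap - 1L))
      S <- stats::rpois(1L, cfg$theta * crm_len * a_n)
      avail <- setdiff(seq_len(crm_len), used)
      if (S > length(avail)) S <- length(avail)
      pos_s <- if (S > 0) avail[sample.int(length(avail), S)] else integer()
      used <- c(used, pos_s)
      for (pos in pos_s) {
        b <- tip[pos]; bi <- match(b, BASES)
        w <- m[bi, -bi]; targets <- BASES[-bi]
        info <- core_map[[pos]]
        if (is.null(info)) {
          cls_all <- rep("spacer", 3L); dlt_all <- rep(NA_real_, 3L)
        } else {
          dlt_all <- vapply(targets, function(tb)
            delta_score(pwms[[info$tf]], info$motif_pos, b, tb), numeric(1))
          cls_all <- classify_mutation(dlt_all, tau)
        }
        pick <- sample.int(3L, 1L, prob = w)
        der <- targets[pick]; cls <- cls_all[pick]; dlt <- dlt_all[pick]
        gamma <- if (is.null(info)) 0 else
          .mutation_gamma(cls, cfg$gamma_inc, cfg$gamma_dec)
        freq_w <- prf_sfs_weights(n_hap, gamma)
        dc <- sample.int(n_hap - 1L, 1L, prob = freq_w)
        carriers <- sample.int(n_hap, dc)
        if (lineage == "mel") hap_mel[carriers, pos] <- der
        else hap_sim[carriers, pos] <- der
        muts[[length(muts) + 1L]] <-
          list(pos = pos, lineage = lineage, kind = "segregating",
               anc = b, der = der, delta = dlt, class = cls,
               count = dc, n = n_hap,
               site = if (is.null(info)) NA_character_ else info$site,
               tf = if (is.null(info)) NA_character_ else info$tf)
      }
    }
    # --- ascertainment: one random mel haplotype per footprint ---------
    assay_hap <- sample.int(cfg$n_mel, cfg$n_tfbs_per_crm, replace = TRUE)
    site_ids <- sprintf("%s_s%02d", crm_id, seq_len(cfg$n_tfbs_per_crm))
    detected <- rep(TRUE, cfg$n_tfbs_per_crm)
    for (k in seq_len(cfg$n_tfbs_per_crm)) {
      core_rng <- core_starts[k]:(core_starts[k] + L_core - 1L)
      for (mu in muts) {
        if (!(mu$pos %in% core_rng)) next
        if (!(mu$class %in% c("increasing", "decreasing"))) next
        carries_weak <- if (mu$lineage == "mel") {
          carries_derived <- if (mu$kind == "fixed") TRUE
            else hap_mel[assay_hap[k], mu$pos] == mu$der
          if (mu$class == "decreasing") carries_derived else !carries_derived
        } else {
          # sim-lineage changes never affect the mel assay allele; for
          # increasing sim mutations the mel allele is the weak one
          mu$class == "increasing"
        }
        if (carries_weak && stats::runif(1) < cfg$f_true)
          detected[k] <- FALSE
      }
    }
    # --- missing data -------------------------------------------------
    cov <- cfg$mel_coverage_fun(crm_len)
    cov <- pmin(pmax(cov, 0L), cfg$n_mel)
    for (j in which(cov < cfg$n_mel))
      hap_mel[sample.int(cfg$n_mel, cfg$n_mel - cov[j]), j] <- "N"
    miss <- matrix(stats::runif(length(hap_sim)) < cfg$sim_missing_rate,
                   nrow = nrow(hap_sim))
    hap_sim[miss] <- "N"

    collapse <- function(mat) apply(mat, 1L, paste, collapse = "")
    crms[[crm_id]] <- crm_alignment(
      crm_id,
      c(mel = paste(mel, collapse = ""), sim = paste(sim, collapse = ""),
        sec = paste(sec, collapse = ""), yak = paste(yak, collapse = ""),
        ere = paste(ere, collapse = "")),
      mel_haplotypes = collapse(hap_mel),
      sim_haplotypes = collapse(hap_sim))
    fp_rows[[crm_id]] <- data.frame(
      crm_id = crm_id, tf_name = core_tf,
      start = core_starts, end = core_starts + L_core - 1L,
      site_id = site_ids, core_start = core_starts, detected = detected,
      stringsAsFactors = FALSE)
    if (length(muts)) {
      det_by_site <- stats::setNames(detected, site_ids)
      truth_rows[[crm_id]] <- do.call(rbind, lapply(muts, function(mu)
        data.frame(crm_id = crm_id,
                   site_id = ifelse(is.na(mu$site), "spacer", mu$site),
                   tf = ifelse(is.na(mu$tf), NA_character_, mu$tf),
                   pos = mu$pos, lineage = mu$lineage, kind = mu$kind,
                   class = mu$class, delta = mu$delta,
                   ancestral_base = mu$anc, derived_base = mu$der,
                   derived_count = mu$count, sample_size = mu$n,
                   detected = if (!is.na(mu$site)) det_by_site[[mu$site]]
                              else TRUE,
                   stringsAsFactors = FALSE)))
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame()
  rownames(truth) <- NULL
  footprints <- do.call(rbind, fp_rows)
  rownames(footprints) <- NULL
  list(crms = crms, footprints = footprints, pwms = pwms, truth = truth,
       mutation_matrix = m, config = cfg)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits one FASTA per CRM (species + haplotype records), a BED-like
#' footprint TSV (0-based half-open, detected footprints only), JASPAR
#' 4-row PWM files, the mutation-rate TSV, and the truth table TSV.
#'
#' @param data result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (crm in data$crms)
    write_crm_alignment(crm, file.path(dir, paste0(crm$crm_id, ".fasta")))
  fp <- data$footprints[data$footprints$detected, ]
  utils::write.table(
    data.frame(fp$crm_id, fp$tf_name, fp$start - 1L, fp$end, fp$site_id),
    file.path(dir, "footprints.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (nm in names(data$pwms)) {
    p <- data$pwms[[nm]]
    lines <- c(paste0(">", nm),
               vapply(seq_len(4L), function(r)
                 paste(c(BASES[r],
                         format(p$probs[r, ], digits = 6)), collapse = "\t"),
                 character(1)))
    writeLines(lines, file.path(dir, paste0(nm, ".pwm")))
  }
  mm <- data$mutation_matrix
  utils::write.table(cbind(base = rownames(mm), as.data.frame(mm)),
                     file.path(dir, "mutation_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
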