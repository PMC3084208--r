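COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read a pipeline input dataset from disk
#'
#' Counterpart of [write_dataset()]: reads per-CRM FASTA alignments
#' (`<crm>.fasta`), the BED-like footprint table (`footprints.tsv`), all
#' `*.pwm` matrices, and `mutation_matrix.tsv` if present.
#'
#' @param dir dataset directory.
#' @return list with `crms`, `footprints`, `pwms`, `mutation_matrix`.
#' @export
read_dataset <- function(dir) {
  fas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  crms <- lapply(fas, read_crm_alignment)
  names(crms) <- vapply(crms, `[[`, character(1), "crm_id")
  footprints <- read_footprints(file.path(dir, "footprints.tsv"))
  pwm_files <- list.files(dir, pattern = "\\.pwm$", full.names = TRUE)
  pwms <- lapply(pwm_files, read_pwm)
  names(pwms) <- vapply(pwms, `[[`, character(1), "tf_name")
  mm_path <- file.path(dir, "mutation_matrix.tsv")
  mm <- if (file.exists(mm_path)) read_mutation_matrix(mm_path) else NULL
  list(crms = crms, footprints = footprints, pwms = pwms,
       mutation_matrix = mm)
}

# affinity change of one polarized core variant, on the matched strand
.variant_affinity <- function(pwm, strand, motif_col, anc, der, tau) {
  L <- pwm_length(pwm)
  if (strand == "+") {
    k <- motif_col; a <- anc; d <- der
  } else {
    k <- L + 1L - motif_col
    a <- COMPLEMENT[[anc]]; d <- COMPLEMENT[[der]]
  }
  delta <- delta_score(pwm, k, a, d)
  list(delta = delta, class = classify_mutation(delta, tau))
}

#' Run the full turnover analysis pipeline
#'
#' Chains every stage on an in-memory dataset (as produced by
#' [simulate_dataset()] or [read_dataset()]): TFBS extraction and
#' filtering, lineage scoring and presence/event calling, variant calling
#' in cores and spacers, parsimony polarization, affinity classification,
#' generalized MK tables per lineage, mutational-input probabilities and
#' test, projected site frequency spectra, and estimation of the
#' ascertainment parameter f.  Every excluded site or variant is logged
#' with a machine-readable reason.
#'
#' Simulated datasets contain no coding sequence, so the spacer class is
#' the default neutral reference for the MK tables; supply
#' `reference_class` and variant tables of your own to use a synonymous
#' no-change reference.
#'
#' @param data list with `crms`, `footprints`, `pwms` (and optionally
#'   `mutation_matrix`).
#' @param tau affinity classification threshold in bits.
#' @param freq_cutoff common-polymorphism frequency cutoff.
#' @param cutoff_mode presence cutoff mode ("score_gt_zero" or
#'   "tf_quantile80").
#' @param target_n SFS projection sample size (sites with lower coverage
#'   are dropped and counted); default 150.
#' @param anc_score_min optional ancestral-score restriction for the sim
#'   MK table (sites with ancestor score below it are excluded there).
#' @param reference_class neutral reference class for MK tables.
#' @param mk_reps Monte-Carlo replicates for the mutational-input test.
#' @param seed RNG seed for the stochastic stages.
#' @param outdir optional directory; when given, TSV reports and a JSON
#'   summary are written there.
#' @return list of class `turnover_run` with elements `scores`,
#'   `turnover_rates`, `variants`, `mk` (per-lineage `mk_table`s),
#'   `mk_tests`, `mut_probs`, `mut_input_test`, `sfs`, `f_estimate`,
#'   `exclusions`, `params`.
#' @export
run_pipeline <- function(data, tau = 1, freq_cutoff = 0.15,
                         cutoff_mode = "score_gt_zero", target_n = 150L,
                         anc_score_min = NULL,
                         reference_class = "spacer", mk_reps = 10000L,
                         seed = 1L, outdir = NULL) {
  set.seed(seed)
  fps <- data$footprints
  if ("detected" %in% names(fps)) fps <- fps[fps$detected, , drop = FALSE]
  excl <- list()
  note <- function(stage, id, reason)
    excl[[length(excl) + 1L]] <<- data.frame(stage = stage, id = id,
                                             reason = reason,
                                             stringsAsFactors = FALSE)
  tfbs_by_crm <- split(seq_len(nrow(fps)), fps$crm_id)
  score_rows <- list(); var_rows <- list(); anc_seq_rows <- list()
  tfbs_objs <- list()
  for (crm_id in names(tfbs_by_crm)) {
    crm <- data$crms[[crm_id]]
    if (is.null(crm)) stop("footprints reference unknown CRM ", crm_id)
    crm_tfbs <- list()
    for (i in tfbs_by_crm[[crm_id]]) {
      fp <- fps[i, ]
      p <- data$pwms[[fp$tf_name]]
      if (is.null(p)) stop("no PWM for TF ", fp$tf_name)
      t <- extract_tfbs(crm, fp, p)
      tfbs_objs[[fp$site_id]] <- t
      if (!isTRUE(t$pass_filters)) {
        note("extract", fp$site_id, t$fail_reason)
        next
      }
      crm_tfbs[[length(crm_tfbs) + 1L]] <- t
      sc <- score_tfbs_lineages(t, p)
      sc$strand <- t$strand
      score_rows[[fp$site_id]] <- sc
      v <- tfbs_variants(t)
      if (nrow(v)) {
        v$crm_id <- crm_id
        v$tf_name <- fp$tf_name
        v$context <- "tfbs"
        var_rows[[length(var_rows) + 1L]] <- v
      }
      anc_seq_rows[[fp$site_id]] <- data.frame(
        tf = fp$tf_name, site_id = fp$site_id,
        stringsAsFactors = FALSE)
    }
    sp_cols <- spacer_columns(crm, crm_tfbs)
    if (length(sp_cols)) {
      v <- call_variants(crm$mel_haplotypes, crm$sim_haplotypes,
                         crm$species_seqs, columns = sp_cols,
                         site_id = paste0(crm_id, "_spacer"))
      if (nrow(v)) {
        v$motif_pos <- NA_integer_
        v$crm_id <- crm_id
        v$tf_name <- NA_character_
        v$context <- "spacer"
        var_rows[[length(var_rows) + 1L]] <- v
      }
    }
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  # --- presence / turnover -------------------------------------------
  presence <- if (!is.null(scores) && nrow(scores)) {
    ok <- !is.na(scores$score_anc) & !is.na(scores$score_sim)
    for (id in scores$site_id[!ok]) note("presence", id, "unscoreable")
    call_presence(scores[ok, , drop = FALSE], cutoff_mode = cutoff_mode)
  } else NULL
  rates <- if (!is.null(presence) && nrow(presence))
    turnover_rates(presence$event) else NULL
  # --- polarize + affinity classes -----------------------------------
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    empty_variant_frame()
  if (nrow(variants)) {
    variants <- polarize_variants(variants)
    for (i in which(variants$lineage == "unpolarized"))
      note("polarize", paste0(variants$site_id[i], ":", variants$column[i]),
           variants$reason[i])
    variants$delta <- NA_real_
    variants$class <- ifelse(variants$context == "spacer", "spacer",
                             NA_character_)
    core_rows <- which(variants$context == "tfbs" &
                         variants$lineage %in% c("mel", "sim"))
    for (i in core_rows) {
      t <- tfbs_objs[[variants$site_id[i]]]
      p <- data$pwms[[variants$tf_name[i]]]
      af <- .variant_affinity(p, t$strand, variants$motif_pos[i],
                              variants$ancestral_base[i],
                              variants$derived_base[i], tau)
      variants$delta[i] <- af$delta
      variants$class[i] <- paste0("affinity_",
                                  switch(af$class,
                                         increasing = "increasing",
                                         decreasing = "decreasing",
                                         "uncertain"))
      if (af$class == "uncertain")
        note("affinity", paste0(variants$site_id[i], ":",
                                variants$column[i]), "uncertain_delta")
    }
    variants$anc_score <- if (!is.null(scores))
      scores$score_anc[match(variants$site_id, scores$site_id)] else
      NA_real_
  }
  # --- MK tables ------------------------------------------------------
  mk_classes <- c("affinity_increasing", "affinity_decreasing", "spacer")
  usable <- variants[!is.na(variants$kind) &
                       variants$lineage %in% c("mel", "sim") &
                       variants$class %in% mk_classes, , drop = FALSE]
  mk <- list(); mk_tests <- list()
  for (lin in c("mel", "sim")) {
    vl <- usable[usable$lineage == lin, , drop = FALSE]
    if (lin == "sim" && !is.null(anc_score_min))
      vl <- vl[vl$context == "spacer" |
                 (!is.na(vl$anc_score) & vl$anc_score >= anc_score_min), ,
               drop = FALSE]
    mk[[lin]] <- build_mk_table(vl, freq_cutoff = freq_cutoff,
                                reference_class = reference_class,
                                classes = mk_classes)
    mk_tests[[lin]] <- lapply(
      setdiff(mk_classes, reference_class),
      function(cl) mk_test(mk[[lin]], cl))
    names(mk_tests[[lin]]) <- setdiff(mk_classes, reference_class)
  }
  # --- mutational input -----------------------------------------------
  anc_sites <- do.call(rbind, lapply(names(tfbs_objs), function(id) {
    t <- tfbs_objs[[id]]
    if (!isTRUE(t$pass_filters)) return(NULL)
    sc <- scores[scores$site_id == id, ]
    anc <- .ancestral_core(t)
    if (is.na(anc) || grepl("[^ACGT]", anc)) return(NULL)
    data.frame(tf = t$tf_name,
               sequence = if (t$strand == "+") anc else revcomp(anc),
               stringsAsFactors = FALSE)
  }))
  mut_probs <- if (!is.null(anc_sites) && nrow(anc_sites))
    mutational_probabilities(data$pwms, anc_sites,
                             m = data$mutation_matrix, tau = tau) else NULL
  sim_seg <- usable[usable$lineage == "sim" & usable$kind == "segregating", ]
  observed <- c(increase = sum(sim_seg$class == "affinity_increasing"),
                decrease = sum(sim_seg$class == "affinity_decreasing"))
  mut_input <- if (!is.null(mut_probs) && sum(observed) > 0)
    mutational_input_test(observed,
                          mut_probs[c("increase", "decrease")],
                          reps = mk_reps) else NULL
  # --- SFS ------------------------------------------------------------
  sfs_out <- list()
  mel_seg <- variants[!is.na(variants$kind) & variants$lineage == "mel" &
                        variants$kind == "segregating", , drop = FALSE]
  for (cl in c("affinity_increasing", "affinity_decreasing", "spacer")) {
    vv <- mel_seg[mel_seg$class %in% cl, , drop = FALSE]
    if (!nrow(vv)) next
    s <- build_sfs(vv$derived_count, vv$sample_size, target = target_n,
                   class_label = cl)
    if (attr(s, "n_dropped_low_coverage") > 0)
      note("sfs", cl, sprintf("low_coverage_x%d",
                              attr(s, "n_dropped_low_coverage")))
    sfs_out[[cl]] <- s
  }
  # --- ascertainment f estimate ---------------------------------------
  f_est <- NULL
  if (!is.null(scores) && nrow(scores)) {
    fp_scores <- data.frame(tf = scores$tf_name, score = scores$score_mel,
                            stringsAsFactors = FALSE)
    core_v <- variants[variants$context == "tfbs" &
                         variants$class %in% c("affinity_increasing",
                                               "affinity_decreasing"), ,
                       drop = FALSE]
    if (nrow(core_v)) {
      base_sc <- scores$score_mel[match(core_v$site_id, scores$site_id)]
      weak <- data.frame(tf = core_v$tf_name,
                         score = base_sc + pmin(core_v$delta, 0),
                         stringsAsFactors = FALSE)
      f_est <- estimate_f(fp_scores, weak)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(stage = character(), id = character(), reason = character())
  out <- structure(list(scores = presence, turnover_rates = rates,
                        variants = variants, mk = mk, mk_tests = mk_tests,
                        mut_probs = mut_probs, mut_input_test = mut_input,
                        sfs = sfs_out, f_estimate = f_est,
                        exclusions = exclusions,
                        params = list(tau = tau, freq_cutoff = freq_cutoff,
                                      cutoff_mode = cutoff_mode,
                                      target_n = target_n,
                                      anc_score_min = anc_score_min,
                                      reference_class = reference_class,
                                      seed = seed)),
                   class = "turnover_run")
  if (!is.null(outdir)) write_run_reports(out, outdir)
  out
}

# column-wise parsimony ancestor of a TFBS core (alignment orientation)
.ancestral_core <- function(tfbs) {
  sp <- tfbs$species_cores
  L <- nchar(sp[["mel"]])
  chars <- vapply(seq_len(L), function(k) {
    st <- vapply(SPECIES, function(x) {
      s <- sp[[x]]
      if (is.null(s) || is.na(s)) NA_character_ else substr(s, k, k)
    }, character(1))
    a <- infer_ancestor(st)
    if (identical(a, "ambiguous")) "N" else a
  }, character(1))
  paste(chars, collapse = "")
}

#' @export
print.turnover_run <- function(x, ...) {
  cat("Turnover pipeline run\n")
  if (!is.null(x$scores))
    cat(" ", nrow(x$scores), "TFBS scored;",
        sum(x$exclusions$stage == "extract"), "excluded at extraction\n")
  if (!is.null(x$turnover_rates))
    cat(sprintf("  total turnover: %.2f%%\n",
                x$turnover_rates[["total_turnover"]]))
  cat(" ", nrow(x$variants), "variant sites (",
      sum(x$variants$lineage %in% c("mel", "sim"), na.rm = TRUE),
      "polarized )\n")
  if (!is.null(x$mut_input_test))
    cat(sprintf("  mutational-input test p = %.4g\n",
                x$mut_input_test$p.value))
  invisible(x)
}

#' Write TSV/JSON reports for a pipeline run
#'
#' @param run a `turnover_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_reports <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(run$scores)) wt(run$scores, "presence.tsv")
  if (nrow(run$variants)) wt(run$variants, "variants.tsv")
  for (lin in names(run$mk)) wt(run$mk[[lin]], paste0("mk_", lin, ".tsv"))
  wt(run$exclusions, "exclusions.tsv")
  summary <- list(turnover_rates = as.list(run$turnover_rates),
                  mut_probs = if (!is.null(run$mut_probs))
                    as.list(unclass(run$mut_probs)) else NULL,
                  mut_input_p = if (!is.null(run$mut_input_test))
                    run$mut_input_test$p.value else NULL,
                  mk_tests = lapply(run$mk_tests, function(l)
                    lapply(l, `[[`, "p.value")),
                  pooled_f = if (!is.null(run$f_estimate))
                    attr(run$f_estimate, "pooled_f") else NULL,
                  params = run$params[setdiff(names(run$params), "")])
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
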