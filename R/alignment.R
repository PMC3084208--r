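SPECIES <- c("mel", "sim", "sec", "yak", "ere")
GAPCHARS <- c("-", "N")

#' CRM alignment container
#'
#' Holds one cis-regulatory module's multiple alignment: the five species
#' reference sequences (mel, sim, sec, yak, ere) plus population haplotypes
#' for mel and sim.  All sequences share one column frame; gaps are `-` and
#' missing data is `N`.  Haplotype coverage masks are derived from those
#' characters.
#'
#' @param crm_id CRM identifier.
#' @param species_seqs named character vector of aligned sequences; names
#'   must include "mel" (outgroups may be absent, in which case the CRM is
#'   flagged unpolarizable).
#' @param mel_haplotypes,sim_haplotypes character vectors of aligned
#'   population haplotypes (may be empty).
#' @param coords optional reference interval c(start, end), 1-based closed.
#' @return object of class `crm_alignment`.
#' @export
crm_alignment <- function(crm_id, species_seqs, mel_haplotypes = character(),
                          sim_haplotypes = character(), coords = NULL) {
  species_seqs <- toupper(species_seqs)
  mel_haplotypes <- unname(toupper(mel_haplotypes))
  sim_haplotypes <- unname(toupper(sim_haplotypes))
  if (!"mel" %in% names(species_seqs))
    stop("CRM ", crm_id, ": mel reference sequence is required")
  lens <- nchar(c(species_seqs, mel_haplotypes, sim_haplotypes))
  if (length(unique(lens)) != 1L)
    stop("CRM ", crm_id, ": aligned sequences differ in length (",
         paste(unique(lens), collapse = ","), ")")
  missing_og <- setdiff(SPECIES, names(species_seqs))
  if (length(missing_og))
    warning("CRM ", crm_id, ": missing species ",
            paste(missing_og, collapse = ","),
            "; polarization may be unavailable")
  structure(list(crm_id = crm_id, species_seqs = species_seqs,
                 mel_haplotypes = mel_haplotypes,
                 sim_haplotypes = sim_haplotypes,
                 coords = coords,
                 polarizable = all(c("sec", "yak", "ere") %in%
                                     names(species_seqs))),
            class = "crm_alignment")
}

#' @export
print.crm_alignment <- function(x, ...) {
  cat("CRM", x$crm_id, "-", nchar(x$species_seqs[["mel"]]), "columns;",
      length(x$species_seqs), "species,",
      length(x$mel_haplotypes), "mel +", length(x$sim_haplotypes),
      "sim haplotypes\n")
  invisible(x)
}

#' Read a CRM alignment from FASTA
#'
#' One FASTA per CRM.  Record naming convention: species records are named
#' `mel`, `sim`, `sec`, `yak`, `ere`; population haplotypes are named
#' `mel_hap_<i>` and `sim_hap_<i>` (any suffix after `mel_hap`/`sim_hap`
#' works).  All records must be aligned to equal length.
#'
#' @param path FASTA file path.
#' @param crm_id CRM identifier; defaults to the file name stem.
#' @return a `crm_alignment`.
#' @export
read_crm_alignment <- function(path, crm_id = NULL) {
  if (is.null(crm_id)) crm_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  nm <- sub("\\s.*$", "", names(seqs))
  is_mel_hap <- grepl("^mel_hap", nm)
  is_sim_hap <- grepl("^sim_hap", nm)
  is_sp <- nm %in% SPECIES
  unknown <- nm[!(is_mel_hap | is_sim_hap | is_sp)]
  if (length(unknown))
    warning("CRM ", crm_id, ": ignoring unrecognized records ",
            paste(unknown, collapse = ","))
  sp <- seqs[is_sp]; names(sp) <- nm[is_sp]
  crm_alignment(crm_id, sp, seqs[is_mel_hap], seqs[is_sim_hap])
}

#' Write a CRM alignment to FASTA
#'
#' Inverse of [read_crm_alignment()]: species records first, then
#' `mel_hap_<i>` and `sim_hap_<i>` records.
#'
#' @param x a `crm_alignment`.
#' @param path output file path.
#' @export
write_crm_alignment <- function(x, path) {
  seqs <- c(x$species_seqs,
            stats::setNames(x$mel_haplotypes,
                            if (length(x$mel_haplotypes))
                              paste0("mel_hap_", seq_along(x$mel_haplotypes))
                            else character()),
            stats::setNames(x$sim_haplotypes,
                            if (length(x$sim_haplotypes))
                              paste0("sim_hap_", seq_along(x$sim_haplotypes))
                            else character()))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read and stitch a UCSC MAF alignment into a CRM alignment
#'
#' Minimal UCSC-dialect MAF support: `a` lines open a block, `s` lines give
#' `src start size strand srcSize text`.  The species label is the `src`
#' prefix before the first dot.  Blocks are stitched in file order; a
#' species absent from a block is padded with `N` over that block's columns.
#'
#' @param path MAF file path.
#' @param crm_id CRM identifier; defaults to the file name stem.
#' @return a `crm_alignment` (species records only).
#' @export
read_maf_alignment <- function(path, crm_id = NULL) {
  if (is.null(crm_id)) crm_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  blocks <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- character()
    } else if (grepl("^s ", ln)) {
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(toks) < 7L) stop("malformed MAF s-line: ", ln)
      sp <- sub("\\..*$", "", toks[2L])
      cur[sp] <- toupper(toks[7L])
    }
  }
  if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (!length(blocks)) stop("no alignment blocks in ", path)
  all_sp <- unique(unlist(lapply(blocks, names)))
  stitched <- vapply(all_sp, function(sp) {
    paste(vapply(blocks, function(b) {
      w <- nchar(b[[1L]])
      if (sp %in% names(b)) b[[sp]] else strrep("N", w)
    }, character(1)), collapse = "")
  }, character(1))
  crm_alignment(crm_id, stitched)
}

#' Read a BED-like footprint table
#'
#' Five-column TSV: crm_id, tf_name, start, end, site_id.  Input intervals
#' are 0-based half-open (BED convention) and are converted to the 1-based
#' closed intervals used throughout the package.  Coordinates are in the
#' ungapped mel reference frame of the CRM.
#'
#' @param path TSV path (no header, or a header line starting with `#`).
#' @return data.frame with columns crm_id, tf_name, start, end, site_id
#'   (1-based closed).
#' @export
read_footprints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("footprint table needs 5 columns")
  names(df)[1:5] <- c("crm_id", "tf_name", "start", "end", "site_id")
  df$start <- df$start + 1L          # 0-based half-open -> 1-based closed
  if (any(df$end < df$start)) stop("footprint with end < start")
  df[1:5]
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# map ungapped mel reference positions to alignment columns
mel_ref_columns <- function(crm) {
  which(!(split_chars(crm$species_seqs[["mel"]]) %in% "-"))
}

#' Extract a TFBS alignment for one footprint
#'
#' Searches the footprint region plus `flank` bases on each end of the
#' ungapped mel reference for the highest-scoring motif match (both
#' strands), then cuts the matched columns out of every species and
#' haplotype sequence.  Sites whose mel or sim sequences (reference or any
#' haplotype) contain an alignment gap in the core are failed with reason
#' `"indel"`; cores that would extend past the CRM fail with reason
#' `"edge"`.
#'
#' @param crm a `crm_alignment`.
#' @param footprint one-row data.frame as from [read_footprints()].
#' @param pwm the `pwm` for the footprint's TF.
#' @param flank bases added to each side of the footprint before the motif
#'   search (default 5).
#' @return object of class `tfbs_alignment` with elements `site_id`,
#'   `tf_name`, `core_columns` (alignment columns), `core_start` (1-based
#'   mel reference), `strand`, `score_mel`, `species_cores`,
#'   `mel_hap_cores`, `sim_hap_cores`, `pass_filters`, `fail_reason`.
#' @export
extract_tfbs <- function(crm, footprint, pwm, flank = 5L) {
  L <- pwm_length(pwm)
  ref_cols <- mel_ref_columns(crm)
  n_ref <- length(ref_cols)
  lo <- max(1L, footprint$start - flank)
  hi <- min(n_ref, footprint$end + flank)
  fail <- function(reason) {
    structure(list(site_id = footprint$site_id, tf_name = footprint$tf_name,
                   pass_filters = FALSE, fail_reason = reason),
              class = "tfbs_alignment")
  }
  if (footprint$end > n_ref || footprint$start < 1L) return(fail("edge"))
  if (hi - lo + 1L < L) return(fail("edge"))
  mel_ref <- paste(split_chars(crm$species_seqs[["mel"]])[ref_cols],
                   collapse = "")
  region <- substr(mel_ref, lo, hi)
  bm <- tryCatch(best_match(pwm, region),
                 tfbs_ambiguous_sequence = function(e) NULL)
  if (is.null(bm)) return(fail("ambiguous"))
  core_start <- lo + bm$offset - 1L          # mel reference coordinate
  core_cols <- ref_cols[core_start:(core_start + L - 1L)]
  cut_core <- function(s) paste(split_chars(s)[core_cols], collapse = "")
  sp_cores <- vapply(crm$species_seqs, cut_core, character(1))
  mel_cores <- vapply(crm$mel_haplotypes, cut_core, character(1),
                      USE.NAMES = FALSE)
  sim_cores <- vapply(crm$sim_haplotypes, cut_core, character(1),
                      USE.NAMES = FALSE)
  melsim <- c(sp_cores[names(sp_cores) %in% c("mel", "sim")],
              mel_cores, sim_cores)
  out <- structure(list(site_id = footprint$site_id,
                        tf_name = footprint$tf_name,
                        core_columns = core_cols, core_start = core_start,
                        strand = bm$strand, score_mel = bm$score,
                        species_cores = sp_cores,
                        mel_hap_cores = mel_cores, sim_hap_cores = sim_cores,
                        pass_filters = TRUE, fail_reason = NA_character_),
                   class = "tfbs_alignment")
  if (any(grepl("-", melsim, fixed = TRUE))) {
    out$pass_filters <- FALSE; out$fail_reason <- "indel"
  }
  out
}

#' @export
print.tfbs_alignment <- function(x, ...) {
  if (!isTRUE(x$pass_filters)) {
    cat("TFBS", x$site_id, "(", x$tf_name, ") FAILED:", x$fail_reason, "\n")
  } else {
    cat("TFBS", x$site_id, "(", x$tf_name, ") strand", x$strand,
        sprintf("mel score %.2f;", x$score_mel),
        length(x$mel_hap_cores), "mel +", length(x$sim_hap_cores),
        "sim haplotype cores\n")
  }
  invisible(x)
}

count_bases <- function(chars) {
  obs <- chars[chars %in% BASES]
  tab <- table(factor(obs, levels = BASES))
  as.integer(tab)
}

#' Call variant sites from aligned columns
#'
#' Scans a set of alignment columns (a TFBS core, a spacer region, or a
#' coding region) and emits one row per column that is variable within or
#' between the mel and sim samples.  A column is included when, pooling mel
#' and sim observed alleles, at least two alleles are observed or the two
#' species are fixed for different bases.  Columns are excluded (and
#' flagged) when the sim sample has fewer than `min_sim` non-missing
#' alleles, or when more than two bases are observed (tri-allelic; the
#' MK and SFS machinery assumes biallelic sites).
#'
#' @param mel_seqs,sim_seqs character vectors of aligned haplotype
#'   sequences (equal length; `-`/`N` treated as missing).
#' @param species_states named list/matrix of per-species reference bases
#'   per column, or a named character vector of aligned species sequences.
#' @param columns which columns to scan (default all).
#' @param site_id label carried into the output.
#' @param min_sim minimum non-missing sim alleles for a site (default 2).
#' @return data.frame with one row per scanned variable column: `site_id`,
#'   `column`, per-base mel and sim counts, `mel_n`, `sim_n`, species state
#'   columns, and `flag` ("ok", "triallelic", "sim_low_coverage").  Rows
#'   with flag != "ok" are reported for logging but must be excluded from
#'   downstream counts.
#' @export
call_variants <- function(mel_seqs, sim_seqs, species_states,
                          columns = NULL, site_id = NA_character_,
                          min_sim = 2L) {
  if (is.character(species_states))
    species_states <- lapply(species_states, split_chars)
  mel_mat <- if (length(mel_seqs)) do.call(rbind, lapply(mel_seqs, split_chars))
             else matrix(character(), 0, 0)
  sim_mat <- if (length(sim_seqs)) do.call(rbind, lapply(sim_seqs, split_chars))
             else matrix(character(), 0, 0)
  ncols <- length(species_states[["mel"]])
  if (is.null(columns)) columns <- seq_len(ncols)
  rows <- vector("list", length(columns))
  for (j in seq_along(columns)) {
    cc <- columns[j]
    mel_c <- if (ncol(mel_mat)) mel_mat[, cc] else character()
    sim_c <- if (ncol(sim_mat)) sim_mat[, cc] else character()
    mel_counts <- count_bases(mel_c)
    sim_counts <- count_bases(sim_c)
    mel_n <- sum(mel_counts); sim_n <- sum(sim_counts)
    obs <- BASES[(mel_counts + sim_counts) > 0]
    if (length(obs) < 2L) next                    # monomorphic/uncallable
    flag <- "ok"
    if (sim_n < min_sim) flag <- "sim_low_coverage"
    else if (length(obs) > 2L) flag <- "triallelic"
    st <- vapply(SPECIES, function(sp) {
      s <- species_states[[sp]]
      if (is.null(s)) return(NA_character_)
      b <- s[cc]
      if (b %in% BASES) b else NA_character_
    }, character(1))
    rows[[j]] <- data.frame(
      site_id = site_id, column = cc,
      mel_A = mel_counts[1], mel_C = mel_counts[2],
      mel_G = mel_counts[3], mel_T = mel_counts[4], mel_n = mel_n,
      sim_A = sim_counts[1], sim_C = sim_counts[2],
      sim_G = sim_counts[3], sim_T = sim_counts[4], sim_n = sim_n,
      mel_state = st[["mel"]], sim_state = st[["sim"]],
      sec_state = st[["sec"]], yak_state = st[["yak"]],
      ere_state = st[["ere"]], flag = flag,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(empty_variant_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_variant_frame <- function() {
  data.frame(site_id = character(), column = integer(),
             mel_A = integer(), mel_C = integer(), mel_G = integer(),
             mel_T = integer(), mel_n = integer(),
             sim_A = integer(), sim_C = integer(), sim_G = integer(),
             sim_T = integer(), sim_n = integer(),
             mel_state = character(), sim_state = character(),
             sec_state = character(), yak_state = character(),
             ere_state = character(), flag = character(),
             stringsAsFactors = FALSE)
}

#' Variant sites of a TFBS alignment
#'
#' Convenience wrapper: runs [call_variants()] over the core columns of an
#' extracted TFBS, using the haplotype core sequences.
#'
#' @param tfbs a passing `tfbs_alignment`.
#' @param min_sim minimum non-missing sim alleles per site.
#' @return variant data.frame (see [call_variants()]) with an extra
#'   `motif_pos` column giving the 1-based position within the core on the
#'   forward strand.
#' @export
tfbs_variants <- function(tfbs, min_sim = 2L) {
  stopifnot(isTRUE(tfbs$pass_filters))
  v <- call_variants(tfbs$mel_hap_cores, tfbs$sim_hap_cores,
                     tfbs$species_cores, site_id = tfbs$site_id,
                     min_sim = min_sim)
  if (nrow(v)) v$motif_pos <- v$column
  else v$motif_pos <- integer()
  v
}

#' Spacer columns of a CRM
#'
#' Columns of the mel reference frame not covered by any extracted TFBS
#' core; implements the TFBS-versus-spacer dichotomy (a column belongs to
#' at most one core).
#'
#' @param crm a `crm_alignment`.
#' @param tfbs_list list of `tfbs_alignment` objects from this CRM.
#' @return integer vector of alignment columns.
#' @export
spacer_columns <- function(crm, tfbs_list) {
  ref_cols <- mel_ref_columns(crm)
  used <- unlist(lapply(tfbs_list, function(t)
    if (isTRUE(t$pass_filters)) t$core_columns else integer()))
  setdiff(ref_cols, used)
}
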