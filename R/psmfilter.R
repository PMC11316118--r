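#' Read a Percolator-pin-style PSM table
#'
#' Tab-separated with a header; required columns `spectrum_id`, `peptide`,
#' `charge`, `score`, `proteins` (semicolon-joined database entry ids) and
#' `label` (1 for targets, -1 for decoys). Extra feature columns are
#' preserved untouched. A row is a decoy only when *all* its mapped
#' entries are decoys; mixed target/decoy mappings resolve to target.
#'
#' @param path Path to the table.
#' @return A data.frame with the required columns plus `protein_ids`
#'   (list-column of split ids) and `is_decoy`.
#' @export
read_psm_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spectrum_id", "peptide", "charge", "score", "proteins", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("PSM table lacks columns: ", paste(miss, collapse = ", "))
  tab$protein_ids <- strsplit(tab$proteins, ";", fixed = TRUE)
  tab$is_decoy <- tab$label == -1L
  tab
}

#' Target-decoy q-values
#'
#' Items are ranked by descending score; at each score threshold s the
#' estimated FDR is (1 + #decoys with score >= s) / (#targets with score
#' >= s), capped at 1, and the q-value is the running minimum of this
#' estimate taken from the permissive end of the list. Tied scores share
#' a q-value.
#'
#' @param score Numeric scores, higher is better.
#' @param is_decoy Logical, same length; at least one target required.
#' @return Numeric q-values in the input order, each in \[0, 1\] and
#'   non-increasing with score.
#' @export
qvalues_target_decoy <- function(score, is_decoy) {
  if (length(score) == 0L) stop("empty input")
  stopifnot(length(score) == length(is_decoy), !anyNA(score), !anyNA(is_decoy))
  if (!any(!is_decoy)) stop("no target items")
  ord <- order(-score)
  s <- score[ord]; d <- is_decoy[ord]
  fdr <- (1 + cumsum(d)) / pmax(cumsum(!d), 1L)
  # tied scores share the estimate at the end of the tie block
  blk <- match(s, unique(s))
  fdr <- fdr[cumsum(rle(blk)$lengths)][blk]
  fdr <- pmin(fdr, 1)
  q <- rev(cummin(rev(fdr)))
  q[order(ord)]
}

## Peptide/protein-level helper: best score per unit with decoy status.
best_by_unit <- function(unit, score, is_decoy) {
  o <- order(unit, -score)
  first <- !duplicated(unit[o])
  data.frame(unit_id = unit[o][first], best_score = score[o][first],
             is_decoy = is_decoy[o][first], stringsAsFactors = FALSE)
}

#' Picked-protein q-values
#'
#' Protein score is the maximum PSM score over the protein's peptides.
#' Each target protein competes with its reversed-sequence decoy: only
#' the higher-scoring member of the pair is retained ("picked"; ties keep
#' the target), and q-values are then computed on the picked list with
#' [qvalues_target_decoy()]. Unpaired proteins (no hit on the partner)
#' enter the list directly.
#'
#' @param psms PSM data.frame with `score`, `is_decoy` and `protein_ids`
#'   (list-column), as from [read_psm_table()].
#' @param db Database data.frame ([build_custom_db()]); used to pair
#'   decoys with their source entries.
#' @return A data.frame, one row per picked protein, with `entry_id`,
#'   `level` (`"protein"`), `best_score`, `is_decoy` and `q_value`,
#'   ordered by descending score.
#' @export
picked_protein_qvalues <- function(psms, db) {
  if (any(db$category == "decoy" & is.na(db$source_id)))
    stop("decoy entries must record their source entry")
  long_id <- unlist(psms$protein_ids)
  long_score <- rep(psms$score, lengths(psms$protein_ids))
  unknown <- setdiff(unique(long_id), db$entry_id)
  if (length(unknown))
    stop("PSMs map to entries absent from the database: ",
         paste(head(unknown, 3L), collapse = ", "))
  cat_of <- setNames(db$category, db$entry_id)
  src_of <- setNames(db$source_id, db$entry_id)
  prot <- best_by_unit(long_id, long_score, cat_of[long_id] == "decoy")
  # pair key: forward id for both members
  prot$pair <- ifelse(prot$is_decoy, src_of[prot$unit_id], prot$unit_id)
  picked <- do.call(rbind, lapply(split(prot, prot$pair), function(p) {
    if (nrow(p) == 1L) return(p)
    tgt <- p[!p$is_decoy, , drop = FALSE]
    dec <- p[p$is_decoy, , drop = FALSE]
    if (dec$best_score > tgt$best_score) dec else tgt
  }))
  q <- qvalues_target_decoy(picked$best_score, picked$is_decoy)
  out <- data.frame(entry_id = picked$unit_id, level = "protein",
                    best_score = picked$best_score, is_decoy = picked$is_decoy,
                    q_value = q, stringsAsFactors = FALSE)
  out <- out[order(-out$best_score, out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptide-level q-values
#'
#' Best PSM score per peptide sequence; a peptide is a decoy when all its
#' PSMs are decoy PSMs. Used for immunopeptidomics data, where the intact
#' peptide is the evidence unit.
#'
#' @inheritParams picked_protein_qvalues
#' @return A data.frame with `unit_id` (peptide), `level` (`"peptide"`),
#'   `best_score`, `is_decoy`, `q_value`, ordered by descending score.
#' @export
peptide_qvalues <- function(psms) {
  pep <- best_by_unit(psms$peptide, psms$score, psms$is_decoy)
  # a peptide observed in any target PSM is a target
  dec_all <- tapply(psms$is_decoy, psms$peptide, all)
  pep$is_decoy <- as.logical(dec_all[pep$unit_id])
  q <- qvalues_target_decoy(pep$best_score, pep$is_decoy)
  out <- data.frame(unit_id = pep$unit_id, level = "peptide",
                    best_score = pep$best_score, is_decoy = pep$is_decoy,
                    q_value = q, stringsAsFactors = FALSE)
  out <- out[order(-out$best_score, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grouped FDR
#'
#' Partitions identifications into microprotein and canonical groups and
#' computes q-values independently within each partition, so a small
#' novel-protein group is not penalized (or flattered) by the canonical
#' bulk. The default pipeline assesses both groups together; grouped
#' estimation is the liberal alternative.
#'
#' @inheritParams picked_protein_qvalues
#' @param grouping Named character vector mapping every forward entry id
#'   to `"microprotein"` or `"canonical"`. Defaults to category-based
#'   grouping (`predicted` entries are microproteins).
#' @param level `"protein"` (picked-protein pairing) or `"peptide"`.
#' @return A list with one scored data.frame per group.
#' @export
grouped_fdr <- function(psms, db, grouping = NULL,
                        level = c("protein", "peptide")) {
  level <- match.arg(level)
  fwd <- db[db$category != "decoy", , drop = FALSE]
  if (is.null(grouping))
    grouping <- setNames(
      ifelse(fwd$category == "predicted", "microprotein", "canonical"),
      fwd$entry_id)
  miss <- setdiff(fwd$entry_id, names(grouping))
  if (length(miss)) stop("grouping must cover every forward entry")
  src_of <- setNames(db$source_id, db$entry_id)
  group_of_entry <- function(ids) {
    fid <- ifelse(ids %in% names(grouping), ids, src_of[ids])
    unname(grouping[fid])
  }
  psm_groups <- vapply(psms$protein_ids,
                       function(ids) group_of_entry(ids)[1L], "")
  out <- lapply(split(seq_len(nrow(psms)), psm_groups), function(idx) {
    sub <- psms[idx, , drop = FALSE]
    if (level == "protein") picked_protein_qvalues(sub, db)
    else peptide_qvalues(sub)
  })
  out
}

#' Remove PSMs explained by annotated or contaminant proteins
#'
#' Drops every PSM whose peptide occurs as a substring of any annotated
#' or contaminant forward protein; PSMs mapping to one or more predicted
#' microproteins (and to no annotated protein) are retained, including
#' multi-predicted mappings. Idempotent.
#'
#' @inheritParams picked_protein_qvalues
#' @return The filtered PSM data.frame.
#' @export
filter_unannotated <- function(psms, db) {
  if (nrow(psms) == 0L) return(psms)
  anno <- db$protein[db$category %in% c("annotated", "contaminant")]
  pred <- db$protein[db$category == "predicted"]
  peps <- unique(psms$peptide)
  in_anno <- vapply(peps, function(p) any(grepl(p, anno, fixed = TRUE)), NA)
  in_pred <- vapply(peps, function(p) any(grepl(p, pred, fixed = TRUE)), NA)
  keep_pep <- peps[!in_anno & in_pred]
  out <- psms[psms$peptide %in% keep_pep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude predicted proteins perfectly contained in annotated ones
#'
#' Removes every predicted microprotein whose full sequence occurs
#' exactly (100% identity over 100% of its length, i.e. substring
#' containment) within any annotated protein.
#'
#' @param microproteins Data.frame of predicted entries (or full db; only
#'   `category == "predicted"` rows are screened).
#' @param annotated Data.frame of annotated entries, or a character
#'   vector of annotated sequences.
#' @return The microprotein data.frame with perfect matches removed.
#' @export
exclude_perfect_matches <- function(microproteins, annotated) {
  anno_seq <- if (is.data.frame(annotated)) annotated$protein else annotated
  sub <- microproteins
  is_pred <- if ("category" %in% names(sub)) sub$category == "predicted" else
    rep(TRUE, nrow(sub))
  hit <- rep(FALSE, nrow(sub))
  hit[is_pred] <- vapply(sub$protein[is_pred],
                         function(p) any(grepl(p, anno_seq, fixed = TRUE)), NA)
  out <- sub[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the second-round (re-scoring) database
#'
#' The microproteins surviving the first search are appended to the
#' reference proteome plus contaminants and fresh decoys are generated,
#' yielding a compact database whose FDR estimate is not inflated by the
#' millions of three-frame-translation entries.
#'
#' @param first_pass_hits Data.frame of predicted entries that passed the
#'   first search (all `category == "predicted"`).
#' @param reference Named character vector of annotated sequences.
#' @param contaminants Named character vector of contaminant sequences.
#' @return A database data.frame with the same contract as
#'   [build_custom_db()].
#' @export
build_rescoring_db <- function(first_pass_hits, reference,
                               contaminants = character()) {
  if (!all(first_pass_hits$category == "predicted"))
    stop("first-pass hits must all be predicted entries")
  build_custom_db(setNames(first_pass_hits$protein, first_pass_hits$entry_id),
                  reference, contaminants)
}

#' HLA class I peptide filter
#'
#' Keeps peptides with predicted binding affinity <= 100 nM, affinity
#' percentile <= 0.02 and length 7-12 residues (all bounds inclusive).
#'
#' @param peptides Data.frame with columns `sequence`, `affinity`
#'   (nM) and `percentile`.
#' @param max_affinity,max_percentile,len_range Filter bounds.
#' @return The filtered data.frame.
#' @export
hla_filter <- function(peptides, max_affinity = 100, max_percentile = 0.02,
                       len_range = c(7L, 12L)) {
  need <- c("sequence", "affinity", "percentile")
  miss <- setdiff(need, names(peptides))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  len <- nchar(peptides$sequence)
  keep <- peptides$affinity <= max_affinity &
    peptides$percentile <= max_percentile &
    len >= len_range[1L] & len <= len_range[2L]
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nonspecific digestion peptide space
#'
#' Enumerates every substring of a protein with length in
#' `[min_len, max_len]` and monoisotopic mass inside `mass_range`,
#' deduplicated — the candidate space an open/nonspecific search engine
#' considers for immunopeptidomics data.
#'
#' @param protein Amino-acid string.
#' @param min_len,max_len Length window (default 8-25 residues).
#' @param mass_range Monoisotopic mass window in Da (default 500-1500).
#' @return Character vector of unique candidate peptides.
#' @export
nonspecific_peptide_space <- function(protein, min_len = 8L, max_len = 25L,
                                      mass_range = c(500.0, 1500.0)) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  protein <- toupper(protein)
  n <- nchar(protein)
  out <- character(0)
  for (len in min_len:max_len) {
    if (len > n) break
    starts <- seq_len(n - len + 1L)
    peps <- substring(protein, starts, starts + len - 1L)
    m <- suppressWarnings(vapply(peps, function(p)
      tryCatch(monoisotopic_mass(p), error = function(e) NA_real_),
      numeric(1), USE.NAMES = FALSE))
    out <- c(out, peps[!is.na(m) & m >= mass_range[1L] & m <= mass_range[2L]])
  }
  unique(out)
}
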