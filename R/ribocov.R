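#' Read alignments from a SAM file
#'
#' Parses a SAM text file (via samtools-backed conversion) into a
#' per-alignment table. The secondary-alignment flag (0x100) is honored;
#' the number of reported alignments per read is taken from the NH tag
#' when present and otherwise inferred from the multiplicity of the read
#' id. Unmapped records are dropped. Every read must have exactly one
#' primary alignment.
#'
#' @param path Path to a SAM file with a valid header.
#' @return A data.frame with columns `read_id`, `chrom`, `strand`,
#'   `is_secondary`, `n_hits` and a list-column `blocks` of
#'   [GenomicRanges::GRanges] aligned blocks (M/=/X stretches, 1-based
#'   closed).
#' @export
read_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ".bam"),
                          overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0L)
    stop("no mapped alignments in ", path)
  blocks <- GenomicAlignments::grglist(aln)
  flag <- S4Vectors::mcols(aln)$flag
  qname <- S4Vectors::mcols(aln)$qname
  nh <- S4Vectors::mcols(aln)$NH
  is_secondary <- bitwAnd(flag, 256L) > 0L
  n_hits <- if (!is.null(nh) && !anyNA(nh)) as.integer(nh) else
    as.integer(table(qname)[qname])
  prim_per_read <- tapply(!is_secondary, qname, sum)
  if (any(prim_per_read != 1L))
    stop("reads without exactly one primary alignment: ",
         paste(head(names(prim_per_read)[prim_per_read != 1L], 3L),
               collapse = ", "))
  df <- data.frame(
    read_id = qname,
    chrom = as.character(GenomicRanges::seqnames(aln)),
    strand = as.character(GenomicRanges::strand(aln)),
    is_secondary = is_secondary,
    n_hits = n_hits,
    stringsAsFactors = FALSE)
  df$blocks <- blocks
  df
}

## Coerce a features argument (GRangesList or plain list of GRanges)
## without paying the list-conversion cost when already compressed.
as_feature_list <- function(features) {
  if (is(features, "GRangesList")) return(features)
  GenomicRanges::GRangesList(as.list(features))
}

## Flattens a features GRangesList into a single GRanges with a
## feature-index mcol, for one findOverlaps pass.
flatten_features <- function(features) {
  if (is.null(names(features)) || anyDuplicated(names(features)))
    stop("features must have unique names (smORF ids)")
  flat <- unlist(GenomicRanges::GRangesList(features), use.names = FALSE)
  flat$feature_idx <- rep(seq_along(features), lengths(features))
  flat
}

#' Count reads over smORF features under one counting regime
#'
#' Implements read assignment with the multi-mapping and ambiguity
#' switches of the four-regime analysis. Per read: if the read reports
#' more than one alignment and multi-mapping is not allowed, it is
#' unassigned (multi-mapping) outright. Otherwise each considered
#' alignment (primary only, or all alignments when multi-mapping is
#' allowed) is tested for overlap (>= `min_overlap` shared bases) with
#' the features; an alignment overlapping exactly one feature assigns
#' it, an alignment overlapping several assigns all of them only when
#' ambiguity is allowed. A read contributes at most one count per
#' feature regardless of how many of its alignments hit it. Reads whose
#' alignments touch no feature are unassigned (no features); reads
#' blocked only by ambiguity are unassigned (ambiguity).
#'
#' @param alignments Data.frame from [read_alignments()].
#' @param features Named [GenomicRanges::GRangesList] (or plain list of
#'   GRanges) of smORF genomic blocks.
#' @param allow_multi Count multi-mapping reads through all their
#'   alignments (featureCounts `-M`).
#' @param allow_ambiguous Assign reads overlapping several features to
#'   all of them (featureCounts `-O`).
#' @param min_overlap Minimum shared bases between an alignment and a
#'   feature (default 1).
#' @param stranded If `TRUE`, only same-strand overlaps count; default
#'   unstranded.
#' @return A list with `counts` (named integer vector per feature),
#'   `summary` (an `AssignmentSummary`-style data.frame with `assigned`,
#'   `unassigned_multimapping`, `unassigned_ambiguity`,
#'   `unassigned_no_features`) and `library_assigned` (number of
#'   assigned reads).
#' @export
count_reads <- function(alignments, features, allow_multi = FALSE,
                        allow_ambiguous = FALSE, min_overlap = 1L,
                        stranded = FALSE) {
  features <- as_feature_list(features)
  flat <- flatten_features(features)
  n_feat <- length(features)
  counts <- setNames(integer(n_feat), names(features))

  prim_count <- tapply(!alignments$is_secondary, alignments$read_id, sum)
  if (any(prim_count != 1L))
    stop("duplicate or missing primary alignment for some reads")

  # per-alignment feature sets via one overlap pass
  aln_blocks <- if (is(alignments$blocks, "GRangesList"))
    alignments$blocks else GenomicRanges::GRangesList(alignments$blocks)
  hits <- GenomicRanges::findOverlaps(aln_blocks, flat,
                                      ignore.strand = !stranded)
  if (min_overlap > 1L) {
    qb <- aln_blocks[S4Vectors::queryHits(hits)]
    sb <- flat[S4Vectors::subjectHits(hits)]
    ow <- vapply(seq_along(qb), function(i)
      sum(GenomicRanges::width(GenomicRanges::intersect(
        qb[[i]], GenomicRanges::granges(sb[i]),
        ignore.strand = !stranded))), numeric(1))
    hits <- hits[ow >= min_overlap]
  }
  feat_of_aln <- split(flat$feature_idx[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
  aln_feats <- vector("list", nrow(alignments))
  idx <- as.integer(names(feat_of_aln))
  aln_feats[idx] <- lapply(feat_of_aln, unique)

  assigned <- 0L; un_mm <- 0L; un_amb <- 0L; un_nf <- 0L
  by_read <- split(seq_len(nrow(alignments)), alignments$read_id)
  for (rows in by_read) {
    n_hits <- alignments$n_hits[rows[1L]]
    if (n_hits > 1L && !allow_multi) { un_mm <- un_mm + 1L; next }
    considered <- if (allow_multi) rows else rows[!alignments$is_secondary[rows]]
    fsets <- aln_feats[considered]
    touched <- unique(unlist(fsets))
    if (length(touched) == 0L) { un_nf <- un_nf + 1L; next }
    ok <- fsets[lengths(fsets) == 1L | allow_ambiguous]
    assignable <- unique(unlist(ok))
    if (length(assignable) == 0L) { un_amb <- un_amb + 1L; next }
    counts[assignable] <- counts[assignable] + 1L
    assigned <- assigned + 1L
  }
  list(counts = counts,
       summary = data.frame(assigned = assigned,
                            unassigned_multimapping = un_mm,
                            unassigned_ambiguity = un_amb,
                            unassigned_no_features = un_nf),
       library_assigned = assigned)
}

#' Reads per kilobase per million assigned reads
#'
#' @param count Raw read count(s).
#' @param feature_length_nt Feature length in nucleotides (> 0).
#' @param library_assigned Total assigned reads in the library under the
#'   same counting regime (> 0).
#' @return RPKM value(s). The log transform used for matrix export is
#'   `log10(x + 1)` and is applied only in [coverage_matrix()].
#' @export
rpkm <- function(count, feature_length_nt, library_assigned) {
  if (any(feature_length_nt <= 0)) stop("feature length must be positive")
  if (any(library_assigned <= 0)) stop("library size must be positive")
  count / ((feature_length_nt / 1e3) * (library_assigned / 1e6))
}

#' Per-smORF coverage profiles under the four counting regimes
#'
#' Runs [count_reads()] with the four switch combinations — default,
#' ambiguity allowed (`amb`), multi-mapping allowed (`mm`) and both
#' (`mm_amb`) — and computes raw counts and RPKM per smORF and regime.
#'
#' @inheritParams count_reads
#' @return A data.frame, one row per smORF: `smorf_id`, `length_nt`,
#'   `count_default`, `count_amb`, `count_mm`, `count_mm_amb` and the
#'   matching `rpkm_*` columns. The per-regime assignment summaries are
#'   attached as the `"summaries"` attribute (a named list), and
#'   per-regime assigned-read totals as `"library_assigned"`.
#' @export
coverage_profiles <- function(alignments, features, min_overlap = 1L,
                              stranded = FALSE) {
  features <- as_feature_list(features)
  regimes <- list(default = c(FALSE, FALSE), amb = c(FALSE, TRUE),
                  mm = c(TRUE, FALSE), mm_amb = c(TRUE, TRUE))
  res <- lapply(regimes, function(sw)
    count_reads(alignments, features, allow_multi = sw[1L],
                allow_ambiguous = sw[2L], min_overlap = min_overlap,
                stranded = stranded))
  len <- vapply(features, function(b) sum(GenomicRanges::width(b)), numeric(1))
  out <- data.frame(smorf_id = names(features), length_nt = unname(len),
                    stringsAsFactors = FALSE)
  lib <- vapply(res, `[[`, numeric(1), "library_assigned")
  for (rg in names(regimes)) {
    cnt <- res[[rg]]$counts
    out[[paste0("count_", rg)]] <- unname(cnt)
    out[[paste0("rpkm_", rg)]] <- if (lib[[rg]] > 0)
      unname(rpkm(cnt, len, lib[[rg]])) else 0
  }
  attr(out, "summaries") <- lapply(res, `[[`, "summary")
  attr(out, "library_assigned") <- lib
  out
}

#' Assign each smORF to a mapping group
#'
#' A smORF qualifies under a regime when that regime yields at least
#' `min_counts` raw counts. The final label is the least permissive
#' qualifying regime: `Default` beats the single-relaxation regimes,
#' which beat `MM_Amb`. When both single relaxations (`Amb`, `MM`)
#' qualify but `Default` does not, the tie is resolved by `tie`:
#' `"amb"` (default — ambiguity is the weaker relaxation, the read is
#' still uniquely placed in the genome), `"mm"`, or `"both"` which
#' labels such smORFs `MM_Amb`. No qualifying regime gives
#' `NoCoverage`.
#'
#' @param profiles Data.frame from [coverage_profiles()] (needs the four
#'   `count_*` columns).
#' @param min_counts Minimum raw counts to qualify (default 10).
#' @param tie Tie rule when `Amb` and `MM` both qualify; see above.
#' @return A data.frame with `smorf_id` and `group` in
#'   `{Default, Amb, MM, MM_Amb, NoCoverage}`.
#' @export
assign_mapping_group <- function(profiles, min_counts = 10L,
                                 tie = c("amb", "mm", "both")) {
  tie <- match.arg(tie)
  q_def <- profiles$count_default >= min_counts
  q_amb <- profiles$count_amb >= min_counts
  q_mm <- profiles$count_mm >= min_counts
  q_both <- profiles$count_mm_amb >= min_counts
  group <- rep("NoCoverage", nrow(profiles))
  group[q_both] <- "MM_Amb"
  group[q_amb & !q_mm] <- "Amb"
  group[q_mm & !q_amb] <- "MM"
  group[q_amb & q_mm] <- switch(tie, amb = "Amb", mm = "MM", both = "MM_Amb")
  group[q_def] <- "Default"
  data.frame(smorf_id = profiles$smorf_id, group = group,
             stringsAsFactors = FALSE)
}

#' smORFs detectable only through multi-mapping
#'
#' Returns the ids grouped as `MM` or `MM_Amb` that do not qualify under
#' the ambiguity-only regime — the smORFs that specifically require
#' multi-mapped reads to show any Ribo-Seq coverage.
#'
#' @inheritParams assign_mapping_group
#' @param groups Data.frame from [assign_mapping_group()].
#' @return Character vector of smORF ids.
#' @export
multimapper_exclusive_set <- function(profiles, groups, min_counts = 10L) {
  stopifnot(identical(profiles$smorf_id, groups$smorf_id))
  sel <- groups$group %in% c("MM", "MM_Amb") &
    profiles$count_amb < min_counts
  profiles$smorf_id[sel]
}

#' Coverage matrix (log RPKM) for heat-map export
#'
#' Dense smORF-by-regime matrix of `log10(RPKM + 1)`, rows ordered by
#' mapping group (Default, Amb, MM, MM_Amb, NoCoverage) and, within a
#' group, by descending `mm_amb` RPKM; deterministic under re-runs.
#'
#' @inheritParams multimapper_exclusive_set
#' @return A numeric matrix with rownames = smORF ids and columns
#'   `default`, `amb`, `mm`, `mm_amb`; the row order's group labels are
#'   attached as the `"group"` attribute.
#' @export
coverage_matrix <- function(profiles, groups = NULL, min_counts = 10L) {
  if (is.null(groups)) groups <- assign_mapping_group(profiles, min_counts)
  stopifnot(identical(profiles$smorf_id, groups$smorf_id))
  m <- log10(as.matrix(profiles[, c("rpkm_default", "rpkm_amb",
                                    "rpkm_mm", "rpkm_mm_amb")]) + 1)
  colnames(m) <- c("default", "amb", "mm", "mm_amb")
  rownames(m) <- profiles$smorf_id
  lev <- c("Default", "Amb", "MM", "MM_Amb", "NoCoverage")
  ord <- order(match(groups$group, lev), -profiles$rpkm_mm_amb,
               profiles$smorf_id)
  m <- m[ord, , drop = FALSE]
  attr(m, "group") <- groups$group[ord]
  m
}

#' Write a coverage matrix as TSV
#'
#' @param mat Matrix from [coverage_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_matrix <- function(mat, path) {
  df <- data.frame(smorf_id = rownames(mat), group = attr(mat, "group"),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
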