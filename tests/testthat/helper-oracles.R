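# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and direct table lookups only.

# ORF finder: scan every ATG, attach it to its closing stop, keep the
# most upstream ATG per inter-stop segment. Truncated ORFs run to the
# last complete codon.
oracle_orfs <- function(seq, max_aa = 150L) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  acc <- list(frame = integer(), tx_start = integer(),
              tx_end = integer(), protein = character(),
              has_stop = logical())
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    aa <- unname(gc_tab[codons])
    aa[is.na(aa)] <- "X"
    aa_str <- paste(aa, collapse = "")
    stop_idx <- which(aa == "*")
    atg_idx <- which(codons == "ATG")
    for (a in atg_idx) {
      later_stops <- stop_idx[stop_idx >= a]
      s <- if (length(later_stops)) later_stops[1L] else NA_integer_
      prev_stops <- stop_idx[stop_idx < a]
      p <- if (length(prev_stops)) max(prev_stops) else 0L
      if (any(atg_idx > p & atg_idx < a)) next   # not the most upstream
      last_cod <- if (is.na(s)) ncod else s - 1L
      prot <- substr(aa_str, a, last_cod)
      if (nchar(prot) > max_aa) next
      acc$frame <- c(acc$frame, frame)
      acc$tx_start <- c(acc$tx_start, frame + 3L * (a - 1L) + 1L)
      acc$tx_end <- c(acc$tx_end,
                      frame + 3L * last_cod + (if (is.na(s)) 0L else 3L))
      acc$protein <- c(acc$protein, prot)
      acc$has_stop <- c(acc$has_stop, !is.na(s))
    }
  }
  out <- data.frame(acc, stringsAsFactors = FALSE)
  out[order(out$frame, out$tx_start), , drop = FALSE]
}

# Trypsin peptide counter: walk the chain one residue at a time.
oracle_tryptic_count <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  n_pep <- 1L
  for (i in seq_along(res)) {
    if (i < length(res) && (res[i] == "K" || res[i] == "R") &&
        res[i + 1L] != "P")
      n_pep <- n_pep + 1L
  }
  n_pep
}

# pI by exhaustive grid search for the charge zero crossing.
oracle_pi_grid <- function(peptide, pka, step = 0.001) {
  res <- strsplit(toupper(peptide), "")[[1L]]
  ph <- seq(0, 14, by = step)
  charge <- 1 / (1 + 10^(ph - pka[["nterm"]])) -
    1 / (1 + 10^(pka[["cterm"]] - ph))
  for (a in c("K", "R", "H"))
    charge <- charge + sum(res == a) / (1 + 10^(ph - pka[[a]]))
  for (a in c("D", "E", "C", "Y"))
    charge <- charge - sum(res == a) / (1 + 10^(pka[[a]] - ph))
  ph[which.min(abs(charge))]
}

# Per-read counting enumerator: plain loops over alignments, features
# and blocks; interval overlap tested by coordinate comparison. All
# coordinates are pulled into plain vectors up front so the enumeration
# itself is scalar arithmetic.
oracle_count_reads <- function(aln, features, allow_multi,
                               allow_ambiguous) {
  feat <- lapply(features, function(g)
    list(chrom = as.character(GenomicRanges::seqnames(g)),
         start = GenomicRanges::start(g),
         end = GenomicRanges::end(g)))
  n_feat <- length(feat)
  # flatten alignment blocks once
  grl <- if (methods::is(aln$blocks, "GRangesList")) aln$blocks else
    GenomicRanges::GRangesList(as.list(aln$blocks))
  flat <- unlist(grl, use.names = FALSE)
  b_chrom <- as.character(GenomicRanges::seqnames(flat))
  b_start <- GenomicRanges::start(flat)
  b_end <- GenomicRanges::end(flat)
  b_of_row <- split(seq_along(flat),
                    factor(rep(seq_along(grl), lengths(grl)),
                           levels = seq_along(grl)))
  counts <- stats::setNames(integer(n_feat), names(feat))
  assigned <- un_mm <- un_amb <- un_nf <- 0L
  for (rows in split(seq_len(nrow(aln)), aln$read_id)) {
    if (aln$n_hits[rows[1L]] > 1L && !allow_multi) {
      un_mm <- un_mm + 1L
      next
    }
    if (!allow_multi) rows <- rows[!aln$is_secondary[rows]]
    touched <- integer(0)
    assignable <- integer(0)
    for (r in rows) {
      bidx <- b_of_row[[r]]
      hit <- integer(0)
      for (fi in seq_len(n_feat)) {
        f <- feat[[fi]]
        ov <- FALSE
        for (i in bidx)
          if (any(b_chrom[i] == f$chrom &
                  b_start[i] <= f$end & f$start <= b_end[i]))
            ov <- TRUE
        if (ov) hit <- c(hit, fi)
      }
      touched <- union(touched, hit)
      if (length(hit) == 1L || (allow_ambiguous && length(hit) >= 1L))
        assignable <- union(assignable, hit)
    }
    if (length(touched) == 0L) un_nf <- un_nf + 1L
    else if (length(assignable) == 0L) un_amb <- un_amb + 1L
    else {
      counts[assignable] <- counts[assignable] + 1L
      assigned <- assigned + 1L
    }
  }
  list(counts = counts,
       summary = c(assigned = assigned, unassigned_multimapping = un_mm,
                   unassigned_ambiguity = un_amb,
                   unassigned_no_features = un_nf))
}

# Quadratic all-pairs interval overlap counter.
oracle_overlap_count <- function(blocks, ref) {
  vapply(blocks, function(b) {
    hits <- 0L
    for (j in seq_along(ref)) {
      ov <- FALSE
      for (i in seq_along(b))
        if (as.character(GenomicRanges::seqnames(b))[i] ==
            as.character(GenomicRanges::seqnames(ref))[j] &&
            GenomicRanges::start(b)[i] <= GenomicRanges::end(ref)[j] &&
            GenomicRanges::start(ref)[j] <= GenomicRanges::end(b)[i])
          ov <- TRUE
      if (ov) hits <- hits + 1L
    }
    hits
  }, integer(1))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Empirical false-discovery proportion among accepted targets.
fdp_at <- function(q, is_decoy, is_true, threshold = 0.01) {
  acc <- !is_decoy & q <= threshold
  if (!any(acc)) return(0)
  mean(!is_true[acc])
}
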