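## Monoisotopic residue masses (Da) for the 20 canonical amino acids.
## Peptide mass = sum of residues + one water.
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

WATER_MONO_MASS <- 18.0105646863
CARBAMIDOMETHYL_MASS <- 57.021464  # fixed Cys alkylation offset, per residue

## pKa tables for pI calculation: side chains D,E,C,Y,H,K,R plus termini.
PKA_TABLES <- list(
  emboss = c(nterm = 8.6, cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  bjellqvist = c(nterm = 7.5, cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                 H = 5.98, K = 10.0, R = 12.0, Y = 10.0))

#' In silico tryptic digestion (Keil rule, zero missed cleavages)
#'
#' Cleaves after every K or R that is not followed by P. Peptides are
#' returned in order with 1-based offsets in the parent, so concatenating
#' them reconstructs the parent sequence exactly.
#'
#' @param protein Amino-acid string (canonical residues plus X).
#' @param parent_id Identifier recorded in the `parent_id` column.
#' @param compute_properties If `TRUE` (default) add `mono_mass` (Da; `NA`
#'   for peptides containing X) and `pI` columns.
#' @param pka pKa table for the pI calculation, see [isoelectric_point()].
#' @return A data.frame with columns `sequence`, `parent_id`, `start`,
#'   and optionally `mono_mass` and `pI`.
#' @export
digest_trypsin <- function(protein, parent_id = NA_character_,
                           compute_properties = TRUE,
                           pka = c("emboss", "bjellqvist")) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty string")
  protein <- toupper(protein)
  if (grepl(sprintf("[^%sX]", paste(names(RESIDUE_MONO_MASS), collapse = "")),
            protein))
    stop("protein contains non-canonical residues")
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # cleavage after position i: res[i] in {K,R} and res[i+1] != P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  peps <- substring(protein, starts, ends)
  out <- data.frame(sequence = peps, parent_id = parent_id, start = starts,
                    stringsAsFactors = FALSE)
  if (compute_properties) {
    out$mono_mass <- suppressWarnings(
      vapply(peps, function(p)
        tryCatch(monoisotopic_mass(p), error = function(e) NA_real_),
        numeric(1), USE.NAMES = FALSE))
    out$pI <- isoelectric_point(peps, pka = pka)
  }
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (18.0105646863 Da).
#' Optionally adds the fixed carbamidomethyl offset (+57.021464 Da) per
#' cysteine.
#'
#' @param peptide Amino-acid string(s), canonical residues only (X is
#'   rejected: its mass is undefined).
#' @param carbamidomethyl Add the fixed Cys modification mass.
#' @return Numeric vector of masses in Da.
#' @export
monoisotopic_mass <- function(peptide, carbamidomethyl = FALSE) {
  vapply(toupper(peptide), function(p) {
    if (!nzchar(p)) stop("empty peptide")
    res <- strsplit(p, "", fixed = TRUE)[[1L]]
    m <- RESIDUE_MONO_MASS[res]
    if (anyNA(m)) stop("unknown residue in peptide: ", p)
    mass <- sum(m) + WATER_MONO_MASS
    if (carbamidomethyl)
      mass <- mass + CARBAMIDOMETHYL_MASS * sum(res == "C")
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

## Net charge of a peptide at a given pH under a pKa table.
## Positive groups: N-terminus, K, R, H; negative: C-terminus, D, E, C, Y.
## Strictly decreasing in pH, so bisection on the root is well posed.
peptide_net_charge <- function(counts, pH, pka) {
  pos <- c(nterm = 1, counts[c("K", "R", "H")])
  pos_pka <- pka[c("nterm", "K", "R", "H")]
  neg <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
  neg_pka <- pka[c("cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - pos_pka))) - sum(neg / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point by bisection on net charge
#'
#' Solves net charge = 0 on pH in (0, 14) to a tolerance of 1e-4 pH
#' units, using the Henderson-Hasselbalch charge model over the termini
#' and the ionizable side chains D, E, C, Y, H, K, R. X residues carry no
#' charge.
#'
#' @param peptide Amino-acid string(s).
#' @param pka pKa table: `"emboss"` (default) or `"bjellqvist"`.
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values; the `pka_table` attribute records
#'   the table used.
#' @export
isoelectric_point <- function(peptide, pka = c("emboss", "bjellqvist"),
                              tol = 1e-4) {
  pka <- match.arg(pka)
  tab <- PKA_TABLES[[pka]]
  out <- vapply(toupper(peptide), function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1L]]
    counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(res == a), numeric(1))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (peptide_net_charge(counts, mid, tab) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
  attr(out, "pka_table") <- pka
  out
}

#' Unique tryptic peptide (UTP) assignment
#'
#' A peptide is a UTP when its sequence occurs as a substring of exactly
#' one forward protein in the database (decoys excluded, sequences
#' deduplicated first). Matching is substring-based, not digest-based, so
#' a homolog sharing the span disqualifies the peptide even if trypsin
#' would never release it from that homolog.
#'
#' @param peptides Character vector of peptide sequences, or the
#'   data.frame from [digest_trypsin()].
#' @param db Database data.frame ([build_custom_db()]); decoy entries are
#'   ignored.
#' @param il_equivalent Treat I and L as indistinguishable (as mass
#'   spectrometry does); default `FALSE`.
#' @return A data.frame with columns `peptide`, `parents`
#'   (semicolon-joined entry ids containing the peptide), `n_parents` and
#'   `is_utp`.
#' @export
find_utps <- function(peptides, db, il_equivalent = FALSE) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(toupper(peptides))
  fwd <- db[db$category != "decoy", , drop = FALSE]
  keep <- !duplicated(fwd$protein)
  fwd <- fwd[keep, , drop = FALSE]
  prot <- fwd$protein
  pep <- peptides
  if (il_equivalent) {
    prot <- gsub("I", "L", prot, fixed = TRUE)
    pep <- gsub("I", "L", pep, fixed = TRUE)
  }
  hits <- lapply(pep, function(p) which(grepl(p, prot, fixed = TRUE)))
  data.frame(
    peptide = peptides,
    parents = vapply(hits, function(i) paste(fwd$entry_id[i], collapse = ";"),
                     ""),
    n_parents = lengths(hits),
    is_utp = lengths(hits) == 1L,
    stringsAsFactors = FALSE)
}

#' Pooled amino-acid composition profile
#'
#' Residue frequencies pooled over a set of protein sequences and
#' normalized to sum to 1 over the 20 canonical residues plus an X
#' bucket.
#'
#' @param proteins Non-empty character vector of amino-acid strings.
#' @return Named numeric vector of relative frequencies (21 entries).
#' @export
composition_profile <- function(proteins) {
  if (length(proteins) == 0L) stop("no proteins supplied")
  alpha <- c(names(RESIDUE_MONO_MASS), "X")
  res <- strsplit(paste(toupper(proteins), collapse = ""), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), alpha)
  if (length(bad)) stop("non-canonical residues: ", paste(bad, collapse = ","))
  counts <- vapply(alpha, function(a) sum(res == a), numeric(1))
  counts / sum(counts)
}
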