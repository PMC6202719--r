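## Species identification from a short aligned mtDNA fragment.
## Input sequences are assumed co-registered to the voucher frame (same
## length, no indels); ND2 is protein-coding so this holds after any standard
## alignment step. register_offset() handles simple off-by-k inputs.

as_seq_matrix <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop_data("sequences must be character or XStringSet")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop_data("sequences must all have the same aligned length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Derive diagnostic sites from aligned voucher sequences
#'
#' Scans the alignment column by column and returns the positions where the
#' two voucher sets are reciprocally fixed for different nucleotide states.
#' `N`, gaps and IUPAC ambiguity codes carry no information: such characters
#' are ignored within a column, but a species with no unambiguous base left
#' in a column cannot be fixed there.
#'
#' @param king_vouchers,clapper_vouchers aligned sequences (character vector
#'   or [Biostrings::DNAStringSet]), all the same length, at least one per
#'   species.
#' @param expected_n if non-`NULL`, warn when the number of diagnostic sites
#'   found differs from this count (8 for the published ND2 panel).
#' @return data.frame `position` (1-based), `king_state`, `clapper_state`.
#' @export
derive_diagnostic_sites <- function(king_vouchers, clapper_vouchers,
                                    expected_n = NULL) {
  km <- as_seq_matrix(king_vouchers)
  cm <- as_seq_matrix(clapper_vouchers)
  if (ncol(km) != ncol(cm))
    stop_data("voucher sets must be aligned to the same length")
  fixed_state <- function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0 || length(unique(col)) != 1) NA_character_
    else col[1]
  }
  ks <- apply(km, 2, fixed_state)
  cs <- apply(cm, 2, fixed_state)
  diag <- which(!is.na(ks) & !is.na(cs) & ks != cs)
  sites <- data.frame(position = diag,
                      king_state = unname(ks[diag]),
                      clapper_state = unname(cs[diag]),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0)
    warning("no reciprocally fixed diagnostic sites found")
  else if (!is.null(expected_n) && nrow(sites) != expected_n)
    warning(sprintf("found %d diagnostic sites, expected %d",
                    nrow(sites), expected_n))
  sites
}

#' Classify species from diagnostic mitochondrial sites
#'
#' Each sequence is scored at the diagnostic positions; a site matching the
#' king state counts toward king, the clapper state toward clapper, and an
#' `N`, gap or third state toward neither.  A species is called when its
#' match count reaches `min_match` (default 6 of 8, the published floor set
#' by the minimum number of diagnostic alleles among voucher specimens);
#' otherwise the call is `AMBIGUOUS`.
#'
#' @param seqs sequences to classify (character vector or
#'   [Biostrings::DNAStringSet]); each must have the aligned fragment length.
#' @param sites diagnostic site table from [derive_diagnostic_sites()] or
#'   [simulate_mtdna()].
#' @param min_match minimum matches required to call a species.
#' @return data.frame `sample_id`, `species` (`KING`/`CLAPPER`/`AMBIGUOUS`),
#'   `matches_king`, `matches_clapper`, `n_scored`.
#' @export
classify_mtdna <- function(seqs, sites, min_match = 6) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs) %||% sprintf("seq%d", seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    chars <- strsplit(toupper(seqs[[i]]), "")[[1]]
    if (max(sites$position, 0) > length(chars))
      stop_data("sequence ", ids[i], " shorter than the diagnostic frame")
    obs <- chars[sites$position]
    scored <- obs %in% c("A", "C", "G", "T")
    mk <- sum(scored & obs == sites$king_state)
    mc <- sum(scored & obs == sites$clapper_state)
    if (mk >= min_match && mc >= min_match)
      stop_data("both species reach min_match at ", ids[i],
                "; min_match must exceed half the site count")
    species <- if (mk >= min_match) "KING"
               else if (mc >= min_match) "CLAPPER"
               else "AMBIGUOUS"
    data.frame(sample_id = ids[i], species = species,
               matches_king = mk, matches_clapper = mc,
               n_scored = sum(scored), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Register a sequence against a consensus by ungapped sliding offset
#'
#' For inputs that are off by a small shift relative to the voucher frame,
#' finds the offset in `-max_shift:max_shift` maximising ungapped identity to
#' the reference and returns the re-registered sequence (padded with `N`).
#' This is a convenience for co-registration only; it performs no indel-aware
#' alignment.
#'
#' @param seq a single sequence (character).
#' @param reference the consensus to register against.
#' @param max_shift largest shift considered.
#' @return list `sequence` (registered, same length as `reference`),
#'   `offset`, `identity`.
#' @export
register_offset <- function(seq, reference, max_shift = 5) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  r <- strsplit(toupper(as.character(reference)), "")[[1]]
  L <- length(r)
  best <- NULL
  for (k in -max_shift:max_shift) {
    shifted <- rep("N", L)
    src <- seq_along(s) + k         # position in reference frame
    keep <- src >= 1 & src <= L
    shifted[src[keep]] <- s[keep]
    id <- mean(shifted == r)
    if (is.null(best) || id > best$identity)
      best <- list(sequence = paste(shifted, collapse = ""),
                   offset = k, identity = id)
  }
  best
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings, exported so pipeline inputs and outputs go
#' through one code path.
#' @param path FASTA file.
#' @return `read_fasta()` returns a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
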