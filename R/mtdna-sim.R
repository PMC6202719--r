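#' Simulate mitochondrial haplotypes with diagnostic sites
#'
#' Builds a pair of species consensus haplotypes for an aligned fragment
#' (defaults emulate a 620 bp ND2 amplicon carrying 8 diagnostic sites) and
#' one sequence per individual: the maternal species' consensus plus i.i.d.
#' background substitutions at non-diagnostic sites at rate
#' `background_divergence`.  Diagnostic positions are untouched unless
#' `diagnostic_site_noise > 0`, a knob for stress-testing the match rule —
#' with the default 0, species calls are driven purely by maternal ancestry.
#'
#' @param truth cohort truth table (from [simulate_cohort()]): needs columns
#'   `sample_id` and `mtdna_species`.
#' @param fragment_length aligned fragment length in bp.
#' @param n_sites number of diagnostic sites between the two consensuses.
#' @param background_divergence per-site substitution probability at
#'   non-diagnostic positions.
#' @param diagnostic_site_noise per-site substitution probability at
#'   diagnostic positions (default 0).
#' @param seed integer seed.
#' @return list with `sequences` (named [Biostrings::DNAStringSet], one per
#'   individual), `consensus` (list `king`, `clapper` character strings) and
#'   `sites` (data.frame `position` (1-based), `king_state`, `clapper_state`).
#' @examples
#' panel <- make_panel(seed = 1)
#' sim <- simulate_cohort(panel, c(PURE_KING = 2), seed = 1)
#' mt <- simulate_mtdna(sim$truth, seed = 1)
#' mt$sites
#' @export
simulate_mtdna <- function(truth, fragment_length = 620, n_sites = 8,
                           background_divergence = 0,
                           diagnostic_site_noise = 0, seed = NULL) {
  if (n_sites > fragment_length)
    stop("`n_sites` cannot exceed `fragment_length`")
  if (background_divergence < 0 || background_divergence > 1 ||
      diagnostic_site_noise < 0 || diagnostic_site_noise > 1)
    stop("divergence rates must be probabilities")
  if (!all(c("sample_id", "mtdna_species") %in% names(truth)))
    stop_data("truth table needs `sample_id` and `mtdna_species`")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    king <- sample(bases, fragment_length, replace = TRUE)
    pos <- sort(sample.int(fragment_length, n_sites))
    clapper <- king
    clapper[pos] <- vapply(king[pos],
                           function(b) sample(setdiff(bases, b), 1L), "")
    mutate <- function(seq, at, rate) {
      if (rate > 0 && length(at) > 0) {
        hit <- at[runif(length(at)) < rate]
        seq[hit] <- vapply(seq[hit],
                           function(b) sample(setdiff(bases, b), 1L), "")
      }
      seq
    }
    nondiag <- setdiff(seq_len(fragment_length), pos)
    seqs <- vapply(truth$mtdna_species, function(sp) {
      s <- if (sp == "KING") king else clapper
      s <- mutate(s, nondiag, background_divergence)
      s <- mutate(s, pos, diagnostic_site_noise)
      paste(s, collapse = "")
    }, "")
    sequences <- Biostrings::DNAStringSet(setNames(seqs, truth$sample_id))
    list(
      sequences = sequences,
      consensus = list(king = paste(king, collapse = ""),
                       clapper = paste(clapper, collapse = "")),
      sites = data.frame(position = pos,
                         king_state = king[pos],
                         clapper_state = clapper[pos],
                         stringsAsFactors = FALSE)
    )
  })
}
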