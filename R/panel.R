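#' Build a synthetic diagnostic SNP panel
#'
#' A diagnostic panel is a set of biallelic loci whose allele frequencies
#' differ strongly between the two parental species.  Per-locus frequency
#' differentials are drawn from a normal distribution truncated to
#' `[floor, 1]`; the defaults reproduce the published panel statistics for the
#' king/clapper rail system (13 loci, mean differential 0.96, SD 0.08,
#' differential floor 0.7).  Given a drawn differential `d`, the king-allele
#' frequencies are placed symmetrically about 0.5: `p_king = 0.5 + d/2`,
#' `p_clapper = 0.5 - d/2`, which keeps both frequencies in `[0, 1]` for any
#' `d <= 1` while preserving the only reported statistic (the differential).
#'
#' @param n_loci number of loci in the panel.
#' @param mean_diff mean of the (untruncated) differential distribution.
#' @param sd_diff standard deviation of the differential distribution; `0`
#'   gives every locus exactly `mean_diff`.
#' @param floor smallest admissible differential; draws below it are rejected.
#' @param seed integer seed; the panel is deterministic given `seed`.
#' @return A `rail_panel`: a data.frame with columns `locus_id`,
#'   `king_allele`, `clapper_allele`, `p_king`, `p_clapper` (frequencies of
#'   the king-associated allele in each parental population).
#' @examples
#' panel <- make_panel(seed = 1)
#' range(panel$p_king - panel$p_clapper) # all differentials >= 0.7
#' fixed <- make_panel(n_loci = 13, mean_diff = 1, sd_diff = 0, seed = 1)
#' @export
make_panel <- function(n_loci = 13, mean_diff = 0.96, sd_diff = 0.08,
                       floor = 0.7, seed = NULL) {
  if (!is.numeric(n_loci) || n_loci < 1) stop("`n_loci` must be >= 1")
  if (!(floor > 0 && floor <= mean_diff && mean_diff <= 1))
    stop("need 0 < floor <= mean_diff <= 1")
  if (sd_diff < 0) stop("`sd_diff` must be non-negative")
  n_loci <- as.integer(n_loci)
  with_seed(seed, {
    diffs <- rtrunc_norm(n_loci, mean_diff, sd_diff, lower = floor, upper = 1)
    bases <- c("A", "C", "G", "T")
    king_allele <- sample(bases, n_loci, replace = TRUE)
    clapper_allele <- vapply(king_allele,
                             function(b) sample(setdiff(bases, b), 1L), "")
    panel <- data.frame(
      locus_id = sprintf("L%03d", seq_len(n_loci)),
      king_allele = king_allele,
      clapper_allele = unname(clapper_allele),
      p_king = 0.5 + diffs / 2,
      p_clapper = 0.5 - diffs / 2,
      stringsAsFactors = FALSE
    )
    class(panel) <- c("rail_panel", "data.frame")
    validate_panel(panel)
  })
}

## Truncated-normal sampler by rejection; exact for the narrow truncation
## windows used here (acceptance rate ~0.5 at the defaults).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate draw outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Validate a diagnostic panel
#'
#' Checks the structural invariants: unique locus ids, frequencies in
#' `[0, 1]`, distinct species alleles.
#'
#' @param panel a `rail_panel` or plain data.frame with the panel columns.
#' @return the panel, invisibly classed as `rail_panel`.
#' @export
validate_panel <- function(panel) {
  need <- c("locus_id", "king_allele", "clapper_allele", "p_king", "p_clapper")
  if (!all(need %in% names(panel)))
    stop_data("panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(panel$locus_id)) stop_data("duplicate locus_id in panel")
  if (any(panel$p_king < 0 | panel$p_king > 1 |
          panel$p_clapper < 0 | panel$p_clapper > 1))
    stop_data("panel frequencies must lie in [0, 1]")
  if (any(panel$king_allele == panel$clapper_allele))
    stop_data("king and clapper alleles must differ at every locus")
  if (!inherits(panel, "rail_panel"))
    class(panel) <- c("rail_panel", class(panel))
  panel
}

## TRUE when every locus has a fixed difference (p_king = 1, p_clapper = 0):
## the hybrid-index MLE then has the exact closed form used by hybrid_index().
is_fixed_panel <- function(panel) {
  all(panel$p_king == 1) && all(panel$p_clapper == 0)
}

#' Read / write a panel definition as TSV
#'
#' @param path file path.
#' @return `read_panel()` returns a validated `rail_panel`.
#' @export
read_panel <- function(path) {
  validate_panel(read_tsv(path))
}

#' @rdname read_panel
#' @param panel a `rail_panel`.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  write_tsv(as.data.frame(panel), path)
}

#' @export
print.rail_panel <- function(x, ...) {
  d <- x$p_king - x$p_clapper
  cat(sprintf("Diagnostic panel: %d loci, differential mean %.3f (range %.3f-%.3f)\n",
              nrow(x), mean(d), min(d), max(d)))
  print(as.data.frame(x), ...)
  invisible(x)
}
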