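#' Call genotypes from per-allele amplicon read counts
#'
#' Implements ratio-based GT-seq calling.  Cells with total depth below
#' `min_depth` (default 10x, the published no-score cutoff) are not scored.
#' Otherwise, with `f = count_allele1 / total` (allele 1 is the
#' king-associated allele): `f >= hom_fraction` calls homozygous king (2),
#' `f <= 1 - hom_fraction` homozygous clapper (0), `het_low <= f <= het_high`
#' heterozygous (1), and anything else is an ambiguous ratio left missing.
#' The ratio thresholds are conventions of the standard GT-seq pipeline, not
#' published values, and are exposed as arguments.
#'
#' @param counts long-form read-count data.frame (`sample_id`, `locus_id`,
#'   `count_allele1`, `count_allele2`).
#' @param min_depth minimum total reads required to score a cell.
#' @param hom_fraction minimum major-allele read fraction for a homozygous
#'   call (must exceed 0.5).
#' @param het_low,het_high read-fraction band accepted as heterozygous.
#' @return integer genotype matrix (samples x loci, `NA` = not scored), with
#'   samples and loci ordered by first appearance in `counts`.
#' @examples
#' counts <- data.frame(sample_id = "a", locus_id = c("L1", "L2"),
#'                      count_allele1 = c(5, 48), count_allele2 = c(4, 52))
#' call_genotypes(counts) # L1 unscored (9 reads), L2 heterozygous
#' @export
call_genotypes <- function(counts, min_depth = 10, hom_fraction = 0.9,
                           het_low = 0.35, het_high = 0.65) {
  validate_counts(counts)
  if (!(hom_fraction > 0.5 && hom_fraction <= 1))
    stop("`hom_fraction` must lie in (0.5, 1]")
  if (!(het_low >= 0 && het_low < het_high && het_high <= 1))
    stop("need 0 <= het_low < het_high <= 1")
  samples <- unique(counts$sample_id)
  loci <- unique(counts$locus_id)
  total <- counts$count_allele1 + counts$count_allele2
  f <- ifelse(total > 0, counts$count_allele1 / total, NA_real_)
  g <- rep(NA_integer_, nrow(counts))
  scored <- total >= min_depth
  g[scored & f >= hom_fraction] <- 2L
  g[scored & f <= 1 - hom_fraction] <- 0L
  g[scored & f >= het_low & f <= het_high] <- 1L
  geno <- matrix(NA_integer_, length(samples), length(loci),
                 dimnames = list(samples, loci))
  geno[cbind(match(counts$sample_id, samples),
             match(counts$locus_id, loci))] <- g
  geno
}

#' Per-sample missingness quality control
#'
#' Applies the two published sample filters in order: samples scored at fewer
#' than `min_scored` loci are dropped first, then samples with a missing-locus
#' fraction strictly greater than `max_missing_fraction` (default the
#' published ">30% of loci" rule).  Retained genotypes are unchanged, so the
#' filter is idempotent.
#'
#' @param genotypes integer genotype matrix.
#' @param max_missing_fraction drop samples with missingness strictly above
#'   this fraction.
#' @param min_scored drop samples scored at fewer than this many loci;
#'   `NULL` disables the filter.
#' @return list with `genotypes` (retained matrix) and `dropped`
#'   (data.frame `sample_id`, `n_scored`, `missing_fraction`, `reason`).
#' @export
sample_qc <- function(genotypes, max_missing_fraction = 0.30,
                      min_scored = 4) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0 || ncol(genotypes) == 0)
    stop_data("empty genotype matrix")
  n_scored <- rowSums(!is.na(genotypes))
  miss <- 1 - n_scored / ncol(genotypes)
  reason <- rep(NA_character_, nrow(genotypes))
  if (!is.null(min_scored))
    reason[n_scored < min_scored] <- sprintf("scored at <%d loci", min_scored)
  late <- is.na(reason) & miss > max_missing_fraction
  reason[late] <- sprintf("missing at >%g%% of loci",
                          100 * max_missing_fraction)
  drop <- !is.na(reason)
  list(
    genotypes = genotypes[!drop, , drop = FALSE],
    dropped = data.frame(sample_id = rownames(genotypes)[drop],
                         n_scored = n_scored[drop],
                         missing_fraction = miss[drop],
                         reason = reason[drop],
                         row.names = NULL,
                         stringsAsFactors = FALSE)
  )
}
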