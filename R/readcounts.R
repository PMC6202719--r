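#' Simulate GT-seq style per-allele read counts
#'
#' Emulates amplicon sequencing of a genotyped cohort.  Total depth per
#' sample-locus cell is negative binomial (mean `depth_mean`, dispersion
#' `depth_dispersion`; smaller dispersion = more overdispersed).  Given the
#' true genotype, the king-associated allele-1 read count is binomial with
#' success probability `1 - error_rate`, `0.5`, or `error_rate` for genotypes
#' 2, 1, 0 — `error_rate` is the per-read chance of reporting the wrong
#' allele.  Cells with missing genotype get depth the same way with allele
#' ratio 0.5 (whether they are scorable is the caller's concern).
#'
#' @param genotypes integer genotype matrix (samples x loci, 0/1/2/NA).
#' @param depth_mean mean total reads per sample-locus cell.
#' @param depth_dispersion negative-binomial size parameter (> 0).
#' @param error_rate per-read allele error probability, `< 0.5`.
#' @param seed integer seed.
#' @return long-form data.frame: `sample_id`, `locus_id`, `count_allele1`
#'   (king-associated), `count_allele2`.
#' @examples
#' panel <- make_panel(mean_diff = 1, sd_diff = 0, seed = 1)
#' sim <- simulate_cohort(panel, c(F1 = 2), seed = 1)
#' head(simulate_read_counts(sim$genotypes, seed = 1))
#' @export
simulate_read_counts <- function(genotypes, depth_mean = 2400,
                                 depth_dispersion = 1.5,
                                 error_rate = 0.005, seed = NULL) {
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop("depth parameters must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("`error_rate` must lie in [0, 0.5)")
  with_seed(seed, {
    n <- nrow(genotypes); L <- ncol(genotypes)
    g <- as.vector(t(genotypes))        # locus-major within sample
    total <- rnbinom(n * L, size = depth_dispersion, mu = depth_mean)
    r <- rep(0.5, n * L)
    r[!is.na(g) & g == 2L] <- 1 - error_rate
    r[!is.na(g) & g == 0L] <- error_rate
    c1 <- rbinom(n * L, total, r)
    data.frame(
      sample_id = rep(rownames(genotypes), each = L),
      locus_id = rep(colnames(genotypes), times = n),
      count_allele1 = c1,
      count_allele2 = total - c1,
      stringsAsFactors = FALSE
    )
  })
}

#' Read / write long-form read-count tables (TSV)
#'
#' Columns: `sample_id`, `locus_id`, `count_allele1`, `count_allele2`.
#' @param path file path.
#' @return `read_counts()` returns the validated data.frame.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  validate_counts(df)
}

#' @rdname read_counts
#' @param counts read-count data.frame.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  write_tsv(counts, path)
}

validate_counts <- function(counts) {
  need <- c("sample_id", "locus_id", "count_allele1", "count_allele2")
  if (!all(need %in% names(counts)))
    stop_data("read-count table must have columns: ",
              paste(need, collapse = ", "))
  if (any(counts$count_allele1 < 0) || any(counts$count_allele2 < 0))
    stop_data("read counts must be non-negative")
  if (anyDuplicated(counts[c("sample_id", "locus_id")]))
    stop_data("duplicate (sample, locus) rows in read-count table")
  counts
}
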