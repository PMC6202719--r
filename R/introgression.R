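#' Maximum-likelihood hybrid index
#'
#' The hybrid index `h` is the proportion of an individual's alleles
#' inherited from the king rail (0 = clapper, 1 = king).  It is estimated per
#' individual by maximising the allele-copy likelihood
#' `sum over scored copies of log[h * p_king(a) + (1 - h) * p_clapper(a)]`
#' given the panel's parental allele frequencies.  On a fixed-difference
#' panel the estimate equals the king-allele fraction among scored copies
#' exactly.  A 2-log-likelihood-unit support interval is reported alongside
#' the point estimate (it plays no role in classification).
#'
#' @param genotypes integer genotype matrix (samples x loci, 0/1/2/NA).
#' @param panel a `rail_panel`.
#' @return data.frame `sample_id`, `h`, `h_low`, `h_high`, `loglik`,
#'   `n_scored`; individuals with zero scored loci get `NA` and are flagged
#'   by `n_scored = 0`.
#' @examples
#' panel <- make_panel(mean_diff = 1, sd_diff = 0, seed = 1)
#' g <- matrix(1L, 1, 13, dimnames = list("f1", panel$locus_id))
#' hybrid_index(g, panel)$h # 0.5: 13 of 26 allele copies are king
#' @export
hybrid_index <- function(genotypes, panel) {
  validate_panel(panel)
  genotypes <- align_to_panel(genotypes, panel)
  per <- lapply(seq_len(nrow(genotypes)), function(i)
    mle_h(genotypes[i, ], panel$p_king, panel$p_clapper))
  data.frame(
    sample_id = rownames(genotypes),
    h = vapply(per, `[[`, numeric(1), "h"),
    h_low = vapply(per, function(x) (x$support %||% c(NA_real_, NA))[1],
                   numeric(1)),
    h_high = vapply(per, function(x) (x$support %||% c(NA, NA_real_))[2],
                    numeric(1)),
    loglik = vapply(per, `[[`, numeric(1), "loglik"),
    n_scored = vapply(per, function(x) as.integer(x$n_scored), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Interspecific heterozygosity
#'
#' The fraction of scored loci at which an individual is heterozygous, i.e.
#' carries one allele characteristic of each species (0 = all homozygous,
#' 1 = all heterozygous).  With fixed parental differences, F1 hybrids are
#' heterozygous at every locus and heterozygosity declines with each
#' backcross generation, so this statistic dates the hybridization event.
#'
#' @param genotypes integer genotype matrix (0/1/2/NA).
#' @return data.frame `sample_id`, `het`, `n_scored` (`NA` het when no locus
#'   is scored).
#' @export
interspecific_het <- function(genotypes) {
  n_scored <- rowSums(!is.na(genotypes))
  het <- rowSums(genotypes == 1L, na.rm = TRUE) / n_scored
  het[n_scored == 0] <- NA_real_
  data.frame(sample_id = rownames(genotypes), het = unname(het),
             n_scored = unname(as.integer(n_scored)),
             stringsAsFactors = FALSE)
}

#' Threshold configuration for hybrid classification
#'
#' Defaults are the published rules: F1/F2 when the hybrid index is
#' intermediate (0.25-0.75) with heterozygosity above 0.3; backcrossed when
#' the hybrid index lies in `[0.05, 0.25)` (clapper side; the king side is
#' mirrored); pure when it is below 0.05 (above 0.95 on the king side).
#'
#' @param f1f2_h_min,f1f2_h_max closed hybrid-index window for F1/F2.
#' @param f1f2_het_min heterozygosity floor (strict) for F1/F2.
#' @param backcross_max upper end of the backcross window.
#' @param pure_max hybrid-index bound (strict) for a pure call.
#' @return named list of thresholds.
#' @export
introgression_thresholds <- function(f1f2_h_min = 0.25, f1f2_h_max = 0.75,
                                     f1f2_het_min = 0.3,
                                     backcross_max = 0.25, pure_max = 0.05) {
  th <- list(f1f2_h_min = f1f2_h_min, f1f2_h_max = f1f2_h_max,
             f1f2_het_min = f1f2_het_min,
             backcross_max = backcross_max, pure_max = pure_max)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("thresholds must lie in [0, 1]")
  th
}

#' Classify an individual by hybrid index and heterozygosity
#'
#' Rules are applied in order: (1) intermediate `h` with high heterozygosity
#' is a recent (F1/F2) hybrid — the boundary `h = 0.25` belongs to this
#' window, a conservative tie-break since the published intervals overlap
#' there; (2) `h` in `[0.05, 0.25)` is backcrossed toward clapper,
#' `(0.75, 0.95]` toward king; (3) `h < 0.05` is pure clapper, `h > 0.95`
#' pure king; (4) anything left — intermediate `h` with low heterozygosity,
#' a cell no published rule covers — is `UNASSIGNED`.  King-side classes are
#' mirror images of the published clapper-side rules.  Every `(h, het)` in
#' the unit square maps to exactly one class.
#'
#' @param h hybrid index (vectorised), in `[0, 1]`; `NA` gives `UNASSIGNED`.
#' @param het interspecific heterozygosity, in `[0, 1]`.
#' @param thresholds see [introgression_thresholds()].
#' @return character vector of classes: `PURE_CLAPPER`, `BACKCROSS_CLAPPER`,
#'   `F1F2`, `BACKCROSS_KING`, `PURE_KING`, `UNASSIGNED`.
#' @examples
#' classify_hybrid(c(0.5, 0.10, 0.02, 0.5), c(1.0, 0.2, 0.0, 0.1))
#' @export
classify_hybrid <- function(h, het, thresholds = introgression_thresholds()) {
  if (length(het) == 1 && length(h) > 1) het <- rep(het, length(h))
  stopifnot(length(h) == length(het))
  ok <- !is.na(h) & !is.na(het)
  if (any(h[ok] < 0 | h[ok] > 1 | het[ok] < 0 | het[ok] > 1))
    stop("h and het must lie in [0, 1]")
  th <- thresholds
  cls <- rep("UNASSIGNED", length(h))
  bc_low <- th$pure_max                       # backcross window starts at pure bound
  f1f2 <- ok & h >= th$f1f2_h_min & h <= th$f1f2_h_max & het > th$f1f2_het_min
  cls[f1f2] <- "F1F2"
  rest <- ok & !f1f2
  cls[rest & h >= bc_low & h < th$backcross_max] <- "BACKCROSS_CLAPPER"
  cls[rest & h > 1 - th$backcross_max & h <= 1 - bc_low] <- "BACKCROSS_KING"
  cls[rest & h < th$pure_max] <- "PURE_CLAPPER"
  cls[rest & h > 1 - th$pure_max] <- "PURE_KING"
  cls
}

#' Per-individual introgression records
#'
#' Convenience wrapper joining [hybrid_index()], [interspecific_het()] and
#' [classify_hybrid()] into one table.
#'
#' @inheritParams hybrid_index
#' @param thresholds see [introgression_thresholds()].
#' @return data.frame `sample_id`, `h`, `h_low`, `h_high`, `het`, `n_scored`,
#'   `hybrid_class`.
#' @export
introgression_records <- function(genotypes, panel,
                                  thresholds = introgression_thresholds()) {
  hi <- hybrid_index(genotypes, panel)
  het <- interspecific_het(genotypes)
  data.frame(
    sample_id = hi$sample_id,
    h = hi$h, h_low = hi$h_low, h_high = hi$h_high,
    het = het$het, n_scored = hi$n_scored,
    hybrid_class = classify_hybrid(hi$h, het$het, thresholds),
    stringsAsFactors = FALSE
  )
}

#' Site-level introgression summary
#'
#' Per-site sample size, mean and sample SD of the hybrid index, mean
#' heterozygosity, F1/F2 and backcross counts, and percent backcrossed
#' (rounded to one decimal) — the schema of a standard hybrid-zone summary
#' table.
#'
#' @param records introgression records (from [introgression_records()] or
#'   equivalent) with columns `sample_id`, `h`, `het`, `hybrid_class`.
#' @param sites data.frame mapping `sample_id` to `site_id`.
#' @return data.frame `site_id`, `n`, `mean_h`, `sd_h`, `mean_het`,
#'   `n_f1f2`, `n_backcrossed`, `percent_backcrossed`.
#' @export
site_summary <- function(records, sites) {
  if (!all(c("sample_id", "site_id") %in% names(sites)))
    stop_data("sites needs columns `sample_id` and `site_id`")
  d <- merge(records, sites[c("sample_id", "site_id")], by = "sample_id")
  if (nrow(d) == 0) stop_data("no samples join to a site")
  res <- lapply(split(d, d$site_id), function(g) {
    data.frame(
      site_id = g$site_id[1],
      n = nrow(g),
      mean_h = mean(g$h, na.rm = TRUE),
      sd_h = sd(g$h, na.rm = TRUE),
      mean_het = mean(g$het, na.rm = TRUE),
      n_f1f2 = sum(g$hybrid_class == "F1F2"),
      n_backcrossed = sum(g$hybrid_class %in%
                            c("BACKCROSS_CLAPPER", "BACKCROSS_KING")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$percent_backcrossed <- round(100 * out$n_backcrossed / out$n, 1)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}

#' Cyto-nuclear discordance table
#'
#' Cross-tabulates mitochondrial species against nuclear status.  Nuclear
#' classes collapse to `pure_clapper`, `mixed` (backcrossed, F1/F2 and the
#' unassigned intermediate cell, all of which carry ancestry from both
#' species) and `pure_king`.  Mismatched combinations (e.g. king mtDNA with
#' pure clapper nuclear genome) indicate the direction of historical
#' hybridization, since mtDNA is maternally inherited.
#'
#' @param mtdna_calls data.frame from [classify_mtdna()] (`sample_id`,
#'   `species`).
#' @param records introgression records (`sample_id`, `hybrid_class`).
#' @return list with `table` (mtDNA species x nuclear status contingency
#'   table over joined samples) and `unjoined` (sample ids present in only
#'   one assay).
#' @export
cytonuclear_table <- function(mtdna_calls, records) {
  if (anyDuplicated(mtdna_calls$sample_id) || anyDuplicated(records$sample_id))
    stop_data("duplicate sample ids")
  joined <- merge(mtdna_calls[c("sample_id", "species")],
                  records[c("sample_id", "hybrid_class")], by = "sample_id")
  nuclear <- ifelse(joined$hybrid_class == "PURE_CLAPPER", "pure_clapper",
             ifelse(joined$hybrid_class == "PURE_KING", "pure_king", "mixed"))
  tab <- table(
    mtdna = factor(joined$species, c("KING", "CLAPPER", "AMBIGUOUS")),
    nuclear = factor(nuclear, c("pure_clapper", "mixed", "pure_king"))
  )
  unjoined <- union(
    setdiff(mtdna_calls$sample_id, records$sample_id),
    setdiff(records$sample_id, mtdna_calls$sample_id)
  )
  list(table = tab, unjoined = unjoined)
}

#' Triangle-plot data (heterozygosity against hybrid index)
#'
#' One row per individual with a usable hybrid index, for the classic
#' hybrid-zone triangle plot: F1s sit at the apex (h = 0.5, het = 1), pure
#' parents at the base corners, backcrosses along the edges.  Individuals
#' with missing `h` or `het` are excluded and returned separately.
#'
#' @param records introgression records.
#' @return list with `data` (data.frame `sample_id`, `h`, `het`,
#'   `hybrid_class`) and `excluded` (sample ids without estimates).
#' @export
triangle_data <- function(records) {
  keep <- !is.na(records$h) & !is.na(records$het)
  list(data = records[keep, c("sample_id", "h", "het", "hybrid_class")],
       excluded = records$sample_id[!keep])
}
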