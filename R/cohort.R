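#' Pedigree classes recognised by the cohort simulator
#'
#' Backcross generations are defined recursively as hybrid x pure parent:
#' `BC1_KING` is F1 x pure king, `BC2_KING` is BC1_KING x pure king, and so on
#' up to `depth` backcross generations (default 2, matching the class
#' vocabulary of the analysis: pure, F1, F2, backcrossed).
#'
#' @param depth number of backcross generations to include.
#' @return character vector of pedigree labels.
#' @export
pedigree_classes <- function(depth = 2) {
  stopifnot(depth >= 0)
  bc <- if (depth > 0)
    as.vector(t(outer(paste0("BC", seq_len(depth)),
                      c("_KING", "_CLAPPER"), paste0)))
  else character(0)
  c("PURE_KING", "PURE_CLAPPER", "F1", "F2", bc)
}

## Expected king-ancestry fraction for each pedigree label.
true_ancestry <- function(labels) {
  k <- function(lab) {
    if (lab == "PURE_KING") return(1)
    if (lab == "PURE_CLAPPER") return(0)
    if (lab %in% c("F1", "F2")) return(0.5)
    m <- regmatches(lab, regexec("^BC([0-9]+)_(KING|CLAPPER)$", lab))[[1]]
    if (length(m) == 0) stop_data("unknown pedigree label: ", lab)
    n <- as.integer(m[2])
    if (m[3] == "KING") 1 - 0.5^(n + 1) else 0.5^(n + 1)
  }
  vapply(labels, k, numeric(1))
}

## An individual is a list: alleles (2 x L matrix of king-allele indicators),
## mtdna ("KING"/"CLAPPER").  Pure parents are Hardy-Weinberg draws at the
## species' panel frequencies.
sim_pure <- function(panel, species) {
  p <- if (species == "KING") panel$p_king else panel$p_clapper
  list(alleles = matrix(rbinom(2L * length(p), 1L, rep(p, each = 2L)),
                        nrow = 2L),
       mtdna = species)
}

## Per-locus Mendelian gamete: one of the two allele copies, independently.
gamete <- function(ind) {
  L <- ncol(ind$alleles)
  ind$alleles[cbind(sample(1:2, L, replace = TRUE), seq_len(L))]
}

## Cross two explicit parents; the mother is chosen by a fair coin
## (recorded through the offspring's mtDNA, which is maternally inherited).
cross <- function(par_a, par_b) {
  mother_is_a <- runif(1) < 0.5
  mom <- if (mother_is_a) par_a else par_b
  dad <- if (mother_is_a) par_b else par_a
  list(alleles = rbind(gamete(mom), gamete(dad)),
       mtdna = mom$mtdna, mom = mom, dad = dad)
}

## Build one individual of the requested pedigree class, simulating its
## ancestors explicitly so Mendelian inheritance holds by construction.
sim_individual <- function(panel, label) {
  if (label == "PURE_KING") return(sim_pure(panel, "KING"))
  if (label == "PURE_CLAPPER") return(sim_pure(panel, "CLAPPER"))
  if (label == "F1")
    return(cross(sim_pure(panel, "KING"), sim_pure(panel, "CLAPPER")))
  if (label == "F2")
    return(cross(sim_individual(panel, "F1"), sim_individual(panel, "F1")))
  m <- regmatches(label, regexec("^BC([0-9]+)_(KING|CLAPPER)$", label))[[1]]
  if (length(m) == 0) stop_data("unknown pedigree label: ", label)
  n <- as.integer(m[2])
  pure <- m[3]
  hybrid <- if (n == 1L) sim_individual(panel, "F1")
            else sim_individual(panel, sprintf("BC%d_%s", n - 1L, pure))
  cross(hybrid, sim_pure(panel, pure))
}

#' Simulate a cohort of known pedigree classes
#'
#' Pure parents are drawn from Hardy-Weinberg proportions at the species'
#' panel frequencies; hybrids and backcrosses are produced by per-locus
#' Mendelian gamete sampling from explicitly simulated parents.  The mother of
#' each cross is chosen at random and her species' mitochondrial haplotype is
#' inherited, which is what later drives the cyto-nuclear discordance
#' analysis.
#'
#' @param panel a `rail_panel`.
#' @param design named integer vector or list mapping pedigree labels (see
#'   [pedigree_classes()]) to the number of individuals to simulate.
#' @param seed integer seed; output is reproducible given `seed`.
#' @param keep_parents if `TRUE`, attach each crossed individual's simulated
#'   parents (used by Mendelian-inheritance tests).
#' @return list with components
#'   `genotypes` (integer matrix, samples x loci, king-allele counts 0/1/2),
#'   `truth` (data.frame `sample_id`, `pedigree`, `true_ancestry_fraction`,
#'   `mtdna_species`), and when `keep_parents = TRUE` a `parents` list.
#' @examples
#' panel <- make_panel(mean_diff = 1, sd_diff = 0, seed = 1)
#' sim <- simulate_cohort(panel, c(F1 = 3, PURE_KING = 2), seed = 42)
#' sim$genotypes # F1s are heterozygous (1) everywhere on a fixed panel
#' @export
simulate_cohort <- function(panel, design, seed = NULL, keep_parents = FALSE) {
  validate_panel(panel)
  design <- unlist(design)
  if (length(design) == 0 || is.null(names(design)))
    stop_data("`design` must be a non-empty named vector of class counts")
  true_ancestry(names(design)) # validates labels
  if (any(design < 0) || any(design != round(design)))
    stop_data("`design` counts must be non-negative integers")
  with_seed(seed, {
    labels <- rep(names(design), times = design)
    n <- length(labels)
    if (n == 0) stop_data("`design` must request at least one individual")
    inds <- lapply(labels, function(lab) sim_individual(panel, lab))
    geno <- t(vapply(inds, function(i) colSums(i$alleles),
                     numeric(nrow(panel))))
    geno <- matrix(as.integer(geno), nrow = n,
                   dimnames = list(sprintf("S%04d", seq_len(n)),
                                   panel$locus_id))
    truth <- data.frame(
      sample_id = rownames(geno),
      pedigree = labels,
      true_ancestry_fraction = unname(true_ancestry(labels)),
      mtdna_species = vapply(inds, function(i) i$mtdna, ""),
      stringsAsFactors = FALSE
    )
    out <- list(genotypes = geno, truth = truth)
    if (keep_parents) out$parents <- inds
    out
  })
}

#' Write a genotype matrix as CSV
#'
#' Rows are samples, columns are loci, values are king-allele counts 0/1/2 or
#' `NA` for missing.
#' @param genotypes integer genotype matrix.
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes
#' @return `read_genotypes()` returns the integer matrix with sample row
#'   names.
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (any(m[!is.na(m)] < 0 | m[!is.na(m)] > 2))
    stop_data("genotypes must be 0, 1, 2 or NA")
  m
}

#' Export genotypes in STRUCTURE two-row format
#'
#' Two rows per individual; alleles coded 1 (king-associated) and 2, missing
#' as -9.  Useful for cross-checking railmix's admixture estimates with
#' external clustering software.
#'
#' @param genotypes integer genotype matrix (0/1/2/NA king-allele counts).
#' @param path output file.
#' @export
write_structure <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(genotypes), collapse = "\t"), con)
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    a1 <- ifelse(is.na(g), -9L, ifelse(g >= 1L, 1L, 2L))
    a2 <- ifelse(is.na(g), -9L, ifelse(g == 2L, 1L, 2L))
    writeLines(paste(c(rownames(genotypes)[i], a1), collapse = "\t"), con)
    writeLines(paste(c(rownames(genotypes)[i], a2), collapse = "\t"), con)
  }
  invisible(path)
}
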