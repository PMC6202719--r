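#' Build a validated pipeline configuration
#'
#' Collects input paths, thresholds and mode flags for [run_pipeline()].  All
#' published thresholds appear here with their published values as defaults.
#' Either `counts` (raw read counts, to be called) or `genotypes` (a called
#' genotype CSV; the calling stage is then skipped) must be supplied.
#'
#' @param panel path to the panel TSV (see [write_panel()]).
#' @param sites path to a TSV mapping `sample_id` to `site_id`.
#' @param counts path to a long-form read-count TSV, or `NULL`.
#' @param genotypes path to a genotype CSV, or `NULL`.
#' @param mtdna_fasta,king_vouchers,clapper_vouchers FASTA paths for sample
#'   and voucher mitochondrial fragments; all three `NULL` skips the
#'   mitochondrial stage.
#' @param outdir output directory (created if absent).
#' @param seed integer seed driving every stochastic stage.
#' @param min_depth,hom_fraction,het_low,het_high genotype-calling thresholds
#'   (see [call_genotypes()]).
#' @param max_missing_fraction,min_scored sample QC (see [sample_qc()]).
#' @param min_match,expected_mtdna_sites mitochondrial rule (see
#'   [classify_mtdna()]).
#' @param q_pure,q_admixed_low site purity rule (see [classify_sites()]).
#' @param thresholds class thresholds (see [introgression_thresholds()]).
#' @param ancestry `"em"` (unsupervised, default) or `"supervised"` (panel
#'   frequencies taken as known).
#' @param ks cluster counts compared by mean log-likelihood.
#' @param K_use cluster count used for membership output.
#' @param n_starts EM restarts per K.
#' @return a `rail_config` list.
#' @export
run_config <- function(panel, sites, counts = NULL, genotypes = NULL,
                       mtdna_fasta = NULL, king_vouchers = NULL,
                       clapper_vouchers = NULL,
                       outdir = "railmix_out", seed = 1,
                       min_depth = 10, hom_fraction = 0.9,
                       het_low = 0.35, het_high = 0.65,
                       max_missing_fraction = 0.30, min_scored = 4,
                       min_match = 6, expected_mtdna_sites = 8,
                       q_pure = 0.98, q_admixed_low = 0.50,
                       thresholds = introgression_thresholds(),
                       ancestry = c("em", "supervised"),
                       ks = 1:3, K_use = 2, n_starts = 5) {
  ancestry <- match.arg(ancestry)
  if (is.null(counts) && is.null(genotypes))
    stop_data("supply either `counts` or `genotypes`")
  if (K_use != 2)
    stop_data("K_use must be 2: downstream purity rules are two-species")
  if (!(K_use %in% ks)) stop_data("K_use must be one of ks")
  cfg <- list(panel = panel, sites = sites, counts = counts,
              genotypes = genotypes, mtdna_fasta = mtdna_fasta,
              king_vouchers = king_vouchers,
              clapper_vouchers = clapper_vouchers,
              outdir = outdir, seed = as.integer(seed),
              min_depth = min_depth, hom_fraction = hom_fraction,
              het_low = het_low, het_high = het_high,
              max_missing_fraction = max_missing_fraction,
              min_scored = min_scored, min_match = min_match,
              expected_mtdna_sites = expected_mtdna_sites,
              q_pure = q_pure, q_admixed_low = q_admixed_low,
              thresholds = thresholds, ancestry = ancestry,
              ks = ks, K_use = as.integer(K_use), n_starts = n_starts)
  for (f in c("panel", "sites", "counts", "genotypes", "mtdna_fasta",
              "king_vouchers", "clapper_vouchers"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_data("input file not found: ", cfg[[f]])
  structure(cfg, class = "rail_config")
}

#' Run the full introgression pipeline
#'
#' Executes, in order: input loading, genotype calling (skipped when called
#' genotypes are supplied), sample QC, mitochondrial species ID, admixture
#' estimation with a mean log-likelihood comparison across K, site purity
#' classification, reference-frequency selection from pooled pure sites,
#' hybrid index / heterozygosity estimation against those references, and
#' threshold classification with site summaries, a cyto-nuclear table and
#' triangle-plot data.  All stage outputs are written as TSV/CSV under
#' `config$outdir` together with a machine-readable `manifest.json` (stage,
#' parameters, output checksums; no timestamps, so identical runs produce
#' identical trees).
#'
#' @param config a `rail_config` from [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every intermediate product: `genotypes`,
#'   `qc`, `mtdna_calls`, `admixture`, `k_table`, `site_purity`,
#'   `reference_panel`, `records`, `summary`, `cytonuclear`, `triangle`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "rail_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[railmix] ", ...)
  manifest <- list()
  outputs <- character(0)
  note <- function(stage, params, files = character(0), status = "done") {
    outputs <<- union(outputs, files)
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, status = status, parameters = params,
      outputs = as.list(setNames(
        unname(tools::md5sum(files)), basename(files))))
  }
  out <- function(name) file.path(config$outdir, name)

  ## 1: load inputs ---------------------------------------------------------
  say("loading inputs")
  panel <- read_panel(config$panel)
  sites <- read_tsv(config$sites)
  if (!all(c("sample_id", "site_id") %in% names(sites)))
    stop_data("stage load_inputs: sites file needs sample_id and site_id")
  ## manifest records basenames only, so runs in different directories with
  ## the same inputs stay byte-identical
  note("load_inputs", list(panel = basename(config$panel),
                           sites = basename(config$sites)))

  ## 2: genotype calling ----------------------------------------------------
  if (!is.null(config$genotypes)) {
    say("calling stage skipped (called genotypes supplied)")
    geno <- read_genotypes(config$genotypes)
    note("genotype_calling", list(input = basename(config$genotypes)),
         status = "skipped")
  } else {
    say("calling genotypes from read counts")
    counts <- read_counts(config$counts)
    geno <- call_genotypes(counts, min_depth = config$min_depth,
                           hom_fraction = config$hom_fraction,
                           het_low = config$het_low,
                           het_high = config$het_high)
    write_genotypes(geno, out("genotypes.csv"))
    note("genotype_calling",
         list(min_depth = config$min_depth,
              hom_fraction = config$hom_fraction,
              het_low = config$het_low, het_high = config$het_high),
         out("genotypes.csv"))
  }

  ## 3: sample QC -----------------------------------------------------------
  qc <- sample_qc(geno, max_missing_fraction = config$max_missing_fraction,
                  min_scored = config$min_scored)
  say(sprintf("sample QC: %d retained, %d dropped",
              nrow(qc$genotypes), nrow(qc$dropped)))
  geno <- qc$genotypes
  if (nrow(geno) == 0) stop_data("stage sample_qc: no samples retained")
  write_tsv(qc$dropped, out("qc_dropped.tsv"))
  note("sample_qc",
       list(max_missing_fraction = config$max_missing_fraction,
            min_scored = config$min_scored),
       out("qc_dropped.tsv"))

  ## 4: mitochondrial ID ----------------------------------------------------
  mtdna_calls <- NULL
  if (!is.null(config$mtdna_fasta)) {
    say("classifying mitochondrial sequences")
    kv <- read_fasta(config$king_vouchers)
    cv <- read_fasta(config$clapper_vouchers)
    dsites <- derive_diagnostic_sites(kv, cv,
                                      expected_n = config$expected_mtdna_sites)
    mtdna_calls <- classify_mtdna(read_fasta(config$mtdna_fasta), dsites,
                                  min_match = config$min_match)
    write_tsv(mtdna_calls, out("mtdna_calls.tsv"))
    note("mtdna_id",
         list(min_match = config$min_match, n_sites = nrow(dsites)),
         out("mtdna_calls.tsv"))
  } else {
    note("mtdna_id", list(), status = "skipped")
  }

  ## 5: ancestry ------------------------------------------------------------
  anchor <- rbind(king = panel$p_king, clapper = panel$p_clapper)
  colnames(anchor) <- panel$locus_id
  if (config$ancestry == "supervised") {
    say("supervised admixture (panel frequencies fixed)")
    adm <- supervised_q(geno, panel)
    k_table <- data.frame(K = 2L, mean_loglik = adm$loglik)
  } else {
    say("unsupervised EM admixture, K = ",
        paste(config$ks, collapse = ","))
    fits <- lapply(seq_along(config$ks), function(i)
      unsupervised_em(geno, K = config$ks[i], n_starts = config$n_starts,
                      seed = child_seed(config$seed, i),
                      anchor_freqs = if (config$ks[i] == 2) anchor))
    k_table <- data.frame(
      K = config$ks,
      mean_loglik = vapply(fits, function(f)
        mean(f$start_logliks %||% f$loglik), numeric(1)))
    adm <- fits[[match(config$K_use, config$ks)]]
  }
  q_king <- adm$Q[, "king"]
  q_df <- data.frame(sample_id = rownames(adm$Q),
                     q_king = q_king, q_clapper = 1 - q_king,
                     stringsAsFactors = FALSE)
  write_tsv(q_df, out("q_matrix.tsv"))
  write_tsv(k_table, out("k_comparison.tsv"))
  write_structure(geno, out("structure_input.txt"))
  note("ancestry",
       list(mode = config$ancestry, K_use = config$K_use,
            n_starts = config$n_starts),
       c(out("q_matrix.tsv"), out("k_comparison.tsv"),
         out("structure_input.txt")))

  ## 6: site purity ---------------------------------------------------------
  site_q <- merge(q_df, sites, by = "sample_id")
  purity <- classify_sites(site_q, q_pure = config$q_pure,
                           q_admixed_low = config$q_admixed_low)
  say("site purity: ",
      paste(sprintf("%d %s", table(purity$status)[unique(purity$status)],
                    unique(purity$status)), collapse = ", "))
  write_tsv(purity, out("site_purity.tsv"))
  note("site_purity",
       list(q_pure = config$q_pure, q_admixed_low = config$q_admixed_low),
       out("site_purity.tsv"))

  ## 7: reference selection -------------------------------------------------
  ref_panel <- reference_panel(geno, panel, purity, sites)
  write_panel(ref_panel, out("reference_panel.tsv"))
  note("reference_selection", list(), out("reference_panel.tsv"))

  ## 8: hybrid index & heterozygosity ---------------------------------------
  say("estimating hybrid index and interspecific heterozygosity")
  records <- introgression_records(geno, ref_panel,
                                   thresholds = config$thresholds)
  note("hybrid_index", list(), character(0))

  ## 9: classification & summaries ------------------------------------------
  write_tsv(records, out("introgression.tsv"))
  summary <- site_summary(records, sites)
  write_tsv(summary, out("site_summary.tsv"))
  tri <- triangle_data(records)
  write_tsv(tri$data, out("triangle.tsv"))
  cyto <- NULL
  files <- c(out("introgression.tsv"), out("site_summary.tsv"),
             out("triangle.tsv"))
  if (!is.null(mtdna_calls)) {
    cyto <- cytonuclear_table(mtdna_calls, records)
    cyto_df <- as.data.frame(cyto$table, stringsAsFactors = FALSE)
    write_tsv(cyto_df, out("cytonuclear.tsv"))
    files <- c(files, out("cytonuclear.tsv"))
  }
  note("classification", config$thresholds, files)

  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(manifest), " stages, outputs in ", config$outdir)
  invisible(list(genotypes = geno, qc = qc, mtdna_calls = mtdna_calls,
                 admixture = adm, k_table = k_table, site_purity = purity,
                 reference_panel = ref_panel, records = records,
                 summary = summary, cytonuclear = cyto, triangle = tri,
                 manifest = manifest))
}

## Pool all-pure sites per species and take empirical king-allele
## frequencies as the reference panel, mirroring reference-file construction
## from clustering output; falls back to the input panel for a species with
## no pure site.
reference_panel <- function(geno, panel, purity, sites) {
  freq_for <- function(status) {
    ids <- sites$sample_id[sites$site_id %in%
                             purity$site_id[purity$status == status]]
    ids <- intersect(ids, rownames(geno))
    if (length(ids) == 0) return(NULL)
    g <- geno[ids, , drop = FALSE]
    colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  }
  pk <- freq_for("PURE_KING")
  pc <- freq_for("PURE_CLAPPER")
  if (is.null(pk)) {
    warning("no pure king site; using panel king frequencies as reference")
    pk <- panel$p_king
  }
  if (is.null(pc)) {
    warning("no pure clapper site; using panel clapper frequencies as reference")
    pc <- panel$p_clapper
  }
  ref <- panel
  ref$p_king <- unname(pk)
  ref$p_clapper <- unname(pc)
  validate_panel(ref)
}

#' Generate a self-contained demo dataset
#'
#' Writes, under `outdir`, a synthetic input set with the structure of a
#' coastal hybrid-zone survey: a 13-locus diagnostic panel (mean differential
#' 0.96), eleven sampling sites — nine pure clapper sites of varying size,
#' one pure king reference site, and two admixed focal sites with injected
#' backcrosses and one F1 — GT-seq style read counts, mitochondrial FASTA
#' for samples and vouchers, a site-membership table, and the simulation
#' truth table.
#'
#' @param seed integer seed.
#' @param outdir directory to write into (created if absent).
#' @param n_hybrids overall scale of injected admixture; `0` gives an
#'   all-pure survey.
#' @return a `rail_config` ready for [run_pipeline()], with the truth table
#'   path attached as attribute `truth`.
#' @export
make_demo <- function(seed = 1, outdir = "railmix_demo", n_hybrids = 14) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_panel(n_loci = 13, mean_diff = 0.96, sd_diff = 0.08,
                      floor = 0.7, seed = child_seed(seed, 1))
  h7 <- c(BC1_CLAPPER = max(0, round(n_hybrids * 10 / 14)),
          BC2_CLAPPER = max(0, round(n_hybrids * 3 / 14)),
          F1 = max(0, round(n_hybrids * 1 / 14)))
  site_designs <- list(
    site_01 = c(PURE_CLAPPER = 14), site_02 = c(PURE_CLAPPER = 10),
    site_03 = c(PURE_CLAPPER = 15), site_04 = c(PURE_CLAPPER = 5),
    site_05 = c(PURE_CLAPPER = 9),  site_06 = c(PURE_CLAPPER = 7),
    site_07 = c(c(PURE_CLAPPER = 30), h7[h7 > 0]),
    site_08 = c(PURE_CLAPPER = 20,
                BC1_CLAPPER = max(0, round(n_hybrids * 3 / 14))),
    site_09 = c(PURE_CLAPPER = 12), site_10 = c(PURE_CLAPPER = 8),
    site_11 = c(PURE_KING = 8)
  )
  site_designs$site_08 <- site_designs$site_08[site_designs$site_08 > 0]
  geno <- NULL; truth <- NULL; site_map <- NULL
  for (i in seq_along(site_designs)) {
    sname <- names(site_designs)[i]
    sim <- simulate_cohort(panel, site_designs[[i]],
                           seed = child_seed(seed, 10 + i))
    ids <- sprintf("%s_%02d", sname, seq_len(nrow(sim$genotypes)))
    rownames(sim$genotypes) <- ids
    sim$truth$sample_id <- ids
    geno <- rbind(geno, sim$genotypes)
    truth <- rbind(truth, sim$truth)
    site_map <- rbind(site_map,
                      data.frame(sample_id = ids, site_id = sname,
                                 stringsAsFactors = FALSE))
  }
  counts <- simulate_read_counts(geno, depth_mean = 2400,
                                 depth_dispersion = 1.5, error_rate = 0.005,
                                 seed = child_seed(seed, 2))
  ## vouchers share the consensus pair with the samples: simulate them in
  ## one mtDNA call on an extended truth table
  vouchers <- data.frame(
    sample_id = c(sprintf("KIRA_voucher_%02d", 1:5),
                  sprintf("CLRA_voucher_%02d", 1:5)),
    mtdna_species = rep(c("KING", "CLAPPER"), each = 5),
    stringsAsFactors = FALSE
  )
  mt_truth <- rbind(truth[c("sample_id", "mtdna_species")], vouchers)
  mt <- simulate_mtdna(mt_truth, background_divergence = 0.002,
                       seed = child_seed(seed, 3))
  is_voucher <- names(mt$sequences) %in% vouchers$sample_id
  p <- function(name) file.path(outdir, name)
  write_panel(panel, p("panel.tsv"))
  write_counts(counts, p("counts.tsv"))
  write_tsv(site_map, p("sites.tsv"))
  write_tsv(truth, p("truth.tsv"))
  write_fasta(mt$sequences[!is_voucher], p("mtdna.fasta"))
  write_fasta(mt$sequences[names(mt$sequences) %in%
                             vouchers$sample_id[vouchers$mtdna_species == "KING"]],
              p("king_vouchers.fasta"))
  write_fasta(mt$sequences[names(mt$sequences) %in%
                             vouchers$sample_id[vouchers$mtdna_species == "CLAPPER"]],
              p("clapper_vouchers.fasta"))
  cfg <- run_config(panel = p("panel.tsv"), sites = p("sites.tsv"),
                    counts = p("counts.tsv"), mtdna_fasta = p("mtdna.fasta"),
                    king_vouchers = p("king_vouchers.fasta"),
                    clapper_vouchers = p("clapper_vouchers.fasta"),
                    outdir = file.path(outdir, "results"),
                    seed = child_seed(seed, 4))
  attr(cfg, "truth") <- p("truth.tsv")
  cfg
}
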