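test_that("hybrid index matches the closed form on fixed panels (exhaustive)", {
  panel <- fixed_panel(4)
  vecs <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  colnames(vecs) <- panel$locus_id
  rownames(vecs) <- sprintf("v%d", seq_len(nrow(vecs)))
  storage.mode(vecs) <- "integer"
  res <- hybrid_index(vecs, panel)
  closed <- rowSums(vecs) / 8
  expect_equal(res$h, unname(closed), tolerance = 1e-9)
  ## dual route: independent numerical optimizer on an oracle likelihood
  for (i in seq_len(nrow(vecs))) {
    expect_lt(abs(res$h[i] -
                    oracle_opt_h(vecs[i, ], panel$p_king, panel$p_clapper)),
              1e-6)
  }
})

test_that("hybrid index matches a 1e-4 grid oracle on non-fixed panels", {
  panel <- validate_panel(data.frame(
    locus_id = sprintf("L%03d", 1:13), king_allele = "A",
    clapper_allele = "C", p_king = 0.95, p_clapper = 0.05,
    stringsAsFactors = FALSE))
  ## the worked example: 20 king alleles of 26
  g20 <- geno_matrix(x = c(rep(2L, 7), rep(1L, 6)))
  h <- hybrid_index(g20, panel)$h
  expect_lt(abs(h - oracle_grid_h(g20[1, ], panel$p_king, panel$p_clapper)),
            1e-4)
  ## random panels and genotypes, including missing cells
  set.seed(111)
  for (rep in 1:20) {
    p_k <- runif(6, 0.6, 1); p_c <- runif(6, 0, 0.4)
    rp <- validate_panel(data.frame(
      locus_id = sprintf("L%03d", 1:6), king_allele = "A",
      clapper_allele = "C", p_king = p_k, p_clapper = p_c,
      stringsAsFactors = FALSE))
    g <- matrix(sample(c(0:2, NA), 6, replace = TRUE), 1, 6,
                dimnames = list("x", rp$locus_id))
    if (all(is.na(g))) next
    h <- hybrid_index(g, rp)$h
    expect_lt(abs(h - oracle_grid_h(g[1, ], p_k, p_c)), 1e-4)
  }
})

test_that("support intervals bracket the estimate", {
  panel <- make_panel(seed = 112)
  sim <- simulate_cohort(panel, c(BC1_CLAPPER = 20), seed = 113)
  res <- hybrid_index(sim$genotypes, panel)
  expect_true(all(res$h_low <= res$h + 1e-9))
  expect_true(all(res$h_high >= res$h - 1e-9))
  expect_true(all(res$h_low >= 0 & res$h_high <= 1))
})

test_that("interspecific heterozygosity counts scored heterozygous loci", {
  g <- geno_matrix(
    all_het = rep(1L, 5),
    mixed = c(2L, 2L, 1L, 0L, NA),
    none_scored = rep(NA_integer_, 5)
  )
  res <- interspecific_het(g)
  expect_equal(res$het, c(1, 0.25, NA))
  expect_equal(res$n_scored, c(5L, 4L, 0L))
  ## simulated F1s on a fixed panel are 100% heterozygous
  sim <- simulate_cohort(fixed_panel(), c(F1 = 10), seed = 114)
  expect_equal(interspecific_het(sim$genotypes)$het, rep(1, 10))
})

test_that("classify_hybrid reproduces the published threshold rules", {
  expect_equal(classify_hybrid(0.5, 1.0), "F1F2")
  expect_equal(classify_hybrid(0.10, 0.2), "BACKCROSS_CLAPPER")
  expect_equal(classify_hybrid(0.02, 0.0), "PURE_CLAPPER")
  expect_equal(classify_hybrid(0.5, 0.1), "UNASSIGNED")
  ## king-side mirror
  expect_equal(classify_hybrid(0.90, 0.2), "BACKCROSS_KING")
  expect_equal(classify_hybrid(0.98, 0.0), "PURE_KING")
  ## boundary policy: h = 0.25 is F1F2 when het > 0.3, else falls through
  expect_equal(classify_hybrid(0.25, 0.5), "F1F2")
  expect_equal(classify_hybrid(0.25, 0.3), "UNASSIGNED")
  expect_equal(classify_hybrid(0.25 - 1e-9, 0.3), "BACKCROSS_CLAPPER")
  expect_equal(classify_hybrid(NA_real_, 0.5), "UNASSIGNED")
  expect_error(classify_hybrid(1.2, 0.5), "0, 1")
})

test_that("classification is total over the unit square", {
  classes <- c("PURE_CLAPPER", "BACKCROSS_CLAPPER", "F1F2",
               "BACKCROSS_KING", "PURE_KING", "UNASSIGNED")
  grid <- expand.grid(h = seq(0, 1, by = 0.01), het = seq(0, 1, by = 0.05))
  out <- classify_hybrid(grid$h, grid$het)
  expect_equal(length(out), nrow(grid))
  expect_true(all(out %in% classes))
  ## deterministic
  expect_identical(out, classify_hybrid(grid$h, grid$het))
})

test_that("site_summary reproduces hand-computed statistics", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:3), h = c(0.0, 0.1, 0.2),
    het = c(0, 0.2, 0.1),
    hybrid_class = c("PURE_CLAPPER", "BACKCROSS_CLAPPER", "PURE_CLAPPER"),
    stringsAsFactors = FALSE)
  sites <- data.frame(sample_id = rec$sample_id, site_id = "A")
  ss <- site_summary(rec, sites)
  expect_equal(ss$mean_h, 0.1)
  expect_equal(ss$sd_h, 0.1) # sample SD
  expect_equal(ss$n_backcrossed, 1)
  expect_equal(ss$percent_backcrossed, 33.3)
  ## a site of one pure individual
  one <- site_summary(rec[1, ], sites[1, ])
  expect_equal(one$percent_backcrossed, 0.0)
  expect_error(site_summary(rec, data.frame(sample_id = "zz",
                                            site_id = "A")), "join")
})

test_that("cytonuclear_table cross-tabulates joined assays", {
  mt <- data.frame(sample_id = sprintf("s%d", 1:25),
                   species = c(rep("CLAPPER", 19), rep("KING", 5), "CLAPPER"),
                   stringsAsFactors = FALSE)
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:25),
    hybrid_class = c(rep("BACKCROSS_CLAPPER", 19), "F1F2",
                     rep("PURE_CLAPPER", 4), "PURE_KING"),
    stringsAsFactors = FALSE)
  ct <- cytonuclear_table(mt, rec)
  expect_equal(ct$table["CLAPPER", "mixed"], 19)
  expect_equal(ct$table["KING", "mixed"], 1)
  expect_equal(ct$table["KING", "pure_clapper"], 4)
  expect_equal(sum(ct$table), 25)
  expect_equal(length(ct$unjoined), 0)
  ## empty join
  empty <- cytonuclear_table(mt[0, ], rec[0, ])
  expect_equal(sum(empty$table), 0)
  expect_error(cytonuclear_table(rbind(mt, mt[1, ]), rec), "duplicate")
})

test_that("F1 mothers split evenly between species (simulator truth)", {
  n <- 200
  sim <- simulate_cohort(fixed_panel(), c(F1 = n), seed = 115)
  frac_king <- mean(sim$truth$mtdna_species == "KING")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac_king - 0.5), 3 * se)
})

test_that("triangle data respects the combinatorial boundary on fixed panels", {
  panel <- fixed_panel(4)
  vecs <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  colnames(vecs) <- panel$locus_id
  rownames(vecs) <- sprintf("v%d", seq_len(nrow(vecs)))
  storage.mode(vecs) <- "integer"
  rec <- introgression_records(vecs, panel)
  tri <- triangle_data(rec)
  ## exact bound het <= 2 * min(h, 1 - h): enumeration over all 81 vectors
  expect_true(all(tri$data$het <=
                    2 * pmin(tri$data$h, 1 - tri$data$h) + 1e-12))
  ## larger simulated cohort on a 13-locus fixed panel
  sim <- simulate_cohort(fixed_panel(), c(F1 = 50, F2 = 50, BC1_CLAPPER = 50,
                                          PURE_CLAPPER = 50), seed = 116)
  rec2 <- introgression_records(sim$genotypes, fixed_panel())
  tri2 <- triangle_data(rec2)
  expect_true(all(tri2$data$het <=
                    2 * pmin(tri2$data$h, 1 - tri2$data$h) + 1e-12))
  ## records without an estimate are excluded and reported
  rec_na <- rec
  rec_na$h[1] <- NA
  tri3 <- triangle_data(rec_na)
  expect_equal(tri3$excluded, rec$sample_id[1])
  expect_equal(nrow(tri3$data), nrow(rec) - 1)
})

test_that("hybrid_index and supervised_q agree (same likelihood)", {
  set.seed(117)
  panel <- make_panel(seed = 118)
  g <- matrix(sample(c(0:2, NA), 100 * 13, replace = TRUE,
                     prob = c(0.3, 0.2, 0.4, 0.1)), 100, 13,
              dimnames = list(sprintf("s%d", 1:100), panel$locus_id))
  h <- hybrid_index(g, panel)$h
  q <- supervised_q(g, panel)$per_individual$q_king
  expect_equal(h, q, tolerance = 1e-6)
})
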