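## Independent oracles, deliberately written from scratch (scalar loops, no
## shared code with the package internals) so dual-route checks stay honest.

## Allele-copy log-likelihood for one individual, copy by copy.
oracle_loglik <- function(q, g, p_k, p_c) {
  ll <- 0
  for (j in seq_along(g)) {
    if (is.na(g[j])) next
    pk <- q * p_k[j] + (1 - q) * p_c[j]
    for (copy in 1:2) {
      is_king <- copy <= g[j]
      ll <- ll + log(if (is_king) pk else 1 - pk)
    }
  }
  ll
}

## Grid-search maximiser of the allele-copy likelihood.
oracle_grid_h <- function(g, p_k, p_c, step = 1e-4) {
  qs <- seq(0, 1, by = step)
  lls <- vapply(qs, oracle_loglik, numeric(1), g = g, p_k = p_k, p_c = p_c)
  qs[which.max(lls)]
}

## Numerical maximiser on the oracle likelihood with explicit endpoint check.
oracle_opt_h <- function(g, p_k, p_c) {
  opt <- optimize(function(q) oracle_loglik(q, g, p_k, p_c),
                  c(0, 1), maximum = TRUE, tol = 1e-10)
  cand <- c(0, opt$maximum, 1)
  lls <- vapply(cand, oracle_loglik, numeric(1), g = g, p_k = p_k, p_c = p_c)
  cand[which.max(lls)]
}

## Rejection-sampling oracle for the truncated-normal mean.
oracle_trunc_mean <- function(mean, sd, lower, upper, n = 2e5) {
  kept <- numeric(0)
  while (length(kept) < n) {
    x <- rnorm(n, mean, sd)
    kept <- c(kept, x[x >= lower & x <= upper])
  }
  kept <- kept[seq_len(n)]
  c(mean = mean(kept), sd = sd(kept))
}

## Brute-force column scan for reciprocally fixed diagnostic sites.
oracle_diag_sites <- function(king, clapper) {
  km <- do.call(rbind, strsplit(toupper(king), ""))
  cm <- do.call(rbind, strsplit(toupper(clapper), ""))
  acgt <- c("A", "C", "G", "T")
  out <- integer(0)
  for (j in seq_len(ncol(km))) {
    ks <- unique(km[, j][km[, j] %in% acgt])
    cs <- unique(cm[, j][cm[, j] %in% acgt])
    if (length(ks) == 1 && length(cs) == 1 && ks != cs)
      out <- c(out, j)
  }
  out
}

## Admixture binomial log-likelihood (K = 2), scalar loops, for the EM grid
## oracle. q: per-individual king membership; f: 2 x L cluster frequencies.
oracle_adm_loglik <- function(G, q, f) {
  ll <- 0
  for (i in seq_len(nrow(G))) for (l in seq_len(ncol(G))) {
    g <- G[i, l]
    if (is.na(g)) next
    p <- q[i] * f[1, l] + (1 - q[i]) * f[2, l]
    ll <- ll + g * log(p) + (2 - g) * log(1 - p)
  }
  ll
}

## Best achievable likelihood over a coarse exhaustive grid on (q, F) for
## K = 2 and tiny problems; q profiled per individual on a fine grid.  The
## frequency grid is coarse (default step 0.1) to stay desk-scale, which only
## lowers the bar the EM solution must clear.
oracle_adm_grid <- function(G, f_step = 0.1, q_step = 0.01) {
  L <- ncol(G); n <- nrow(G)
  fvals <- seq(f_step, 1 - f_step, by = f_step)
  fgrid <- as.matrix(expand.grid(rep(list(fvals), 2 * L)))
  qs <- seq(0, 1, by = q_step)
  best <- -Inf
  for (r in seq_len(nrow(fgrid))) {
    f <- matrix(fgrid[r, ], nrow = 2, byrow = TRUE)
    tot <- 0
    for (i in seq_len(n)) {
      ll_q <- numeric(length(qs))
      for (l in seq_len(L)) {
        g <- G[i, l]
        if (is.na(g)) next
        p <- qs * f[1, l] + (1 - qs) * f[2, l]
        ll_q <- ll_q + g * log(p) + (2 - g) * log(1 - p)
      }
      tot <- tot + max(ll_q)
    }
    if (tot > best) best <- tot
  }
  best
}

## Small fixture builders -------------------------------------------------

fixed_panel <- function(n_loci = 13) {
  validate_panel(data.frame(
    locus_id = sprintf("L%03d", seq_len(n_loci)),
    king_allele = "A", clapper_allele = "C",
    p_king = 1, p_clapper = 0, stringsAsFactors = FALSE))
}

geno_matrix <- function(..., loci = NULL) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, as.integer))
  rownames(m) <- names(rows) %||% sprintf("s%d", seq_along(rows))
  colnames(m) <- loci %||% sprintf("L%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
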