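#' Supervised admixture proportions with known parental frequencies
#'
#' Estimates each individual's king-cluster membership `q` by maximising the
#' allele-copy mixture likelihood with the two cluster allele frequencies
#' fixed at the panel's parental values (the special case of admixture
#' estimation where reference populations are known, e.g. from simulation
#' truth or pooled pure reference sites).  This optimises exactly the same
#' likelihood as [hybrid_index()], so the two agree to numerical tolerance.
#'
#' @param genotypes integer genotype matrix (samples x loci, 0/1/2/NA
#'   king-allele counts); columns must match `panel$locus_id`.
#' @param panel a `rail_panel` supplying `p_king`, `p_clapper` per locus.
#' @return A `rail_admixture` list: `Q` (samples x 2 matrix, columns `king`,
#'   `clapper`), `freqs` (2 x loci cluster frequencies), `loglik` (sum over
#'   individuals), `per_individual` (data.frame `sample_id`, `q_king`,
#'   `loglik`, `n_scored`), `K = 2`, `converged`, `n_iterations`.
#'   Individuals with zero scored loci get `NA` membership and are flagged.
#' @export
supervised_q <- function(genotypes, panel) {
  validate_panel(panel)
  genotypes <- align_to_panel(genotypes, panel)
  per <- lapply(seq_len(nrow(genotypes)), function(i)
    mle_h(genotypes[i, ], panel$p_king, panel$p_clapper))
  q <- vapply(per, `[[`, numeric(1), "h")
  per_df <- data.frame(
    sample_id = rownames(genotypes),
    q_king = q,
    loglik = vapply(per, `[[`, numeric(1), "loglik"),
    n_scored = vapply(per, function(x) as.integer(x$n_scored), integer(1)),
    stringsAsFactors = FALSE
  )
  Q <- cbind(king = q, clapper = 1 - q)
  rownames(Q) <- rownames(genotypes)
  freqs <- rbind(king = panel$p_king, clapper = panel$p_clapper)
  colnames(freqs) <- panel$locus_id
  structure(list(Q = Q, freqs = freqs,
                 loglik = sum(per_df$loglik, na.rm = TRUE),
                 per_individual = per_df, K = 2L,
                 converged = TRUE, n_iterations = 0L,
                 method = "supervised"),
            class = "rail_admixture")
}

align_to_panel <- function(genotypes, panel) {
  if (is.null(colnames(genotypes)))
    stop_data("genotype matrix must have locus column names")
  missing <- setdiff(panel$locus_id, colnames(genotypes))
  if (length(missing))
    stop_data("genotypes lack panel loci: ", paste(missing, collapse = ", "))
  genotypes[, panel$locus_id, drop = FALSE]
}

#' Unsupervised maximum-likelihood admixture (EM)
#'
#' Fits the standard K-cluster admixture model with independent cluster
#' allele frequencies: genotype `g_il ~ Binomial(2, sum_k q_ik f_kl)`.  Block
#' EM updates membership vectors `q` and cluster frequencies `f` jointly;
#' the log-likelihood ascends monotonically.  This is a deterministic
#' maximum-likelihood replacement for Bayesian MCMC clustering: at a handful
#' of strongly diagnostic loci with K = 2 the point estimates are
#' operationally interchangeable with posterior-mean memberships for the
#' 0.98 / 0.50 thresholding done downstream.
#'
#' Cluster labels are arbitrary under the likelihood (label switching);
#' when `anchor_freqs` is supplied the clusters are permuted to best match
#' those reference frequencies and take their row names.
#'
#' @param genotypes integer genotype matrix (0/1/2/NA).
#' @param K number of clusters.
#' @param tol stop when the log-likelihood gain falls below this.
#' @param max_iter iteration cap per start.
#' @param n_starts number of random restarts; the best likelihood wins
#'   (default 5, mirroring five clustering runs per K in the field protocol).
#' @param seed integer seed for the restarts.
#' @param anchor_freqs optional K x loci matrix of reference cluster
#'   frequencies (e.g. `rbind(king = panel$p_king, clapper = panel$p_clapper)`)
#'   used only to resolve label switching.
#' @return A `rail_admixture` list: `Q` (samples x K), `freqs` (K x loci),
#'   `loglik`, `loglik_trace` (best start), `K`, `converged`, `n_iterations`.
#' @export
unsupervised_em <- function(genotypes, K, tol = 1e-6, max_iter = 2000,
                            n_starts = 5, seed = NULL, anchor_freqs = NULL) {
  if (K < 1) stop("K must be >= 1")
  G <- genotypes
  if (any(rowSums(!is.na(G)) == 0))
    stop_data("every individual needs at least one scored locus")
  n <- nrow(G); L <- ncol(G)
  if (K == 1) { # closed form: q degenerate, f = observed allele frequencies
    f <- colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
    fit <- list(Q = matrix(1, n, 1, dimnames = list(rownames(G), "C1")),
                freqs = matrix(f, 1, L, dimnames = list("C1", colnames(G))),
                loglik = em_loglik(G, matrix(1, n, 1), matrix(f, 1, L)),
                loglik_trace = numeric(0), K = 1L,
                converged = TRUE, n_iterations = 0L, method = "em")
    return(structure(fit, class = "rail_admixture"))
  }
  best <- NULL
  start_lls <- numeric(n_starts)
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      fit <- em_one_start(G, K, tol, max_iter)
      start_lls[s] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  best$start_logliks <- start_lls
  best$K <- as.integer(K)
  best$method <- "em"
  dimnames(best$Q) <- list(rownames(G), paste0("C", seq_len(K)))
  dimnames(best$freqs) <- list(paste0("C", seq_len(K)), colnames(G))
  if (!is.null(anchor_freqs)) best <- anchor_labels(best, anchor_freqs)
  structure(best, class = "rail_admixture")
}

## Binomial admixture log-likelihood (binomial coefficient omitted, as is
## conventional for this model).
em_loglik <- function(G, Q, Fm) {
  P <- Q %*% Fm
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  sum(G * log(P) + (2 - G) * log(1 - P), na.rm = TRUE)
}

em_one_start <- function(G, K, tol, max_iter) {
  n <- nrow(G); L <- ncol(G)
  scored <- !is.na(G)
  G0 <- G; G0[!scored] <- 0          # masked copy for sums
  two_n_scored <- 2 * rowSums(scored)
  Q <- matrix(runif(n * K), n, K); Q <- Q / rowSums(Q)
  Fm <- matrix(runif(K * L, 0.05, 0.95), K, L)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  eps <- 1e-9
  while (it < max_iter) {
    it <- it + 1L
    P1 <- Q %*% Fm                   # P(copy = allele 1)
    P1 <- pmin(pmax(P1, eps), 1 - eps)
    P0 <- 1 - P1
    A_tot <- matrix(0, n, K)         # expected allele-1 copies from cluster k
    B_tot <- matrix(0, n, K)         # expected allele-2 copies from cluster k
    f_num <- matrix(0, K, L)
    f_den <- matrix(0, K, L)
    for (k in seq_len(K)) {
      a <- G0 * (Q[, k] * rep(Fm[k, ], each = n)) / P1 * scored
      b <- (2 - G0) * (Q[, k] * rep(1 - Fm[k, ], each = n)) / P0 * scored
      A_tot[, k] <- rowSums(a)
      B_tot[, k] <- rowSums(b)
      f_num[k, ] <- colSums(a)
      f_den[k, ] <- colSums(a + b)
    }
    Q <- (A_tot + B_tot) / two_n_scored
    Q <- pmin(pmax(Q, eps), 1)
    Q <- Q / rowSums(Q)
    Fm <- f_num / pmax(f_den, eps)
    Fm <- pmin(pmax(Fm, eps), 1 - eps)
    ll <- em_loglik(G, Q, Fm)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && is.finite(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(Q = Q, freqs = Fm, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged, n_iterations = it)
}

## Resolve label switching by matching estimated cluster frequencies to
## reference frequencies (never by Q magnitude).
anchor_labels <- function(fit, anchor_freqs) {
  K <- nrow(fit$freqs)
  if (nrow(anchor_freqs) != K || ncol(anchor_freqs) != ncol(fit$freqs))
    stop_data("anchor_freqs must be K x n_loci")
  perms <- all_perms(K)
  cost <- vapply(perms, function(p)
    sum(abs(fit$freqs[p, , drop = FALSE] - anchor_freqs)), numeric(1))
  p <- perms[[which.min(cost)]]
  fit$freqs <- fit$freqs[p, , drop = FALSE]
  fit$Q <- fit$Q[, p, drop = FALSE]
  labs <- rownames(anchor_freqs) %||% paste0("C", seq_len(K))
  rownames(fit$freqs) <- labs
  colnames(fit$Q) <- labs
  fit
}

all_perms <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K))
    for (rest in all_perms(K - 1L))
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[rest])
  out
}

#' @export
print.rail_admixture <- function(x, ...) {
  cat(sprintf("Admixture result (%s): K = %d, n = %d, logLik = %.3f, %s\n",
              x$method %||% "?", x$K, nrow(x$Q), x$loglik,
              if (isTRUE(x$converged)) sprintf("converged in %d iterations",
                                               x$n_iterations)
              else "NOT converged"))
  invisible(x)
}

#' Classify sampling sites as pure or admixed
#'
#' A site is `PURE_KING` or `PURE_CLAPPER` when every individual has
#' membership at least `q_pure` (default 0.98, the conservative cutoff set by
#' the minimum voucher membership) toward the same species.  A site is
#' `ADMIXED` when any individual's max-species membership falls in
#' `[q_admixed_low, q_pure)`, and also when all individuals pass the pure
#' cutoff but for different species (a mixed-species site cannot serve as a
#' single-species reference).  The two rules partition `[0.5, 1]`: the pure
#' rule is closed at `q_pure` and the admixed interval half-open below it.
#'
#' @param site_q data.frame with columns `site_id` and `q_king` (one row per
#'   individual).
#' @param q_pure pure-site membership cutoff.
#' @param q_admixed_low lower end of the admixed interval.
#' @return data.frame `site_id`, `n`, `status`, `min_q_max` (smallest
#'   max-species membership at the site).
#' @export
classify_sites <- function(site_q, q_pure = 0.98, q_admixed_low = 0.50) {
  if (!all(c("site_id", "q_king") %in% names(site_q)))
    stop_data("site_q needs columns `site_id` and `q_king`")
  if (nrow(site_q) == 0) stop_data("no individuals supplied")
  if (any(is.na(site_q$q_king))) stop_data("NA membership in site_q")
  res <- lapply(split(site_q, site_q$site_id), function(d) {
    q_max <- pmax(d$q_king, 1 - d$q_king)
    toward_king <- d$q_king >= 0.5
    status <- if (all(q_max >= q_pure)) {
      if (all(toward_king)) "PURE_KING"
      else if (all(!toward_king)) "PURE_CLAPPER"
      else "ADMIXED"
    } else "ADMIXED"
    data.frame(site_id = d$site_id[1], n = nrow(d), status = status,
               min_q_max = min(q_max), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}
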