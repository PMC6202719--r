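## Allele-copy mixture likelihood shared by hybrid_index() and
## supervised_q(). For an individual with genotype g (king-allele count) at a
## locus with parental king-allele frequencies p_k (king pop) and p_c
## (clapper pop), each of the g king-allele copies contributes
##   log[ h * p_k + (1 - h) * p_c ]
## and each of the (2 - g) clapper-allele copies contributes
##   log[ h * (1 - p_k) + (1 - h) * (1 - p_c) ].
## The sum over scored loci is concave in h (log of affine functions), so the
## maximiser on [0, 1] is unique.

copy_loglik <- function(h, g, p_k, p_c) {
  pk1 <- h * p_k + (1 - h) * p_c          # P(a copy is the king allele)
  pk0 <- 1 - pk1
  ll <- 0
  pos <- g > 0
  if (any(pos)) ll <- ll + sum(g[pos] * log(pk1[pos]))
  neg <- g < 2
  if (any(neg)) ll <- ll + sum((2 - g[neg]) * log(pk0[neg]))
  ll
}

## Maximise the allele-copy likelihood for one individual. Fixed-difference
## panels (p_k = 1, p_c = 0 everywhere) admit the exact closed form
## h = (king allele copies) / (scored copies); otherwise Brent search with an
## endpoint check (the optimum can sit on the boundary).
mle_h <- function(g, p_k, p_c, tol = 1e-9) {
  scored <- !is.na(g)
  g <- g[scored]; p_k <- p_k[scored]; p_c <- p_c[scored]
  n_scored <- length(g)
  if (n_scored == 0)
    return(list(h = NA_real_, loglik = NA_real_, n_scored = 0L,
                h_low = NA_real_, h_high = NA_real_))
  if (all(p_k == 1) && all(p_c == 0)) {
    h <- sum(g) / (2 * n_scored)
  } else {
    f <- function(h) copy_loglik(h, g, p_k, p_c)
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
    cand <- c(0, opt$maximum, 1)
    h <- cand[which.max(vapply(cand, f, numeric(1)))]
  }
  ll <- copy_loglik(h, g, p_k, p_c)
  list(h = h, loglik = ll, n_scored = n_scored,
       support = support_interval(h, ll, g, p_k, p_c))
}

## 2-log-likelihood-unit support interval (profile likelihood); reported for
## context, never used in classification.
support_interval <- function(h_hat, ll_hat, g, p_k, p_c, drop = 2) {
  f <- function(h) copy_loglik(h, g, p_k, p_c) - (ll_hat - drop)
  lo <- if (h_hat <= 0 || f(0) >= 0) 0
        else uniroot(f, c(0, h_hat), tol = 1e-8)$root
  hi <- if (h_hat >= 1 || f(1) >= 0) 1
        else uniroot(f, c(h_hat, 1), tol = 1e-8)$root
  c(lower = lo, upper = hi)
}
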