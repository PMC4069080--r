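# Independent oracles used across the suite.  These deliberately take a
# different route than the package implementation (recurrences, exhaustive
# path enumeration, direct normal equations).

# Levene-Haldane heterozygote distribution via the Wigginton recurrence
# P(h + 2) / P(h) = 4 * nAA(h) * naa(h) / ((h + 2) * (h + 1)),
# built upward from the minimal heterozygote count, then normalized.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      hom_rare <- (n_minor - h) / 2
      hom_common <- n - h - hom_rare
      w[i + 1] <- w[i] * 4 * hom_rare * hom_common / ((h + 2) * (h + 1))
    }
  }
  p <- w / sum(w)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Two-sided Fisher exact P for a 2x2 table via direct hypergeometric
# enumeration over the support of the first cell.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Normalized betweenness by exhaustive enumeration of all simple paths.
# adj: symmetric 0/1 matrix, n <= ~8.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  if (n < 3) return(bc)
  paths_between <- function(s, t) {
    res <- list()
    rec <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1]] <<- path
        return()
      }
      for (v in which(adj[last, ] == 1)) {
        if (!(v %in% path)) rec(c(path, v))
      }
    }
    rec(s)
    res
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- lengths(ps)
      sp <- ps[lens == min(lens)]
      cnt <- numeric(n)
      for (p in sp) {
        inner <- setdiff(p, c(s, t))
        cnt[inner] <- cnt[inner] + 1
      }
      bc <- bc + cnt / length(sp)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# OLS of y on [1, covs, x] by direct normal equations.
oracle_ols <- function(y, x, covs = NULL) {
  X <- cbind(1, covs, x)
  XtX <- crossprod(X)
  coefs <- solve(XtX, crossprod(X, y))
  res <- y - X %*% coefs
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[ncol(X), ncol(X)])
  beta <- coefs[ncol(X)]
  t <- beta / se
  list(beta = beta, t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
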