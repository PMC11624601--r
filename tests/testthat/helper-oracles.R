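# Independent brute-force oracles. These deliberately re-derive each quantity
# with the most literal possible algorithm (explicit loops, flood fill via
# igraph, closed forms) and never call the implementation they check.

# --- TFCE: explicit threshold loop + igraph flood fill ----------------------
# Integration convention mirrors the package's documented rule: full steps of
# size dh at h0 + k*dh up to the map maximum, plus a final partial step at the
# maximum itself; supra-threshold means stat >= h (within 1e-9 * dh).
oracle_tfce <- function(stat, edges, E = 0.5, H = 2, h0 = 0, dh = 0.4,
                        two_sided = TRUE) {
  enh <- function(m) {
    out <- 0 * m
    hmax <- max(m)
    if (hmax <= h0) return(out)
    K <- floor((hmax - h0) / dh + 1e-9)
    hs <- h0 + seq_len(K) * dh
    wts <- rep(dh, K)
    if (hmax > h0 + K * dh + 1e-9 * dh) {
      hs <- c(hs, hmax)
      wts <- c(wts, hmax - (h0 + K * dh))
    }
    V <- nrow(m); Tn <- ncol(m)
    for (j in seq_along(hs)) {
      h <- hs[j]
      mask <- m >= h - 1e-9 * dh
      pts <- which(mask)
      if (length(pts) == 0L) next
      idx <- matrix(0L, V, Tn); idx[pts] <- seq_along(pts)
      el <- matrix(0L, 0, 2)
      for (tt in seq_len(Tn)) {
        if (nrow(edges)) for (e in seq_len(nrow(edges))) {
          a <- edges[e, 1]; b <- edges[e, 2]
          if (mask[a, tt] && mask[b, tt])
            el <- rbind(el, c(idx[a, tt], idx[b, tt]))
        }
        if (tt < Tn) for (v in seq_len(V)) if (mask[v, tt] && mask[v, tt + 1])
          el <- rbind(el, c(idx[v, tt], idx[v, tt + 1]))
      }
      g <- igraph::make_graph(edges = as.vector(t(el)), n = length(pts),
                              directed = FALSE)
      comp <- igraph::components(g)
      sizes <- comp$csize[comp$membership]
      out[pts] <- out[pts] + wts[j] * sizes^E * h^H
    }
    out
  }
  enh(stat) - if (two_sided) enh(-stat) else 0
}

# --- partial correlation via two-stage OLS residuals ------------------------
oracle_partial_cor <- function(x, y, Z) {
  rx <- resid(lm(x ~ ., data = as.data.frame(Z)))
  ry <- resid(lm(y ~ ., data = as.data.frame(Z)))
  cor(rx, ry)
}

# --- Benjamini-Hochberg step-up by the definition ---------------------------
oracle_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# --- Mann-Whitney U by explicit pair counting -------------------------------
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# --- Pearson chi-square for a 2x2 table, textbook formula -------------------
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# --- Steiger Z for dependent overlapping correlations, direct formula -------
oracle_steiger_z <- function(r12, r13, r23, n) {
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  cz <- psi / (1 - rbar^2)^2
  (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * cz))
}
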