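# independent brute-force oracles, deliberately coded apart from the package
# implementations they check

# DUST-style score of one window, via table() over a plain loop
oracle_dust_score <- function(s) {
  k <- nchar(s) - 2L
  if (k < 2L) return(0)
  trips <- character(0)
  for (i in seq_len(k)) {
    t3 <- substr(s, i, i + 2L)
    if (!grepl("N", t3, fixed = TRUE)) trips <- c(trips, t3)
  }
  if (length(trips) < 2L) return(0)
  cnt <- as.integer(table(trips))
  sum(cnt * (cnt - 1) / 2) / (length(trips) - 1)
}

# max DUST score over every full window of the sequence
oracle_dust_max <- function(seq, window = 64L) {
  n <- nchar(seq)
  w <- min(window, n)
  scores <- vapply(0:(n - w), function(s) oracle_dust_score(substr(seq, s + 1L, s + w)),
                   numeric(1))
  max(scores)
}

# exhaustive ungapped cross-hybridization screen: every offset of every
# probe against every non-same-gene transcript. An alignment is seed-reachable
# iff it contains an exact run >= seed_length; the identity rule applies to
# seed-reachable alignments (the screen's stated definition), the exact-run
# rule to any alignment.
oracle_xhyb_flags <- function(probes, ts, seed_length = 15L,
                              flag_exact_run = 25L, flag_identity = 45L) {
  flags <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    if (probes$status[i] != "designed") next
    praw <- charToRaw(probes$sequence[i])
    plen <- length(praw)
    for (t in seq_len(nrow(ts))) {
      if (ts$gene_id[t] == probes$gene_id[i]) next
      traw <- charToRaw(ts$sequence[t])
      tlen <- length(traw)
      for (o in (-(plen - 1L)):(tlen - 1L)) {
        j0 <- max(1L, 1L - o); j1 <- min(plen, tlen - o)
        if (j1 < j0) next
        eq <- praw[j0:j1] == traw[(j0:j1) + o]
        r <- rle(eq)
        run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
        if (run >= flag_exact_run ||
            (run >= seed_length && sum(eq) >= flag_identity)) {
          flags[i] <- TRUE
          break
        }
      }
      if (flags[i]) break
    }
  }
  flags
}

# closed-form moderated t, written independently: per-feature loops,
# uniroot-based trigamma inversion
oracle_moderated_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b); G <- nrow(a)
  dg <- na + nb - 2L
  logfc <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    xa <- a[g, ]; xb <- b[g, ]
    logfc[g] <- mean(xa) - mean(xb)
    s2[g] <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / dg
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  excess <- sum((e - mean(e))^2) / (G - 1) - trigamma(dg / 2)
  if (excess > 0) {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - excess,
                              lower = 1e-8, upper = 1e8, tol = 1e-14)$root
    d0 <- 2 * half_d0
    s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2post <- (d0 * s0 + dg * s2) / (d0 + dg)
    dftot <- d0 + dg
  } else {
    s2post <- rep(exp(mean(e)), G)
    dftot <- Inf
  }
  tt <- logfc / sqrt(s2post * (1 / na + 1 / nb))
  list(logFC = logfc, t = tt, df_total = dftot,
       p = 2 * pt(-abs(tt), df = dftot))
}

# hand step-up BH
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
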