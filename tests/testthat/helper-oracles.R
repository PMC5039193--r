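# Independent brute-force oracles and fixture generators shared by the suite.
# Each oracle deliberately avoids the code path it checks.

# random non-negative symmetric weighted graph, zero diagonal, some zeros
random_graph <- function(n, density = 0.7, wmax = 1) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up), 0, wmax) * (runif(sum(up)) < density)
  w[up] <- vals
  w + t(w)
}

# strength by explicit double loop
oracle_strength <- function(w) {
  n <- nrow(w)
  cs <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) cs[i] <- cs[i] + w[i, j]
  cs
}

# clustering by exhaustive triple loop over ordered (j, k) pairs
oracle_clustering <- function(w, denominator = "degree") {
  n <- nrow(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      num <- num + (w[i, j] * w[i, k] * w[j, k])^(1 / 3)
    }
    k_i <- sum(w[i, ] > 0)
    den <- if (denominator == "degree") k_i * (k_i - 1) else {
      cs <- sum(w[i, ]); cs * (cs - 1)
    }
    cc[i] <- if (k_i < 2 || den <= 0) 0 else num / den
  }
  cc
}

# efficiency via Floyd-Warshall all-pairs shortest paths on inverse weights
oracle_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  ge <- numeric(n)
  for (i in seq_len(n)) {
    inv <- 1 / d[i, -i]
    inv[!is.finite(inv)] <- 0
    ge[i] <- sum(inv) / (n - 1)
  }
  ge
}

# classical two-way within-subject ANOVA by explicit sum-of-squares
# decomposition (cell/marginal means), independent of aov()
oracle_rm_anova <- function(tab) {
  n <- dim(tab)[1]; b <- dim(tab)[2]; cc <- dim(tab)[3]
  gm <- mean(tab)
  m_s <- apply(tab, 1, mean); m_b <- apply(tab, 2, mean)
  m_c <- apply(tab, 3, mean)
  m_sb <- apply(tab, c(1, 2), mean); m_sc <- apply(tab, c(1, 3), mean)
  m_bc <- apply(tab, c(2, 3), mean)
  ss_b <- n * cc * sum((m_b - gm)^2)
  ss_c <- n * b * sum((m_c - gm)^2)
  ss_sb <- cc * sum((m_sb - outer(m_s, m_b, "+") + gm)^2)
  ss_sc <- b * sum((m_sc - outer(m_s, m_c, "+") + gm)^2)
  ss_bc <- n * sum((m_bc - outer(m_b, m_c, "+") + gm)^2)
  ss_sbc <- 0
  for (s in 1:n) for (bi in 1:b) for (ci in 1:cc) {
    ss_sbc <- ss_sbc + (tab[s, bi, ci] - m_sb[s, bi] - m_sc[s, ci] -
                          m_bc[bi, ci] + m_s[s] + m_b[bi] + m_c[ci] - gm)^2
  }
  f_b <- (ss_b / (b - 1)) / (ss_sb / ((b - 1) * (n - 1)))
  f_c <- (ss_c / (cc - 1)) / (ss_sc / ((cc - 1) * (n - 1)))
  f_i <- (ss_bc / ((b - 1) * (cc - 1))) /
    (ss_sbc / ((b - 1) * (cc - 1) * (n - 1)))
  list(F_band = f_b, F_cond = f_c, F_inter = f_i)
}

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= seq_len(m) / m * q)
  rej <- rep(FALSE, m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# tiny joint matrix with labelled EEG/IC columns
toy_ef <- function(t_len = 30, n_eeg = 3, n_ic = 4) {
  eeg <- matrix(rnorm(t_len * n_eeg), t_len,
                dimnames = list(NULL, paste0("E", seq_len(n_eeg))))
  ic <- matrix(rnorm(t_len * n_ic), t_len,
               dimnames = list(NULL, paste0("C", seq_len(n_ic))))
  build_joint_matrix(eeg, ic)
}
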