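# Independent brute-force implementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with R/).

oracle_burden <- function(panel, risk, normalise = FALSE) {
  n_s <- nrow(panel$dosage)
  f <- numeric(n_s); J <- integer(n_s)
  for (i in seq_len(n_s)) {
    tot <- 0; cnt <- 0L
    for (j in seq_len(ncol(panel$dosage))) {
      g <- panel$dosage[i, j]
      if (is.na(g)) next
      k <- which(risk$snp_id == panel$snps$snp_id[j])
      if (!length(k)) next
      if (risk$risk_allele[k] == panel$snps$alt[j] &&
          risk$nonrisk_allele[k] == panel$snps$ref[j]) {
        gr <- g
      } else if (risk$risk_allele[k] == panel$snps$ref[j] &&
                 risk$nonrisk_allele[k] == panel$snps$alt[j]) {
        gr <- panel$ploidy[i] - g
      } else next
      if (normalise) gr <- gr / panel$ploidy[i]
      tot <- tot + gr; cnt <- cnt + 1L
    }
    f[i] <- tot / cnt; J[i] <- cnt
  }
  data.frame(sample_id = panel$meta$sample_id, J = J, f = f)
}

# Kendall tau-b by O(n^2) pair enumeration with tie correction
oracle_kendall_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_weighted_kendall <- function(a, b, w) {
  n <- length(a)
  num <- den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ww <- w[i] * w[j]
    num <- num + ww * sign(a[i] - a[j]) * sign(b[i] - b[j])
    den <- den + ww
  }
  num / den
}

oracle_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / b) / (c / d)
}

# brute-force windowed VIF pruning with the same window walk but
# independent VIF computation (correlation-matrix inversion via solve())
oracle_vif_prune <- function(dosage, snp_id, window, step, vif_threshold) {
  m <- ncol(dosage)
  for (j in seq_len(m)) {
    mj <- is.na(dosage[, j])
    if (any(mj)) dosage[mj, j] <- mean(dosage[, j], na.rm = TRUE)
  }
  vif_of <- function(cols, j) {
    others <- setdiff(cols, j)
    others <- others[apply(dosage[, others, drop = FALSE], 2, sd) > 0]
    if (sd(dosage[, j]) == 0 || !length(others)) return(1)
    r2 <- summary(lm(dosage[, j] ~ dosage[, others, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  keep <- rep(TRUE, m)
  start <- 1
  repeat {
    idx <- which(keep & seq_len(m) >= start & seq_len(m) < start + window)
    while (length(idx) >= 2) {
      vifs <- vapply(idx, function(j) vif_of(idx, j), numeric(1))
      over <- which(vifs > vif_threshold)
      if (!length(over)) break
      worst <- over[which.max(vifs[over])]
      keep[idx[worst]] <- FALSE
      idx <- idx[-worst]
    }
    if (start + window > m) break
    start <- start + step
  }
  snp_id[keep]
}
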