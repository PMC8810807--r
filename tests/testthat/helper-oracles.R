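# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# Dice similarity by explicit set arithmetic over active indices
brute_dice <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# paired t by the closed-form definition
brute_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Benjamini-Hochberg step-up by direct enumeration
brute_bh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(n) / n * q)
  sig <- logical(n)
  if (length(ok) > 0) sig[o[seq_len(max(ok))]] <- TRUE
  sig
}

# fully-within two-factor ANOVA by direct sums-of-squares enumeration over
# subject/cell means (a, b: factor vectors; s: subject vector; y: values)
brute_rm_anova_2w <- function(s, a, b, y) {
  gm <- mean(y)
  m_s <- tapply(y, s, mean)
  m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(s, a), mean)
  m_sb <- tapply(y, list(s, b), mean)
  ka <- length(m_a); kb <- length(m_b); n <- length(m_s)
  ss_a <- n * kb * sum((m_a - gm)^2)
  ss_b <- n * ka * sum((m_b - gm)^2)
  ss_s <- ka * kb * sum((m_s - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, `+`) - gm)^2)
  ss_sa <- kb * sum((m_sa - outer(m_s - gm, m_a - gm, `+`) - gm)^2)
  ss_sb <- ka * sum((m_sb - outer(m_s - gm, m_b - gm, `+`) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_sa - ss_sb
  list(
    F_a = (ss_a / (ka - 1)) / (ss_sa / ((ka - 1) * (n - 1))),
    F_b = (ss_b / (kb - 1)) / (ss_sb / ((kb - 1) * (n - 1))),
    F_ab = (ss_ab / ((ka - 1) * (kb - 1))) /
      (ss_sab / ((ka - 1) * (kb - 1) * (n - 1))),
    ss = list(a = ss_a, b = ss_b, ab = ss_ab, s = ss_s,
              sa = ss_sa, sb = ss_sb, sab = ss_sab)
  )
}

# minimal custom design for dynamics tests
toy_design <- function(n_items, boundaries = integer(0), probes = NULL,
                       name = "toy") {
  if (is.null(probes)) {
    probes <- tibble::tibble(pos_early = integer(0), pos_late = integer(0),
                             pair_type = character(0))
  }
  experiment_design(name = name, n_items = n_items, boundaries = boundaries,
                    probes = probes)
}

# a random subject x 2x2 accuracy table for property checks
random_2x2_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = seq_len(n), condition = c("c1", "c2"),
                   pair_type = c("t1", "t2"), stringsAsFactors = FALSE)
  d$accuracy <- rnorm(nrow(d), 70, 10)
  tibble::as_tibble(d)
}
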