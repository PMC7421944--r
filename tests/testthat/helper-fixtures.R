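# Shared fixtures and independent oracles used across test files.

# small default config for fast tests
small_config <- function(...) {
  args <- list(m_snps = 1000L, n1 = 5000L, n2 = 5000L, block_size = 20L,
               block_rho = 0.8, pi_a = 0.01, pi_b = 0.01, pi_shared = 0.005,
               sign_concordance = 0.7, h2_a = 0.4, h2_b = 0.4, seed = 101L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(simulation_config, args)
}

# hand-built panel from a dosage matrix; positions 10 kb apart on one chromosome
toy_panel <- function(dos, chr = NULL, pos = NULL, freq = NULL) {
  m <- ncol(dos)
  chr <- chr %||% rep(1L, m)
  pos <- pos %||% (unlist(lapply(split(seq_len(m), chr), seq_along)) * 10000L)
  freq <- freq %||% pmin(pmax(colMeans(dos, na.rm = TRUE) / 2, 0.01), 0.99)
  genotype_panel(dos, data.frame(
    id = paste0("v", seq_len(m)), chr = chr, pos = pos,
    a1 = rep("A", m), a2 = rep("C", m), freq = freq,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal sumstats table from vectors
toy_ss <- function(p, chr = NULL, pos = NULL, z = NULL, n = 1000) {
  m <- length(p)
  sumstats(data.frame(
    id = paste0("v", seq_len(m)), chr = chr %||% rep(1L, m),
    pos = pos %||% (seq_len(m) * 10000L), a1 = "A", a2 = "C",
    z = z %||% stats::qnorm(p / 2) * sample(c(-1, 1), m, replace = TRUE),
    p = p, n = n, stringsAsFactors = FALSE))
}

# exchange the two traits of a harmonized pair
swap_pair_for_test <- function(pair) {
  out <- pair
  out$z1 <- pair$z2; out$z2 <- pair$z1
  out$p1 <- pair$p2; out$p2 <- pair$p1
  out$n1 <- pair$n2; out$n2 <- pair$n1
  out
}

# ---- independent oracles -------------------------------------------------

# HWE exact test by brute-force enumeration with the factorial formula
# P(h | nA, na) = choose(n, (nA-h)/2) * ... computed via lchoose/lfactorial
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  nr <- min(nA, na)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nr - h) / 2          # rare-homozygote count
    bb <- (max(nA, na) - h) / 2 # common-homozygote count
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 1)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# direct double-loop counting oracle for the stratified conditional FDR
cfdr_oracle <- function(p1, p2) {
  m <- length(p1)
  vapply(seq_len(m), function(i) {
    S <- which(p2 <= p2[i])
    min(1, p1[i] * length(S) / sum(p1[S] <= p1[i]))
  }, 1)
}

# naive re-derivation of the clumping hierarchy: greedy by ascending p with
# (chr, pos) tie-break, dependence at r2 >= r2_ind within the window
clump_oracle <- function(ss, r2mat, params) {
  sig <- which(ss$p < params$p_threshold)
  sig <- sig[order(ss$p[sig], ss$chr[sig], ss$pos[sig])]
  acc <- integer(0)
  for (i in sig) {
    dep <- FALSE
    for (j in acc) {
      if (ss$chr[j] == ss$chr[i] &&
          abs(ss$pos[j] - ss$pos[i]) <= params$window_bp &&
          r2mat[i, j] >= params$r2_independent) dep <- TRUE
    }
    if (!dep) acc <- c(acc, i)
  }
  ss$id[acc]
}

# sweep-line interval-union region count
union_count_oracle <- function(df) {
  df <- df[order(df$chr, df$start), , drop = FALSE]
  n <- 0L; cur_chr <- -1L; cur_end <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$chr[i] != cur_chr || df$start[i] > cur_end) {
      n <- n + 1L; cur_chr <- df$chr[i]; cur_end <- df$end[i]
    } else cur_end <- max(cur_end, df$end[i])
  }
  n
}

# BH step-up from the definition: largest k with p_(k) <= k q / m rejected
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
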