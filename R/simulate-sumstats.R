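#' Construct a summary-statistics table
#'
#' Per-variant GWAS results for one trait.  `z` is derived from `beta`/`se`
#' when absent; `p` is floored at 1e-300 so that -log10(p) stays finite.
#'
#' @param df data.frame with columns `id`, `chr`, `pos`, `a1`, `a2`, `p`, `n`
#'   and at least one of `z` or `beta` + `se`; optional `freq`, `info`.
#' @return an object of class `sumstats` (a data.frame).
#' @export
sumstats <- function(df) {
  df <- as.data.frame(df)
  req <- c("id", "chr", "pos", "a1", "a2", "p", "n")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sumstats lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(df$z)) {
    if (is.null(df$beta) || is.null(df$se)) {
      stop("sumstats needs `z` or both `beta` and `se`", call. = FALSE)
    }
    df$z <- df$beta / df$se
  }
  if (!is.null(df$beta) && !is.null(df$se)) {
    bad <- !is.na(df$z) & !is.na(df$beta) & sign(df$z) * sign(df$beta) < 0
    if (any(bad)) stop("z and beta disagree in sign for ", sum(bad), " variants",
                       call. = FALSE)
  }
  df$p <- floor_p(df$p)
  if (any(df$p > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]", call. = FALSE)
  key <- paste(df$chr, df$pos, pmin(df$a1, df$a2), pmax(df$a1, df$a2))
  if (anyDuplicated(key)) stop("duplicate (chr, pos, allele pair) rows", call. = FALSE)
  class(df) <- c("sumstats", "data.frame")
  df
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variants, median N = %g, min p = %.3g\n",
              nrow(x), stats::median(x$n), min(x$p, na.rm = TRUE)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# Dosage-scale correlation of one LD block under the thresholded-Gaussian
# copula, computed analytically via Mehler's expansion of the bivariate
# normal orthant probability:
#   cov(I(Z1 < t1), I(Z2 < t2)) = sum_{n>=1} r^n / n! *
#       He_{n-1}(t1) phi(t1) * He_{n-1}(t2) phi(t2)
# with He the probabilists' Hermite polynomials; the haplotype indicator
# covariance carries over to dosages unchanged (two iid haplotypes scale
# covariance and variance alike).  Truncation at 12 terms is far below the
# shrinkage applied for Cholesky stability.
MEHLER_TERMS <- 12L

dosage_block_cor <- function(freq, rho, ...) {
  k <- length(freq)
  if (k == 1L) return(matrix(1, 1, 1))
  t <- stats::qnorm(freq)
  phi <- stats::dnorm(t)
  # g[, n] = He_{n-1}(t) * phi(t)
  He <- matrix(0, k, MEHLER_TERMS)
  He[, 1] <- 1
  if (MEHLER_TERMS >= 2) He[, 2] <- t
  for (n in 3:MEHLER_TERMS) He[, n] <- t * He[, n - 1] - (n - 2) * He[, n - 2]
  g <- He * phi
  D <- abs(outer(seq_len(k), seq_len(k), "-"))
  covb <- matrix(0, k, k)
  for (n in seq_len(MEHLER_TERMS)) {
    covb <- covb + (rho^n)^D * outer(g[, n], g[, n]) / factorial(n)
  }
  v <- freq * (1 - freq)
  R <- covb / sqrt(outer(v, v))
  diag(R) <- 1
  0.995 * R + 0.005 * diag(k)
}

# standardized-scale per-causal effect SD for target h2 with expected causal
# count m * pi
per_causal_sd <- function(h2, m, pi_total) {
  if (pi_total <= 0 || h2 <= 0) return(0)
  sqrt(h2 / (m * pi_total))
}

#' Simulate paired GWAS summary statistics under a bivariate causal mixture
#'
#' Causal indicators are drawn per variant from four components (trait-A-only,
#' trait-B-only, shared, null) with probabilities `pi_a`, `pi_b`, `pi_shared`.
#' Standardized effects are Gaussian with per-causal variance `h2 / (m * pi)`
#' so realized heritability matches the target in expectation.  A shared
#' causal variant gets the trait-A effect rescaled to the trait-B per-causal
#' scale, with its sign flipped with probability `1 - sign_concordance` — the
#' generative analogue of a mixed pattern of allelic effect directions.
#' Z-scores are drawn block-wise from the standard infinitesimal-noise GWAS
#' approximation `z ~ Normal(sqrt(N) R beta_std, R)`.  `R` is the block LD
#' matrix on the dosage scale: the genotype copula attenuates the latent
#' AR(1) correlation, so `R` is estimated per block from an internal
#' reference draw of the same copula (4000 individuals), keeping the z-score
#' LD consistent with the r-squared an external panel measures.  Two-sided
#' p-values are attached; both traits share the variant map and alleles.
#'
#' @param config a [simulation_config()].
#' @param panel optional [genotype_panel()] from [simulate_ld_genotypes()]
#'   supplying the variant map and block structure (its first `m_snps`
#'   variants are used).  When omitted the map comes directly from
#'   [simulate_variant_map()] — no genotypes are generated, since the
#'   z-score model only needs the analytic block LD.
#' @param seed optional override of `config$seed` for the causal-effect and
#'   z-score draws; the variant map still follows `config$seed`, so replicate
#'   summary statistics over one map are obtained by varying `seed` only.
#' @return list with elements `ss1`, `ss2` ([sumstats()] tables) and `truth`,
#'   a data.frame recording per-variant causal component, standardized
#'   effects, and the same/opposite sign of shared effects.
#' @export
simulate_sumstats_pair <- function(config, panel = NULL, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  v <- if (is.null(panel)) simulate_variant_map(config) else panel$variants
  if (nrow(v) < config$m_snps) {
    stop("panel has fewer variants than `m_snps`", call. = FALSE)
  }
  v <- v[seq_len(config$m_snps), , drop = FALSE]
  m <- config$m_snps
  with_seed((seed %||% config$seed) + 1L, {
    u <- stats::runif(m)
    comp <- ifelse(u < config$pi_a, "A",
            ifelse(u < config$pi_a + config$pi_b, "B",
            ifelse(u < config$pi_a + config$pi_b + config$pi_shared, "AB", "null")))
    s_a <- per_causal_sd(config$h2_a, m, config$pi_a + config$pi_shared)
    s_b <- per_causal_sd(config$h2_b, m, config$pi_b + config$pi_shared)
    beta1 <- beta2 <- numeric(m)
    ia <- comp %in% c("A", "AB"); ib <- comp == "B"; iab <- comp == "AB"
    beta1[ia] <- stats::rnorm(sum(ia), 0, s_a)
    beta2[ib] <- stats::rnorm(sum(ib), 0, s_b)
    same <- rep(NA, m)
    if (any(iab)) {
      same[iab] <- stats::runif(sum(iab)) < config$sign_concordance
      scale_b <- if (s_a > 0) s_b / s_a else 0
      beta2[iab] <- beta1[iab] * scale_b * ifelse(same[iab], 1, -1)
    }
    blk <- v$block %||% rep(1L, m)
    rho_col <- v$rho %||% rep(if (length(config$block_rho) == 2L)
      mean(config$block_rho) else config$block_rho, m)
    z1 <- numeric(m); z2 <- numeric(m)
    ez1 <- numeric(m); ez2 <- numeric(m)  # expected (noncentral) z per trait
    for (idx in split(seq_len(m), blk)) {
      k <- length(idx)
      R <- dosage_block_cor(v$freq[idx], rho_col[idx[1]])
      L <- chol(R)  # upper triangular, R = L'L
      mu1 <- sqrt(config$n1) * drop(R %*% beta1[idx])
      mu2 <- sqrt(config$n2) * drop(R %*% beta2[idx])
      ez1[idx] <- mu1; ez2[idx] <- mu2
      z1[idx] <- mu1 + drop(crossprod(L, stats::rnorm(k)))
      z2[idx] <- mu2 + drop(crossprod(L, stats::rnorm(k)))
    }
    base <- data.frame(id = v$id, chr = v$chr, pos = v$pos,
                       a1 = v$a1, a2 = v$a2, freq = v$freq,
                       stringsAsFactors = FALSE)
    ss1 <- base; ss1$z <- z1; ss1$p <- p_from_z(z1); ss1$n <- config$n1
    ss2 <- base; ss2$z <- z2; ss2$p <- p_from_z(z2); ss2$n <- config$n2
    truth <- data.frame(id = v$id, block = blk, component = comp,
                        beta1 = beta1, beta2 = beta2, same_sign = same,
                        ez1 = ez1, ez2 = ez2, stringsAsFactors = FALSE)
    list(ss1 = sumstats(ss1), ss2 = sumstats(ss2), truth = truth)
  })
}

#' Simulate a phenotype with target heritability from a genotype panel
#'
#' `y = sum(x_std * beta) + e` with the genetic variance fraction equal to
#' `h2` in expectation; effects act on column-standardized dosages.  When
#' `h2 = 1` the noise term is identically zero.
#'
#' @param panel a [genotype_panel()].
#' @param h2 target heritability in `[0, 1]`.
#' @param n_causal number of causal variants (sampled uniformly).
#' @param seed integer seed.
#' @return list with `y` (length-n vector), `beta` (length-m standardized
#'   effects, zero for non-causal variants), `causal` (indices), and
#'   `realized_h2` (realized genetic variance fraction).
#' @export
simulate_phenotype <- function(panel, h2, n_causal, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  check_fraction(h2, "h2")
  m <- ncol(panel$dosages)
  n_causal <- check_count(n_causal, "n_causal", min = 0)
  if (n_causal > m) stop_config("n_causal", "exceeds the number of variants")
  with_seed(seed, {
    causal <- sort(sample.int(m, n_causal))
    beta <- numeric(m)
    if (n_causal > 0 && h2 > 0) {
      beta[causal] <- stats::rnorm(n_causal, 0, sqrt(h2 / n_causal))
    }
    X <- scale(panel$dosages[, causal, drop = FALSE])
    g <- if (n_causal > 0) drop(X %*% beta[causal]) else numeric(nrow(panel$dosages))
    e <- if (h2 >= 1) numeric(length(g)) else stats::rnorm(length(g), 0, sqrt(1 - h2))
    y <- g + e
    vg <- stats::var(g)
    list(y = y, beta = beta, causal = causal,
         realized_h2 = if (stats::var(y) > 0) vg / stats::var(y) else 0)
  })
}
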