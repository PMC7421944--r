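make_pair <- function(p1, p2, block = NULL, z1 = NULL, z2 = NULL) {
  m <- length(p1)
  structure(list(
    variants = data.frame(id = paste0("v", seq_len(m)), chr = 1L,
                          pos = seq_len(m) * 10000L, a1 = "A", a2 = "C",
                          stringsAsFactors = FALSE),
    z1 = z1 %||% stats::qnorm(p1 / 2), z2 = z2 %||% stats::qnorm(p2 / 2),
    p1 = p1, p2 = p2, n1 = 1000, n2 = 1000,
    block = block %||% seq_len(m),
    log = data.frame(id = character(0), reason = character(0))),
    class = "harmonized_pair")
}

test_that("harmonization aligns alleles per the 16-case truth table", {
  # flip identity: swapped alleles with negated z harmonize back exactly
  sc <- small_config(m_snps = 200L, seed = 41L)
  pr <- simulate_sumstats_pair(sc)
  ss2 <- pr$ss1
  tmp <- ss2$a1; ss2$a1 <- ss2$a2; ss2$a2 <- tmp
  ss2$z <- -ss2$z
  pair <- harmonize_pair(pr$ss1, ss2)
  expect_equal(pair$z2, pair$z1)
  # strand-ambiguous variants are dropped with reason
  ssa <- pr$ss1; ssa$a1[1] <- "A"; ssa$a2[1] <- "T"
  pair2 <- harmonize_pair(ssa, ssa)
  expect_true("strand-ambiguous" %in% pair2$log$reason)
  expect_false("v1" %in% pair2$variants$id || ssa$id[1] %in% pair2$variants$id)
  # truth-table oracle over all allele-pair matchings of 1000 random variants
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(6)
  base <- pr$ss1[rep(1:200, length.out = 1000), ]
  base$pos <- seq_len(1000) * 1000L; base$id <- paste0("x", 1:1000)
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a1 = bases, a2 = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a1 != pairs$a2, ]
  k <- nrow(base)
  base$a1 <- pairs$a1[rep_len(seq_len(nrow(pairs)), k)]
  base$a2 <- pairs$a2[rep_len(seq_len(nrow(pairs)), k)]
  other <- base
  relabel <- sample(1:4, k, replace = TRUE)
  other$a1 <- ifelse(relabel == 1, base$a1,
              ifelse(relabel == 2, base$a2,
              ifelse(relabel == 3, comp[base$a1], comp[base$a2])))
  other$a2 <- ifelse(relabel == 1, base$a2,
              ifelse(relabel == 2, base$a1,
              ifelse(relabel == 3, comp[base$a2], comp[base$a1])))
  got <- harmonize_pair(sumstats(base), sumstats(other))
  # oracle: expected flip per variant; ambiguous pairs (a2 == complement(a1))
  # are dropped; for non-ambiguous, relabel 2 and 4 swap -> flip sign
  ambiguous <- comp[base$a1] == base$a2
  expected_flip <- ifelse(relabel %in% c(2, 4), -1, 1)
  kept <- !ambiguous
  expect_equal(nrow(got$variants), sum(kept))
  expect_equal(got$z2, (base$z * expected_flip)[kept])
})

test_that("genomic inflation control rescales by the median chi-square", {
  set.seed(7)
  z <- stats::rnorm(100000)
  ss <- toy_ss(p = 2 * stats::pnorm(-abs(z)), z = z, pos = 1:100000 * 100L)
  ss$z <- z
  lam <- lambda_gc(ss)
  expect_gt(lam, 0.97); expect_lt(lam, 1.03)
  # z scaled by sqrt(1.2): lambda ~= 1.2, corrected back to ~1
  ss_inf <- ss; ss_inf$z <- z * sqrt(1.2); ss_inf$p <- 2 * stats::pnorm(-abs(ss_inf$z))
  out <- genomic_inflation_correct(ss_inf)
  expect_lt(abs(attr(out, "lambda") - 1.2), 0.03)
  expect_lt(abs(lambda_gc(out) - 1), 0.03)
  # lambda <= 1 input: identical output
  ss_ok <- ss; ss_ok$z <- z * 0.9; ss_ok$p <- 2 * stats::pnorm(-abs(ss_ok$z))
  out2 <- genomic_inflation_correct(ss_ok)
  expect_equal(out2$p, ss_ok$p, tolerance = 1e-12)
})

test_that("exclusion regions are inclusive at the printed hg19 boundaries", {
  pos6 <- c(25119105L, 25119106L, 30000000L, 33854733L, 33854734L)
  pos8 <- c(7242714L, 7242715L, 12483982L, 12483983L)
  ss <- sumstats(data.frame(
    id = paste0("s", 1:9), chr = c(rep(6L, 5), rep(8L, 4)),
    pos = c(pos6, pos8), a1 = "A", a2 = "C",
    z = 1, p = 0.5, n = 1000, stringsAsFactors = FALSE))
  out <- exclude_regions(ss)
  expect_equal(attr(out, "n_removed"), 5L)
  expect_setequal(out$pos, c(25119105L, 33854734L, 7242714L, 12483983L))
})

test_that("conditional Q-Q reduces to the ordinary Q-Q and detects enrichment", {
  # self-conditioning at cutoff 1 equals the ordinary quantile curve
  set.seed(8)
  p <- stats::runif(5000)
  pair <- make_pair(p, p)
  qq <- conditional_qq(pair, cutoffs = 1, prune_iter = 1)
  grid <- qq$grid
  ecdf_direct <- vapply(grid, function(q) -log10(mean(p <= 10^(-q))), 1)
  ok <- is.finite(ecdf_direct)
  expect_equal(qq$curves[ok, 1], ecdf_direct[ok], tolerance = 1e-12)
  # independent null traits: curves hug the diagonal
  p2 <- stats::runif(5000)
  qq0 <- conditional_qq(make_pair(p, p2), prune_iter = 1)
  # at nominal 0.01 (knot 2.0) all strata should be close to 2.0
  k <- which(qq0$grid == 2)
  vals <- qq0$curves[k, ]
  expect_lt(max(abs(vals - 2), na.rm = TRUE), 0.5)
  # shared-signal simulation: monotone leftward deflection with stricter cutoffs
  sc <- simulation_config(m_snps = 20000L, n1 = 50000L, n2 = 50000L,
                          block_size = 20L, pi_a = 0, pi_b = 0,
                          pi_shared = 0.02, sign_concordance = 0.5,
                          h2_a = 0.5, h2_b = 0.5, seed = 43L)
  pr <- simulate_sumstats_pair(sc)
  hp <- harmonize_pair(pr$ss1, pr$ss2, blocks = pr$truth$block)
  qq1 <- conditional_qq(hp, prune_iter = 5, seed = 2)
  # enrichment pushes the curve below the null diagonal (a larger proportion
  # of small p1 than nominal), monotonically with stricter conditioning
  for (k in which(qq1$grid %in% c(1, 2, 3))) {
    deflect <- qq1$curves[k, ]
    expect_true(all(diff(deflect) < 0))
    expect_lt(deflect[4], qq1$grid[k])  # strictest stratum well under the null
  }
})

test_that("conditional FDR equals the direct counting formula", {
  # 12-variant toy with listed (p1, p2), no LD, no pruning: exact equality
  p1 <- c(0.001, 0.5, 0.04, 0.2, 0.0005, 0.9, 0.3, 0.07, 0.15, 0.6, 0.02, 0.8)
  p2 <- c(0.01, 0.3, 0.002, 0.7, 0.05, 0.1, 0.004, 0.5, 0.25, 0.9, 0.03, 0.6)
  pair <- make_pair(p1, p2)
  cf <- cond_fdr(pair, 1, prune_iter = 1)
  expect_equal(cf$fdr, cfdr_oracle(p1, p2), tolerance = 1e-12)
  # conditioning on a constant (all variants in stratum): unconditional
  # empirical FDR p * m / rank
  pair_const <- make_pair(p1, rep(1, 12))
  cf2 <- cond_fdr(pair_const, 1, prune_iter = 1)
  expect_equal(cf2$fdr, pmin(1, p1 * 12 / rank(p1)), tolerance = 1e-12)
  # p1 == p2: conditioning on a perfectly informative trait only enriches
  pair_same <- make_pair(p1, p1)
  cf3 <- cond_fdr(pair_same, 1, prune_iter = 1)
  expect_true(all(cf3$fdr <= cf2$fdr + 1e-12))
  # bounds: cFDR in [p1, 1]
  expect_true(all(cf$fdr >= p1 - 1e-15 & cf$fdr <= 1))
})

test_that("cFDR with ties handles <= counting exactly", {
  p1 <- c(0.1, 0.1, 0.5, 0.02, 0.02, 1)
  p2 <- c(0.3, 0.3, 0.3, 0.01, 0.9, 0.01)
  pair <- make_pair(p1, p2)
  cf <- cond_fdr(pair, 1, prune_iter = 1)
  expect_equal(cf$fdr, cfdr_oracle(p1, p2), tolerance = 1e-12)
})

test_that("grid lookup table is monotone and the pruned estimate tracks the exact one", {
  sc <- small_config(m_snps = 4000L, pi_shared = 0.01, seed = 44L)
  pr <- simulate_sumstats_pair(sc)
  hp <- harmonize_pair(pr$ss1, pr$ss2, blocks = pr$truth$block)
  cf <- cond_fdr(hp, 1, prune_iter = 10, seed = 3)
  tab <- cf$table
  for (j in seq_len(ncol(tab))) {
    col <- tab[, j][!is.na(tab[, j])]
    expect_true(all(diff(col) <= 1e-12))
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ][!is.na(tab[i, ])]
    expect_true(all(diff(row) <= 1e-12))
  }
  exact <- cond_fdr(hp, 1, prune_iter = 1)
  # the pruned-grid estimate is a smoothed (block-subsampled, interpolated)
  # version of the exact pointwise one: strong but not perfect agreement
  expect_gt(stats::cor(log10(cf$fdr), log10(exact$fdr)), 0.75)
  expect_lt(mean(abs(log10(cf$fdr) - log10(exact$fdr))), 0.3)
})

test_that("conjunctional FDR is the max of the reciprocal cFDRs and is symmetric", {
  sc <- small_config(m_snps = 2000L, seed = 45L)
  pr <- simulate_sumstats_pair(sc)
  hp <- harmonize_pair(pr$ss1, pr$ss2, blocks = pr$truth$block)
  cj <- conj_fdr(hp, prune_iter = 5, seed = 7)
  expect_equal(cj$fdr, pmax(cj$cfdr12$fdr, cj$cfdr21$fdr))
  # swap the traits: identical conjFDR with the same seed
  cj_sw <- conj_fdr(swap_pair_for_test(hp), prune_iter = 5, seed = 7)
  expect_equal(cj_sw$fdr, cj$fdr)
})

test_that("cFDR converges to the unconditional FDR under an independent conditioning trait", {
  set.seed(9)
  m <- 20000
  p1 <- stats::runif(m)
  p2 <- stats::runif(m)
  pair <- make_pair(p1, p2)
  cf <- cond_fdr(pair, 1, prune_iter = 1)
  uncond <- pmin(1, p1 * m / rank(p1))
  expect_lt(mean(abs(cf$fdr - uncond)), 0.02)
})

test_that("shared loci report effect directions matching the generator", {
  run_shared <- function(conc, seed) {
    sc <- simulation_config(m_snps = 8000L, n1 = 60000L, n2 = 60000L,
                            block_size = 20L, pi_a = 0, pi_b = 0,
                            pi_shared = 0.01, sign_concordance = conc,
                            h2_a = 0.5, h2_b = 0.5, seed = seed)
    panel <- simulate_ld_genotypes(sc, n_samples = 1000)
    pr <- simulate_sumstats_pair(sc, panel)
    hp <- harmonize_pair(pr$ss1, pr$ss2, panel)
    cj <- conj_fdr(hp, prune_iter = 5, seed = seed)
    sl <- shared_loci(hp, cj, panel, 0.05)
    # truth filter: loci whose lead sits in a block carrying a shared causal
    # (a conjFDR < 0.05 report is expected to contain ~5% false loci, which
    # carry arbitrary directions)
    shared_blocks <- unique(pr$truth$block[pr$truth$component == "AB"])
    lead_block <- pr$truth$block[match(sl$loci$lead, pr$truth$id)]
    sl$true_dirs <- sl$loci$direction[lead_block %in% shared_blocks]
    sl
  }
  sl1 <- run_shared(1, 46L)
  expect_gt(length(sl1$true_dirs), 0)
  expect_true(all(sl1$true_dirs == 1))
  sl0 <- run_shared(0, 47L)
  expect_gt(length(sl0$true_dirs), 0)
  expect_true(all(sl0$true_dirs == -1))
  # mixed directions at 70% concordance: within binomial error
  sl7 <- run_shared(0.7, 48L)
  n <- length(sl7$true_dirs)
  expect_gt(n, 10)
  ci <- stats::binom.test(sum(sl7$true_dirs == 1), n, 0.7)$p.value
  expect_gt(ci, 0.001)
  # empty report below threshold is not an error
  sc0 <- small_config(m_snps = 500L, pi_a = 0, pi_b = 0, pi_shared = 0,
                      seed = 49L)
  panel0 <- simulate_ld_genotypes(sc0)
  pr0 <- simulate_sumstats_pair(sc0, panel0)
  hp0 <- harmonize_pair(pr0$ss1, pr0$ss2, panel0)
  cj0 <- conj_fdr(hp0, prune_iter = 1)
  sl_empty <- shared_loci(hp0, cj0, panel0, 1e-6)
  expect_equal(nrow(sl_empty$loci), 0L)
})

test_that("conjFDR discovers more than joint genome-wide significance", {
  sc <- simulation_config(m_snps = 10000L, n1 = 30000L, n2 = 30000L,
                          block_size = 20L, pi_a = 0, pi_b = 0,
                          pi_shared = 0.01, sign_concordance = 0.7,
                          h2_a = 0.4, h2_b = 0.4, seed = 50L)
  pr <- simulate_sumstats_pair(sc)
  hp <- harmonize_pair(pr$ss1, pr$ss2, blocks = pr$truth$block)
  cj <- conj_fdr(hp, prune_iter = 5, seed = 1)
  n_conj <- sum(cj$fdr < 0.05)
  n_joint_gws <- sum(hp$p1 < 5e-8 & hp$p2 < 5e-8)
  expect_gt(n_conj, n_joint_gws)
})
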