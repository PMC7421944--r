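test_that("ld_r2 equals a brute-force correlation oracle", {
  set.seed(3)
  dos <- matrix(stats::rbinom(200 * 8, 2, 0.3), 200, 8)
  dos[, 2] <- dos[, 1]                      # identical pair
  panel <- toy_panel(dos)
  expect_equal(ld_r2(panel, 1, 2), 1.0)
  expect_equal(ld_r2(panel, "v1", "v1"), 1.0)
  # full matrix against a double loop
  for (i in 1:8) for (j in 1:8) {
    expect_equal(ld_r2(panel, i, j), stats::cor(dos[, i], dos[, j])^2,
                 tolerance = 1e-12)
  }
  # independence at n = 5000
  big <- matrix(stats::rbinom(5000 * 2, 2, 0.4), 5000, 2)
  expect_lt(ld_r2(toy_panel(big), 1, 2), 0.01)
  # zero variance errors
  dos[, 3] <- 1
  expect_error(ld_r2(toy_panel(dos), 3, 4), "zero-variance")
})

test_that("greedy clumping matches the exhaustive oracle on random toys", {
  params <- clump_params(p_threshold = 0.05)
  set.seed(42)
  for (rep in 1:100) {
    m <- sample(4:12, 1)
    n <- 300
    # random block structure with some tight LD
    base <- stats::rbinom(n, 2, 0.4)
    dos <- sapply(seq_len(m), function(j) {
      if (stats::runif(1) < 0.5) {
        flip <- stats::runif(n) < stats::runif(1, 0, 0.3)
        ifelse(flip, stats::rbinom(n, 2, 0.4), base)
      } else stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5))
    })
    keep <- apply(dos, 2, stats::var) > 0
    dos <- dos[, keep, drop = FALSE]
    m <- ncol(dos)
    if (m < 2) next
    pos <- sort(sample(1:2000, m)) * 1000L
    panel <- toy_panel(dos, pos = pos)
    ss <- toy_ss(stats::runif(m, 1e-6, 0.2), pos = pos)
    r2mat <- stats::cor(dos)^2
    got <- as.character(clump_independent(ss, panel, params))
    want <- clump_oracle(ss, r2mat, params)
    expect_equal(got, want)
  }
})

test_that("two dependent significant SNPs collapse to the smaller-p one", {
  set.seed(9)
  n <- 1000
  g1 <- stats::rbinom(n, 2, 0.3)
  flip <- stats::runif(n) < 0.05
  g2 <- ifelse(flip, stats::rbinom(n, 2, 0.3), g1)   # r2 ~ 0.8
  panel <- toy_panel(cbind(g1, g2), pos = c(100000L, 150000L))
  expect_gt(ld_r2(panel, 1, 2), 0.6)
  ss <- toy_ss(c(1e-9, 1e-10), pos = c(100000L, 150000L))
  ind <- clump_independent(ss, panel)
  expect_equal(as.character(ind), "v2")  # the smaller p
})

test_that("lead merging respects the 250 kb rule and candidate spans", {
  # two independent signals on one chromosome, no LD between them
  set.seed(10)
  n <- 2000
  dos <- cbind(stats::rbinom(n, 2, 0.3), stats::rbinom(n, 2, 0.4))
  # 200 kb apart -> one locus; 300 kb apart -> two
  p_two <- toy_panel(dos, pos = c(1000000L, 1200000L))
  ss <- toy_ss(c(1e-9, 1e-9), pos = c(1000000L, 1200000L))
  loci_merged <- define_loci(clump_independent(ss, p_two), ss, p_two)
  expect_equal(nrow(loci_merged), 1L)
  p_far <- toy_panel(dos, pos = c(1000000L, 1300000L))
  ss2 <- toy_ss(c(1e-9, 1e-9), pos = c(1000000L, 1300000L))
  loci_two <- define_loci(clump_independent(ss2, p_far), ss2, p_far)
  expect_equal(nrow(loci_two), 2L)
})

test_that("a 20-SNP three-block toy reproduces the hand-enumerated loci", {
  # three LD blocks: SNPs 1-7 (tight LD), 8-14 (tight LD), 15-20 independent.
  # blocks 1-2 are 100 kb apart (leads merge), block 3 is 2 Mb away.
  set.seed(11)
  n <- 3000
  mk_block <- function(k, f) {
    base <- stats::rbinom(n, 2, f)
    sapply(seq_len(k), function(j) {
      flip <- stats::runif(n) < 0.01 * j  # all pairwise r2 stay >= 0.6
      ifelse(flip, stats::rbinom(n, 2, f), base)
    })
  }
  dos <- cbind(mk_block(7, 0.3), mk_block(7, 0.4),
               matrix(stats::rbinom(n * 6, 2, 0.35), n, 6))
  pos <- c(seq(1000000L, by = 10000L, length.out = 7),
           seq(1170000L, by = 10000L, length.out = 7),
           seq(4000000L, by = 50000L, length.out = 6))
  panel <- toy_panel(dos, pos = pos)
  p <- rep(0.5, 20)
  p[3] <- 1e-12   # block-1 signal (lead)
  p[5] <- 1e-9    # same block, dependent
  p[10] <- 1e-10  # block-2 signal
  p[15] <- 1e-9   # isolated significant SNP
  ss <- toy_ss(p, pos = pos)
  loci <- find_loci(ss, panel)
  # hand enumeration: v3 and v10 are leads 100 kb apart -> merged locus;
  # v5 is dependent on v3 (same tight block); v15 isolated -> second locus
  expect_equal(nrow(loci), 2L)
  l1 <- loci[loci$start < 2e6, ]
  expect_setequal(l1$ind_ids[[1]], c("v3", "v10"))
  expect_true(all(c("v1", "v7", "v8", "v14") %in% l1$cand_ids[[1]]))
  expect_equal(l1$top_p, 1e-12)
  l2 <- loci[loci$start > 2e6, ]
  expect_equal(l2$ind_ids[[1]], "v15")
  # post-hoc invariants: independent SNPs pairwise r2 < 0.6 within 1 Mb
  ind <- unlist(loci$ind_ids)
  for (a in ind) for (b in ind) {
    ia <- match(a, panel$variants$id); ib <- match(b, panel$variants$id)
    if (a != b && abs(pos[ia] - pos[ib]) <= 1e6) {
      expect_lt(ld_r2(panel, ia, ib), 0.6)
    }
  }
  # every significant SNP is in r2 >= 0.6 with an independent SNP or is one
  for (s in which(p < 5e-8)) {
    id <- paste0("v", s)
    ok <- id %in% ind ||
      any(vapply(ind, function(a) ld_r2(panel, id, a) >= 0.6, TRUE))
    expect_true(ok)
  }
})

test_that("locus count is monotone in the significance threshold", {
  sc <- small_config(m_snps = 2000L, n1 = 40000L, n2 = 40000L,
                     pi_a = 0.02, h2_a = 0.5, seed = 13L)
  pr <- simulate_sumstats_pair(sc)
  panel <- simulate_ld_genotypes(sc, n_samples = 1000)
  n_strict <- nrow(find_loci(pr$ss1, panel, clump_params(p_threshold = 1e-8)))
  n_loose <- nrow(find_loci(pr$ss1, panel, clump_params(p_threshold = 5e-8)))
  expect_gte(n_loose, n_strict)
  expect_gt(n_loose, 0)
})

test_that("clumping output is invariant to input row order", {
  sc <- small_config(m_snps = 1000L, n1 = 40000L, n2 = 40000L,
                     pi_a = 0.02, h2_a = 0.5, seed = 23L)
  pr <- simulate_sumstats_pair(sc)
  panel <- simulate_ld_genotypes(sc, n_samples = 1000)
  ind1 <- clump_independent(pr$ss1, panel)
  set.seed(1)
  shuffled <- pr$ss1[sample(nrow(pr$ss1)), ]
  ind2 <- clump_independent(shuffled, panel)
  expect_equal(as.character(ind1), as.character(ind2))
})

test_that("cross-trait unique regions match the sweep-line union oracle", {
  # identity for k = 1
  one <- data.frame(chr = c(1L, 2L), start = c(100L, 5000L),
                    end = c(900L, 8000L))
  u1 <- cross_trait_unique_loci(list(t1 = one))
  expect_equal(nrow(u1), 2L)
  expect_equal(u1$start, one$start)
  # identical locus in two traits -> one region, two memberships
  u2 <- cross_trait_unique_loci(list(t1 = one[1, ], t2 = one[1, ]))
  expect_equal(nrow(u2), 1L)
  expect_equal(u2$n_traits, 2L)
  expect_equal(u2$traits, "t1;t2")
  # randomized interval sets vs the oracle
  set.seed(31)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    lst <- lapply(seq_len(k), function(i) {
      nloc <- sample(1:8, 1)
      start <- sort(sample(1:10000, nloc)) * 100L
      len <- sample(50:5000, nloc, replace = TRUE)
      df <- data.frame(chr = sample(1:2, nloc, replace = TRUE),
                       start = start, end = start + len)
      df[order(df$chr, df$start), ]
    })
    # make each per-trait list non-overlapping (precondition)
    lst <- lapply(lst, function(df) {
      keep <- rep(TRUE, nrow(df))
      for (i in seq_len(nrow(df))[-1]) {
        prev <- max(which(keep[seq_len(i - 1)]))
        if (df$chr[i] == df$chr[prev] && df$start[i] <= df$end[prev]) {
          keep[i] <- FALSE
        }
      }
      df[keep, ]
    })
    got <- cross_trait_unique_loci(lst)
    want <- union_count_oracle(do.call(rbind, lst))
    expect_equal(nrow(got), want)
  }
})

test_that("BED export is 0-based half-open and round-trips", {
  loci <- data.frame(chr = c(1L, 6L), start = c(101L, 25119106L),
                     end = c(900L, 33854733L), lead = c("a", "b"))
  path <- tempfile(fileext = ".bed")
  write_loci_bed(loci, path)
  raw <- utils::read.table(path, sep = "\t")
  expect_equal(raw[[2]], c(100L, 25119105L))  # start - 1
  expect_equal(raw[[3]], c(900L, 33854733L))  # end unchanged
  back <- read_regions_bed(path)
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
  expect_equal(back$chr, loci$chr)
})
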