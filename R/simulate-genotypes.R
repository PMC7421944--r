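#' Simulation configuration for the synthetic two-trait study
#'
#' Bundles the parameters of the synthetic-data generators: a block-LD
#' genotype panel, a bivariate causal-mixture architecture for paired GWAS
#' summary statistics, and target SNP heritabilities.  Defaults describe the
#' desk-scale study the package is exercised on: a UK-Biobank-like discovery
#' sample size, MAF in the post-QC range, moderate within-block LD, a sparse
#' polygenic architecture with a small shared-causal component, mixed effect
#' directions (70% concordant, the pattern reported for Parkinson's disease
#' loci), and heritabilities spanning the brainstem-volume range 0.27-0.48.
#'
#' @param m_snps number of variants.
#' @param n1,n2 GWAS sample sizes for traits A and B.
#' @param maf_range length-2 numeric, allele-frequency range in (0, 0.5].
#' @param block_size variants per LD block (>= 1).
#' @param block_rho within-block adjacent latent correlation in `[0, 1)`;
#'   correlation between block members i and j is `block_rho^|i-j|` (AR(1)).
#'   A length-2 range draws each block's rho uniformly from it, giving the
#'   heterogeneous LD-score distribution real genomes show (needed for
#'   LD-score-regression experiments to be well conditioned).
#' @param pi_a,pi_b,pi_shared causal fractions for the trait-A-only,
#'   trait-B-only, and shared mixture components; their sum must be <= 1.
#' @param sign_concordance probability that a shared causal variant has
#'   same-sign effects in both traits.
#' @param h2_a,h2_b target narrow-sense heritabilities in `[0, 1]`.
#' @param seed integer seed; every generator taking this config is
#'   deterministic given the seed.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(m_snps = 20000L, n1 = 27000L, n2 = 27000L,
                              maf_range = c(0.05, 0.5),
                              block_size = 40L, block_rho = 0.8,
                              pi_a = 0.003, pi_b = 0.003, pi_shared = 0.001,
                              sign_concordance = 0.7,
                              h2_a = 0.48, h2_b = 0.27, seed = 1L) {
  m_snps <- check_count(m_snps, "m_snps")
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(is.na(maf_range)) || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop_config("maf_range", "must be an increasing pair within (0, 0.5]")
  }
  block_size <- check_count(block_size, "block_size")
  if (!length(block_rho) %in% c(1L, 2L)) {
    stop_config("block_rho", "must be a scalar or a length-2 range")
  }
  for (r in block_rho) check_fraction(r, "block_rho", 0, 1, hi_open = TRUE)
  if (length(block_rho) == 2L && block_rho[1] > block_rho[2]) {
    stop_config("block_rho", "range must be increasing")
  }
  check_fraction(pi_a, "pi_a"); check_fraction(pi_b, "pi_b")
  check_fraction(pi_shared, "pi_shared")
  if (pi_a + pi_b + pi_shared > 1) {
    stop_config("pi_shared", "pi_a + pi_b + pi_shared must be <= 1")
  }
  check_fraction(sign_concordance, "sign_concordance")
  check_fraction(h2_a, "h2_a"); check_fraction(h2_b, "h2_b")
  seed <- check_count(seed, "seed", min = 0)
  structure(list(m_snps = m_snps, n1 = n1, n2 = n2, maf_range = maf_range,
                 block_size = block_size, block_rho = block_rho,
                 pi_a = pi_a, pi_b = pi_b, pi_shared = pi_shared,
                 sign_concordance = sign_concordance,
                 h2_a = h2_a, h2_b = h2_b, seed = seed),
            class = "simulation_config")
}

#' Construct a genotype panel
#'
#' A genotype panel couples an n x m dosage matrix (counts of the effect
#' allele, in `{0, 1, 2}` or `NA` for missing) with its variant map.  It is
#' the source of LD (r-squared), LD scores, and the genomic relationship
#' matrix, standing in for an external LD reference such as 1000 Genomes EUR.
#'
#' @param dosages numeric n x m matrix, entries in `[0, 2]` or `NA`.
#' @param variants data.frame with columns `id`, `chr` (1-22), `pos`
#'   (1-based bp, strictly increasing within chromosome), `a1` (effect
#'   allele), `a2` (other allele), `freq` (effect-allele frequency in (0,1));
#'   optional columns (e.g. `info`, `block`) are preserved.
#' @param sample_ids character vector of row identifiers.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    stop("column count of `dosages` must equal the variant count", call. = FALSE)
  }
  req <- c("id", "chr", "pos", "a1", "a2", "freq")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant map lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(variants$id)) stop("duplicate variant ids", call. = FALSE)
  for (cc in unique(variants$chr)) {
    p <- variants$pos[variants$chr == cc]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", cc,
           call. = FALSE)
    }
  }
  if (any(variants$freq <= 0 | variants$freq >= 1)) {
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  rownames(dosages) <- NULL
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = as.data.frame(variants),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d variants, %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chr))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

# AR(1) latent Gaussian vectors for one block: z1 = e1, zi = rho z_{i-1} +
# sqrt(1-rho^2) ei, so cor(zi, zj) = rho^|i-j| exactly.
ar1_latent <- function(n, k, rho) {
  z <- matrix(stats::rnorm(n * k), n, k)
  if (rho > 0 && k > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:k) z[, j] <- rho * z[, j - 1L] + s * z[, j]
  }
  z
}

#' Simulate the variant map of a synthetic genome
#'
#' Draws allele frequencies, a block structure, positions, and allele pairs —
#' everything about the variants except individual genotypes.  Deterministic
#' given `config$seed` and independent of the sample sizes, so summary
#' statistics simulated at biobank scale and a small LD reference panel built
#' from the same config share an identical map.  Variants are laid on a
#' synthetic genome (blocks spread over up to 22 chromosomes) with 10 kb
#' spacing inside blocks and at least 1 Mb between blocks, so a 1 Mb clumping
#' window spans a block but not its neighbours.
#'
#' @param config a [simulation_config()].
#' @return data.frame with `id`, `chr`, `pos`, `a1`, `a2`, `freq`, `block`.
#' @export
simulate_variant_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$m_snps
  with_seed(config$seed, {
    freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    nblock <- ceiling(m / config$block_size)
    block_id <- rep(seq_len(nblock), each = config$block_size)[seq_len(m)]
    rho_of_block <- if (length(config$block_rho) == 2L) {
      stats::runif(nblock, config$block_rho[1], config$block_rho[2])
    } else rep(config$block_rho, nblock)
    chr_of_block <- sort(rep_len(seq_len(min(22L, nblock)), nblock))
    pos <- integer(m); chr <- integer(m)
    for (b in seq_len(nblock)) {
      idx <- which(block_id == b)
      prior <- sum(chr_of_block[seq_len(b - 1L)] == chr_of_block[b])
      base <- prior * (1e6 + config$block_size * 1e4) + 1
      pos[idx] <- as.integer(base + (seq_along(idx) - 1L) * 1e4)
      chr[idx] <- chr_of_block[b]
    }
    # avoid strand-ambiguous (A/T, C/G) pairs: harmonization would have to
    # drop them, and real post-QC imputation panels are aligned anyway
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a1 <- sample(names(comp), m, replace = TRUE)
    a2 <- vapply(a1, function(x) {
      sample(setdiff(names(comp), c(x, comp[[x]])), 1L)
    }, "")
    data.frame(id = sprintf("rs%d_%d", chr, pos), chr = chr, pos = pos,
               a1 = a1, a2 = unname(a2), freq = freq, block = block_id,
               rho = rho_of_block[block_id], stringsAsFactors = FALSE)
  })
}

#' Simulate a block-LD genotype panel
#'
#' Hard-call dosages are generated per LD block from a latent Gaussian copula
#' with AR(1) correlation `block_rho^|i-j|`: each of the two haplotypes per
#' individual gets an independent latent vector, and the allele is called when
#' the latent value falls below the allele-frequency quantile, so genotypes
#' satisfy Hardy-Weinberg proportions marginally while adjacent variants are
#' correlated.  Blocks are mutually independent.  The variant map comes from
#' [simulate_variant_map()] and depends only on the config seed, not on
#' `n_samples`.
#'
#' @param config a [simulation_config()].
#' @param n_samples panel size; defaults to `max(n1, n2)`.  An LD reference
#'   panel does not need GWAS-scale n — a few hundred to a few thousand
#'   samples give stable r-squared.
#' @return a [genotype_panel()] whose variant map carries a `block` column.
#' @export
simulate_ld_genotypes <- function(config, n_samples = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$m_snps
  n <- if (is.null(n_samples)) max(config$n1, config$n2) else
    check_count(n_samples, "n_samples", min = 2)
  variants <- simulate_variant_map(config)
  with_seed(config$seed + 1000003L, {
    thr <- stats::qnorm(variants$freq)
    dos <- matrix(0L, n, m)
    for (idx in split(seq_len(m), variants$block)) {
      k <- length(idx)
      rho <- variants$rho[idx[1]]
      h1 <- ar1_latent(n, k, rho)
      h2 <- ar1_latent(n, k, rho)
      dos[, idx] <- (h1 < rep(thr[idx], each = n)) + (h2 < rep(thr[idx], each = n))
    }
    genotype_panel(dos, variants)
  })
}

# Block AR(1) correlation matrix rho^|i-j| (always positive definite for
# |rho| < 1).
ar1_cor <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))
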