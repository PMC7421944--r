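#' Variant QC thresholds
#'
#' Standard imputation-era GWAS quality-control thresholds: variants are
#' removed when the imputation info score is below `min_info`, the minor
#' allele frequency is below `min_maf`, the missing-call rate exceeds
#' `max_missing`, or the exact Hardy-Weinberg test p-value falls below
#' `hwe_p_floor`.
#'
#' @param min_info,min_maf,max_missing,hwe_p_floor numeric thresholds in (0,1).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.5, min_maf = 0.05,
                          max_missing = 0.05, hwe_p_floor = 1e-6) {
  for (f in c("min_info", "min_maf", "max_missing", "hwe_p_floor")) {
    check_fraction(get(f), f, 0, 1, lo_open = TRUE, hi_open = TRUE)
  }
  structure(list(min_info = min_info, min_maf = min_maf,
                 max_missing = max_missing, hwe_p_floor = hwe_p_floor),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic variant: conditional on the observed
#' allele counts, sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are computed with the standard stable recurrence over
#' heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts (total >= 1).
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  nA <- 2 * n_AA + n_Aa           # count of the rarer-or-not allele A
  na <- 2 * n_aa + n_Aa
  n_rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  # start from the largest possible het count and recurse downward:
  # P(h-2)/P(h) = h*(h-1) / ((nr-h+2)(nc-h+2)) with nr+nc = 2n allele counts
  h_max <- n_rare
  i_max <- length(hets)
  probs[i_max] <- 1
  if (i_max > 1) {
    for (i in seq(i_max, 2)) {
      h <- hets[i]
      num <- h * (h - 1)
      den <- (n_rare - h + 2) * (max(nA, na) - h + 2)
      probs[i - 1] <- probs[i] * num / den
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts",
                         call. = FALSE)
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

# vectorized HWE p over dosage columns (0/1/2 with NA allowed)
hwe_p_columns <- function(dos) {
  apply(dos, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))
  })
}

#' Filter a genotype panel on QC thresholds
#'
#' Applies the info-score, MAF, missingness, and exact-HWE filters in that
#' fixed order; each removed variant is logged with the first failing rule.
#' Boundary values are kept (the rules are strict inequalities: removal when
#' info < `min_info`, MAF < `min_maf`, missingness > `max_missing`,
#' HWE p < `hwe_p_floor`).  MAF, missingness, and HWE are computed in-sample.
#'
#' @param panel a [genotype_panel()]; an `info` column in the variant map is
#'   used when present.
#' @param thresholds a [qc_thresholds()].
#' @return list with `panel` (filtered) and `log` (data.frame of removed
#'   variant ids and reason codes `"info"`, `"maf"`, `"missing"`, `"hwe"`).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(thresholds, "qc_thresholds"))
  if (ncol(panel$dosages) == 0) stop("empty panel", call. = FALSE)
  dos <- panel$dosages
  n_nonmiss <- colSums(!is.na(dos))
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  missing_rate <- 1 - n_nonmiss / nrow(dos)
  reason <- rep(NA_character_, ncol(dos))
  if (!is.null(panel$variants$info)) {
    reason[is.na(reason) & panel$variants$info < thresholds$min_info] <- "info"
  }
  reason[is.na(reason) & maf < thresholds$min_maf] <- "maf"
  reason[is.na(reason) & missing_rate > thresholds$max_missing] <- "missing"
  todo <- which(is.na(reason))
  if (length(todo)) {
    hwe_p <- hwe_p_columns(dos[, todo, drop = FALSE])
    reason[todo[!is.na(hwe_p) & hwe_p < thresholds$hwe_p_floor]] <- "hwe"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("empty panel after QC", call. = FALSE)
  log <- data.frame(id = panel$variants$id[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  out <- genotype_panel(dos[, keep, drop = FALSE],
                        panel$variants[keep, , drop = FALSE], panel$sample_ids)
  list(panel = out, log = log)
}

# residualize the columns of M on covariate matrix X (with intercept) via QR
residualize <- function(M, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  qr.resid(qr_x, M)
}

# expand a covariate data.frame into a numeric model matrix with intercept;
# character/factor columns become indicator contrasts
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = df)
}

#' Covariate-adjusted per-variant association scan
#'
#' Ordinary least squares of the phenotype on each dosage column, controlling
#' for covariates.  Implemented by the Frisch-Waugh-Lovell identity:
#' phenotype and dosages are residualized on the covariates, the per-variant
#' slope is the simple regression of the residuals, and degrees of freedom are
#' those of the full multiple regression (`n - k - 1` with `k` fitted
#' covariate columns), so the result equals the full model exactly.
#'
#' @param panel a [genotype_panel()].
#' @param phenotype numeric vector, no missing values.
#' @param covariates data.frame of covariates (categorical columns expanded
#'   to indicators) or `NULL` for intercept only.
#' @param adjust_for optional named numeric vector/one-column data.frame
#'   appended to the covariates (e.g. whole-brainstem volume when scanning a
#'   regional volume).
#' @param block_cols number of dosage columns processed per block (memory
#'   control only; no effect on results).
#' @return a [sumstats()] table with `beta`, `se`, `z`, `p`, `n`; variants
#'   with constant dosage get `NA` statistics and reason code in the
#'   `note` column.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL, adjust_for = NULL,
                     block_cols = 2000L) {
  stopifnot(inherits(panel, "genotype_panel"))
  y <- as.numeric(phenotype)
  n <- nrow(panel$dosages)
  if (length(y) != n || anyNA(y)) {
    stop("phenotype must be complete and match the panel sample count", call. = FALSE)
  }
  covdf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  if (!is.null(adjust_for)) {
    extra <- as.data.frame(adjust_for)
    if (is.null(covdf)) covdf <- extra else covdf <- cbind(covdf, extra)
  }
  X <- covariate_matrix(covdf, n)
  k <- qr(X)$rank
  df_resid <- n - k - 1L
  if (df_resid < 1) stop("not enough residual degrees of freedom", call. = FALSE)
  y_res <- drop(residualize(y, X))
  m <- ncol(panel$dosages)
  beta <- se <- rep(NA_real_, m)
  note <- rep(NA_character_, m)
  ssy <- sum(y_res^2)
  for (start in seq(1L, m, by = block_cols)) {
    idx <- start:min(start + block_cols - 1L, m)
    G <- panel$dosages[, idx, drop = FALSE]
    if (anyNA(G)) {
      # mean-impute missing dosages for the scan (pairwise-complete slope
      # would break the FWL identity); missingness should be handled by QC
      mu <- colMeans(G, na.rm = TRUE)
      na_idx <- which(is.na(G), arr.ind = TRUE)
      G[na_idx] <- mu[na_idx[, 2]]
    }
    const <- apply(G, 2, function(g) stats::var(g) == 0)
    G_res <- residualize(G, X)
    ssx <- colSums(G_res^2)
    bad <- const | ssx <= 0
    b <- colSums(G_res * y_res) / ssx
    rss <- ssy - b^2 * ssx
    s <- sqrt(pmax(rss, 0) / df_resid / ssx)
    b[bad] <- NA_real_; s[bad] <- NA_real_
    beta[idx] <- b; se[idx] <- s
    note[idx][bad] <- "constant dosage"
  }
  tstat <- beta / se
  p <- floor_p(2 * stats::pt(-abs(tstat), df_resid))
  v <- panel$variants
  out <- data.frame(id = v$id, chr = v$chr, pos = v$pos, a1 = v$a1, a2 = v$a2,
                    freq = colMeans(panel$dosages, na.rm = TRUE) / 2,
                    beta = beta, se = se, z = tstat, p = p, n = n,
                    note = note, stringsAsFactors = FALSE)
  # constant-dosage rows keep NA statistics with a reason code, so the class
  # is attached directly rather than through the finite-p validator
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`.
#'
#' @param ss a [sumstats()] table (or numeric z vector).
#' @return numeric scalar.
#' @export
lambda_gc <- function(ss) {
  z <- if (is.numeric(ss)) ss else ss$z
  stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Discovery-to-replication concordance of lead variants
#'
#' Matches discovery lead variants into a replication scan by chromosome,
#' position, and allele pair (flipping the replication z when the effect and
#' other alleles are swapped), then reports the number with the same effect
#' direction, a one-sided exact binomial sign-test p-value against 0.5, and
#' counts reaching nominal (p < 0.05) and genome-wide (p < 5e-8)
#' significance in the replication scan.
#'
#' @param discovery_leads [sumstats()] subset of lead variants.
#' @param replication [sumstats()] table for the replication sample.
#' @return an object of class `replication_report`.
#' @export
replication_concordance <- function(discovery_leads, replication) {
  d <- as.data.frame(discovery_leads); r <- as.data.frame(replication)
  key <- function(x) paste(x$chr, x$pos, sep = ":")
  j <- match(key(d), key(r))
  ok <- !is.na(j)
  z_rep <- rep(NA_real_, nrow(d)); p_rep <- rep(NA_real_, nrow(d))
  for (i in which(ok)) {
    ri <- r[j[i], ]
    if (ri$a1 == d$a1[i] && ri$a2 == d$a2[i]) {
      z_rep[i] <- ri$z
    } else if (ri$a1 == d$a2[i] && ri$a2 == d$a1[i]) {
      z_rep[i] <- -ri$z
    } else {
      ok[i] <- FALSE; next
    }
    p_rep[i] <- ri$p
  }
  if (!any(ok)) stop("no discovery leads matchable in the replication scan",
                     call. = FALSE)
  zd <- d$z[ok]; zr <- z_rep[ok]; pr <- p_rep[ok]
  n_leads <- sum(ok)
  n_same <- sum(sign(zd) == sign(zr))
  sign_p <- stats::binom.test(n_same, n_leads, p = 0.5,
                              alternative = "greater")$p.value
  structure(list(n_leads = n_leads, n_same_direction = n_same,
                 sign_test_p = sign_p,
                 n_nominal = sum(pr < 0.05),
                 n_gws = sum(pr < 5e-8),
                 unmatched = d$id[!ok]),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("Replication concordance: %d/%d leads same direction (sign-test p = %.3g)\n",
              x$n_same_direction, x$n_leads, x$sign_test_p))
  cat(sprintf("  replication p < 0.05: %d   p < 5e-8: %d\n", x$n_nominal, x$n_gws))
  if (length(x$unmatched)) cat(sprintf("  unmatched leads: %d\n", length(x$unmatched)))
  invisible(x)
}
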