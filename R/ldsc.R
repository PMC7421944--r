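#' Per-variant LD scores from a reference panel
#'
#' `l_j = sum_k r2_adj(j, k)` over variants within `window_bp` of variant j
#' (including j itself), with the finite-reference bias adjustment
#' `r2_adj = r2 - (1 - r2) / (n_ref - 2)`.
#'
#' @param panel a [genotype_panel()] with sorted positions.
#' @param window_bp window in base pairs (default 1 Mb).
#' @return data.frame of class `ld_score_table` with `id`, `chr`, `pos`, `l`;
#'   attributes `window_bp` and `n_ref`.
#' @export
ld_scores <- function(panel, window_bp = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_ref <- nrow(panel$dosages)
  if (n_ref < 3) stop("reference panel needs at least 3 samples", call. = FALSE)
  v <- panel$variants
  m <- nrow(v)
  l <- numeric(m)
  Xs <- scale(panel$dosages)
  for (cc in unique(v$chr)) {
    idx <- which(v$chr == cc)
    pos <- v$pos[idx]
    # sliding window over sorted positions
    lo <- 1L
    for (a in seq_along(idx)) {
      while (pos[a] - pos[lo] > window_bp) lo <- lo + 1L
      hi <- a
      while (hi < length(idx) && pos[hi + 1L] - pos[a] <= window_bp) hi <- hi + 1L
      js <- idx[lo:hi]
      r2 <- drop(crossprod(Xs[, idx[a]], Xs[, js]) / (n_ref - 1))^2
      l[idx[a]] <- sum(r2 - (1 - r2) / (n_ref - 2))
    }
  }
  out <- data.frame(id = v$id, chr = v$chr, pos = v$pos, l = l,
                    stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  attr(out, "n_ref") <- n_ref
  class(out) <- c("ld_score_table", "data.frame")
  out
}

# match sumstats to ld table, returning aligned indices
match_ld <- function(ss, ld) {
  j <- match(ss$id, ld$id)
  ok <- !is.na(j) & !is.na(ss$z)
  if (sum(ok) < 200) stop("fewer than 200 variants matched to LD scores",
                          call. = FALSE)
  list(ss_idx = which(ok), ld_idx = j[ok])
}

# weighted LS slope/intercept of y on x with weights w; returns c(int, slope)
wls <- function(x, y, w) {
  W <- sum(w); mx <- sum(w * x) / W; my <- sum(w * y) / W
  slope <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

#' SNP heritability by LD-score regression
#'
#' Weighted regression of the chi-square statistic `z^2` on the LD score:
#' `E[chi2_j] = 1 + N h2 l_j / M`, so `h2 = slope * M / N`.  Weights are
#' `1 / max(l, 1)`.  With `two_step = TRUE` the intercept is estimated on the
#' `chi2 < 30` subset and fixed for the slope regression, the standard guard
#' against large-effect variants leveraging the intercept.
#'
#' @param ss a [sumstats()] table.
#' @param ld an [ld_scores()] table.
#' @param two_step logical.
#' @return object of class `ldsc_h2`: list with `h2`, `intercept`, `m`, `n`.
#' @export
ldsc_h2 <- function(ss, ld, two_step = FALSE) {
  mm <- match_ld(ss, ld)
  chi2 <- ss$z[mm$ss_idx]^2
  l <- ld$l[mm$ld_idx]
  n <- stats::median(ss$n[mm$ss_idx])
  m <- length(chi2)
  w <- 1 / pmax(l, 1)
  if (two_step) {
    sub <- chi2 < 30
    fit1 <- wls(l[sub], chi2[sub], w[sub])
    slope <- sum(w * l * (chi2 - fit1["intercept"])) / sum(w * l^2)
    est <- c(intercept = unname(fit1["intercept"]), slope = unname(slope))
  } else {
    est <- wls(l, chi2, w)
  }
  structure(list(h2 = unname(est["slope"]) * m / n,
                 intercept = unname(est["intercept"]), m = m, n = n),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.3f, intercept = %.3f (m = %d, N = %g)\n",
              x$h2, x$intercept, x$m, x$n))
  invisible(x)
}

#' Genetic correlation by cross-trait LD-score regression
#'
#' Regresses the z-score product `z1_j z2_j` on the LD score: the slope is
#' `sqrt(N1 N2) rho_g / M`, and `rg = rho_g / sqrt(h2_1 h2_2)` with the
#' per-trait heritabilities from [ldsc_h2()] on the same LD scores and
#' weights.  The standard error of rg comes from a block jackknife over
#' contiguous variant blocks (the whole pipeline — three slopes and the ratio
#' — is recomputed leaving each block out).
#'
#' @param ss1,ss2 [sumstats()] tables (aligned to the same effect alleles, as
#'   from [harmonize_pair()]; any common variants are matched by id).
#' @param ld an [ld_scores()] table.
#' @param n_blocks jackknife blocks (default 200, auto-reduced to
#'   `ceiling(m / 100)` when fewer than 100 variants per block).
#' @return object of class `ldsc_rg`: list with `rg`, `se`, `p`, `h2_1`,
#'   `h2_2`, `gencov`, `intercepts` (3-vector), `n_blocks`, `m`; `rg` is `NA`
#'   with a flag when either heritability estimate is non-positive.
#' @export
ldsc_rg <- function(ss1, ss2, ld, n_blocks = 200L) {
  ids <- intersect(intersect(ss1$id, ss2$id), ld$id)
  if (length(ids) < 200) stop("fewer than 200 variants shared", call. = FALSE)
  i1 <- match(ids, ss1$id); i2 <- match(ids, ss2$id); il <- match(ids, ld$id)
  z1 <- ss1$z[i1]; z2 <- ss2$z[i2]; l <- ld$l[il]
  n1 <- stats::median(ss1$n[i1]); n2 <- stats::median(ss2$n[i2])
  m <- length(ids)
  n_blocks <- min(n_blocks, ceiling(m / 100))
  w <- 1 / pmax(l, 1)
  est_all <- function(keep) {
    f1 <- wls(l[keep], z1[keep]^2, w[keep])
    f2 <- wls(l[keep], z2[keep]^2, w[keep])
    fx <- wls(l[keep], (z1 * z2)[keep], w[keep])
    h2_1 <- f1["slope"] * m / n1
    h2_2 <- f2["slope"] * m / n2
    gencov <- fx["slope"] * m / sqrt(n1 * n2)
    rg <- if (h2_1 > 0 && h2_2 > 0) gencov / sqrt(h2_1 * h2_2) else NA_real_
    c(rg = unname(rg), h2_1 = unname(h2_1), h2_2 = unname(h2_2),
      gencov = unname(gencov), int1 = unname(f1["intercept"]),
      int2 = unname(f2["intercept"]), intx = unname(fx["intercept"]))
  }
  full <- est_all(rep(TRUE, m))
  block_id <- ceiling(seq_len(m) / ceiling(m / n_blocks))
  nb <- length(unique(block_id))
  jack <- vapply(unique(block_id),
                 function(b) est_all(block_id != b)["rg"], 1)
  ok <- !is.na(jack)
  se <- if (is.na(full["rg"]) || sum(ok) < 2) NA_real_ else {
    sqrt((sum(ok) - 1) / sum(ok) * sum((jack[ok] - mean(jack[ok]))^2))
  }
  p <- if (is.na(se) || se == 0) NA_real_ else 2 * stats::pnorm(-abs(full["rg"] / se))
  structure(list(rg = unname(full["rg"]), se = se, p = p,
                 h2_1 = unname(full["h2_1"]), h2_2 = unname(full["h2_2"]),
                 gencov = unname(full["gencov"]),
                 intercepts = unname(full[c("int1", "int2", "intx")]),
                 n_blocks = nb, m = m,
                 undefined = is.na(full["rg"])),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  if (x$undefined) {
    cat("LDSC rg undefined: non-positive heritability estimate\n")
  } else {
    cat(sprintf("LDSC rg = %.3f (jackknife SE %.3f, p = %.3g); h2 = %.3f / %.3f, m = %d\n",
                x$rg, x$se, x$p, x$h2_1, x$h2_2, x$m))
  }
  invisible(x)
}

#' Keep one variant per LD-pruning block
#'
#' Greedy LD pruning of summary statistics against a panel: variants are
#' grouped into connected components at `r2 >= r2_threshold` within
#' `window_bp`, and one member per component is kept per iteration (uniformly
#' at random); with `n_iter > 1` the union of kept sets across iterations is
#' summarized by selection frequency.  Used to decorrelate variants before
#' LDSC-style analyses.
#'
#' @param ss a [sumstats()] table.
#' @param panel a [genotype_panel()].
#' @param r2_threshold prune threshold (default 0.2).
#' @param window_bp pairing window (default 1 Mb).
#' @param n_iter pruning iterations (default 20).
#' @param seed seed.
#' @return list with `keep_ids` (ids kept in the first iteration) and
#'   `freq` (data.frame of id, selection frequency across iterations).
#' @export
ld_prune <- function(ss, panel, r2_threshold = 0.2, window_bp = 1e6,
                     n_iter = 20L, seed = 1L) {
  v <- panel$variants
  idx <- match(ss$id, v$id)
  ok <- !is.na(idx)
  comp <- ld_components(panel, idx[ok], r2_threshold, window_bp)
  with_seed(seed, {
    sel <- matrix(FALSE, sum(ok), n_iter)
    for (it in seq_len(n_iter)) {
      keep <- prune_indices(comp)
      sel[keep, it] <- TRUE
    }
    ids <- ss$id[ok]
    list(keep_ids = ids[sel[, 1]],
         freq = data.frame(id = ids, freq = rowMeans(sel),
                           stringsAsFactors = FALSE))
  })
}

# connected components at r2 >= threshold within window (single-linkage over
# adjacent-in-position pairs is insufficient; use full pairwise within window)
ld_components <- function(panel, cols, r2_threshold, window_bp) {
  v <- panel$variants[cols, , drop = FALSE]
  k <- length(cols)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(k)) {
    js <- which(v$chr == v$chr[i] & abs(v$pos - v$pos[i]) <= window_bp &
                  seq_len(k) > i)
    if (!length(js)) next
    r2 <- ld_r2_vec(panel, cols[i], cols[js])
    for (jj in js[!is.na(r2) & r2 >= r2_threshold]) {
      ri <- find(i); rj <- find(jj)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(k), find, 1L)
}
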