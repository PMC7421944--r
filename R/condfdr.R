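# Conditional Q-Q curves, conditional FDR, conjunctional FDR, and shared-locus
# calling for a harmonized pair of GWAS summary statistics.

# For each i, count #{j : p2_j <= p2_i  and  p1_j <= p1_i} (both inequalities
# inclusive, ties handled exactly).  O(m log m): sweep in p2 order inserting
# p1 ranks into a Fenwick tree; tie groups in p2 are inserted before querying.
count_dominated <- function(p1, p2) {
  m <- length(p1)
  r1 <- rank(p1, ties.method = "max")     # query rank: #{p1_j <= p1_i} uses max
  r1_ins <- rank(p1, ties.method = "min") # insertion uses a dense key; min/max
  # Fenwick tree over p1 ranks (use 'min' rank as key so equal p1 share a key)
  tree <- integer(m)
  add <- function(pos) {
    while (pos <= m) { tree[pos] <<- tree[pos] + 1L; pos <- pos + bitwAnd(pos, -pos) }
  }
  qry <- function(pos) {
    s <- 0L
    while (pos > 0L) { s <- s + tree[pos]; pos <- pos - bitwAnd(pos, -pos) }
    s
  }
  ord <- order(p2)
  out <- integer(m)
  i <- 1L
  while (i <= m) {
    # tie group in p2
    jmax <- i
    while (jmax < m && p2[ord[jmax + 1L]] == p2[ord[i]]) jmax <- jmax + 1L
    for (k in i:jmax) add(r1_ins[ord[k]])
    for (k in i:jmax) out[ord[k]] <- qry(r1[ord[k]])
    i <- jmax + 1L
  }
  out
}

# one variant per LD block, chosen uniformly at random
prune_indices <- function(block) {
  idx <- seq_along(block)
  keep <- vapply(split(idx, block), function(v) {
    if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
  }, 1L)
  sort(unname(keep))
}

#' Conditional Q-Q enrichment curves
#'
#' For each conditioning cutoff `c`, restricts to the stratum
#' `S(c) = {i : p2_i <= c}` and returns the empirical distribution of the
#' primary trait's p-values in that stratum: at each nominal `-log10 p1` knot
#' the curve gives `-log10` of the proportion of stratum variants with p1 at
#' or below the knot.  Under the null the curve follows the identity
#' diagonal; cross-trait enrichment makes a stratum's proportion exceed the
#' nominal value, deflecting the curve below the diagonal — successively
#' further with stricter conditioning (the leftward deflection of the
#' conventional plot orientation).  With LD blocks present, curves are
#' averaged over random-pruning iterations (one variant per block per
#' iteration).
#'
#' @param pair a [harmonize_pair()] result.
#' @param cutoffs conditioning p-value cutoffs (default the conventional
#'   `1, 0.1, 0.01, 0.001`).
#' @param grid `-log10 p1` knots for the curves.
#' @param prune_iter random-pruning iterations (1 = no averaging; pruning only
#'   has an effect when the pair carries LD blocks).
#' @param seed seed for the pruning draws.
#' @return object of class `cond_qq`: list with `grid`, a `curves` matrix
#'   (knots x cutoffs) of empirical `-log10` ECDF values (NA where a stratum
#'   is empty), `cutoffs`, and per-stratum sizes `n_stratum`.
#' @export
conditional_qq <- function(pair, cutoffs = c(1, 0.1, 0.01, 0.001),
                           grid = seq(0, 7.3, by = 0.1),
                           prune_iter = 20L, seed = 1L) {
  stopifnot(inherits(pair, "harmonized_pair"))
  prune_iter <- check_count(prune_iter, "prune_iter")
  has_ld <- length(unique(pair$block)) < length(pair$block)
  iters <- if (has_ld) prune_iter else 1L
  acc <- matrix(0, length(grid), length(cutoffs))
  cnt <- matrix(0L, length(grid), length(cutoffs))
  n_str <- numeric(length(cutoffs))
  with_seed(seed, {
    for (it in seq_len(iters)) {
      idx <- if (has_ld) prune_indices(pair$block) else seq_along(pair$p1)
      p1 <- pair$p1[idx]; p2 <- pair$p2[idx]
      for (ci in seq_along(cutoffs)) {
        s <- p1[p2 <= cutoffs[ci]]
        n_str[ci] <- n_str[ci] + length(s)
        if (!length(s)) next
        prop <- vapply(grid, function(q) mean(s <= 10^(-q)), 1)
        okk <- prop > 0
        acc[okk, ci] <- acc[okk, ci] - log10(prop[okk])
        cnt[okk, ci] <- cnt[okk, ci] + 1L
      }
    }
  })
  curves <- acc / cnt
  curves[cnt == 0L] <- NA_real_
  colnames(curves) <- paste0("p2<=", format(cutoffs))
  structure(list(grid = grid, curves = curves, cutoffs = cutoffs,
                 n_stratum = n_str / iters),
            class = "cond_qq")
}

#' @export
print.cond_qq <- function(x, ...) {
  cat("Conditional Q-Q curves at cutoffs:", paste(x$cutoffs, collapse = ", "),
      "\n  mean stratum sizes:", paste(round(x$n_stratum), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cond_qq <- function(x, ...) {
  ok <- rowSums(!is.na(x$curves)) > 0
  graphics::matplot(x$grid[ok], x$curves[ok, , drop = FALSE], type = "l",
                    lty = 1, xlab = expression(-log[10] ~ "nominal p"),
                    ylab = expression(-log[10] ~ "empirical quantile"), ...)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  graphics::legend("topleft", legend = colnames(x$curves), lty = 1,
                   col = seq_len(ncol(x$curves)), bty = "n")
  invisible(x)
}

# stratified-ECDF conditional FDR evaluated exactly at each variant's own
# (p1, p2): cFDR_i = p1_i * |S(p2_i)| / #{j in S(p2_i) : p1_j <= p1_i},
# with pi0 = 1, clipped to [p1_i, 1]
cfdr_pointwise <- function(p1, p2) {
  s_size <- rank(p2, ties.method = "max")   # |{j : p2_j <= p2_i}|
  dom <- count_dominated(p1, p2)
  pmin(1, p1 * s_size / dom)
}

# build the grid lookup table from one pruned subset
cfdr_table_once <- function(p1, p2, grid1, grid2) {
  q1 <- 10^(-grid1); q2 <- 10^(-grid2)
  tab <- matrix(NA_real_, length(grid1), length(grid2))
  for (j in seq_along(q2)) {
    s <- p1[p2 <= q2[j]]
    ns <- length(s)
    if (!ns) next
    cnt <- vapply(q1, function(q) sum(s <= q), 1L)
    tab[, j] <- ifelse(cnt > 0, pmin(1, q1 * ns / cnt), 1)
  }
  tab
}

# enforce non-increase along increasing -log10 p on both axes (running min)
enforce_monotone <- function(tab) {
  for (j in seq_len(ncol(tab))) {
    col <- tab[, j]
    ok <- !is.na(col)
    col[ok] <- cummin(col[ok])
    tab[, j] <- col
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    ok <- !is.na(row)
    row[ok] <- cummin(row[ok])
    tab[i, ] <- row
  }
  tab
}

# bilinear interpolation of log10(table) at (-log10 p1, -log10 p2), clamped to
# the grid hull
interp_table <- function(tab, grid1, grid2, x1, x2) {
  lx <- log10(pmax(tab, 1e-320))
  f <- function(v, knots) {
    v <- pmin(pmax(v, knots[1]), knots[length(knots)])
    hi <- pmax(2L, findInterval(v, knots, rightmost.closed = TRUE) + 1L)
    hi <- pmin(hi, length(knots))
    lo <- hi - 1L
    w <- (v - knots[lo]) / (knots[hi] - knots[lo])
    list(lo = lo, hi = hi, w = w)
  }
  a <- f(x1, grid1); b <- f(x2, grid2)
  v00 <- lx[cbind(a$lo, b$lo)]; v10 <- lx[cbind(a$hi, b$lo)]
  v01 <- lx[cbind(a$lo, b$hi)]; v11 <- lx[cbind(a$hi, b$hi)]
  out <- (1 - a$w) * (1 - b$w) * v00 + a$w * (1 - b$w) * v10 +
    (1 - a$w) * b$w * v01 + a$w * b$w * v11
  10^out
}

#' Conditional FDR of one trait given another
#'
#' The conditional FDR of variant i for the primary trait is the stratified
#' empirical estimate `cFDR(p1 | p2) = p1 * |S(p2)| / #{j in S(p2): p1_j <=
#' p1}` with `S(p2) = {j : p2_j <= p2}` and the null proportion fixed at 1
#' (conservative); values are clipped to `[p1, 1]`.  With `prune_iter = 1`
#' the estimate is evaluated exactly at each variant's own `(p1, p2)` (the
#' direct counting formula).  With `prune_iter > 1` and LD blocks present, a
#' lookup table on a `-log10` grid is built per random-pruning iteration
#' (one variant per block), averaged, made monotone non-increasing along both
#' axes, and bilinearly interpolated in `-log10` space to every variant.
#'
#' @param pair a [harmonize_pair()] result.
#' @param which 1 to condition trait 1 on trait 2, 2 for the reverse.
#' @param grid1 `-log10 p` knots for the primary axis.
#' @param grid2 `-log10 p` knots for the conditioning axis (defaults to the
#'   conventional cutoffs 1, 0.1, 0.01, 0.001 plus half-decade knots and the
#'   primary-axis extent).
#' @param prune_iter random-pruning iterations (default 20).
#' @param seed seed for the pruning draws.
#' @return object of class `cond_fdr`: list with `fdr` (per-variant values),
#'   `table` (the grid lookup), `grid1`, `grid2`, `lambda` = NULL (inflation
#'   handled upstream), `prune_iter`, `which`.
#' @export
cond_fdr <- function(pair, which = 1, grid1 = seq(0, 7.3, by = 0.1),
                     grid2 = NULL, prune_iter = 20L, seed = 1L) {
  stopifnot(inherits(pair, "harmonized_pair"), which %in% c(1, 2))
  if (which == 2) pair <- swap_pair(pair)
  prune_iter <- check_count(prune_iter, "prune_iter")
  p1 <- pair$p1; p2 <- pair$p2
  if (is.null(grid2)) grid2 <- sort(unique(c(seq(0, 3, by = 0.5), max(grid1))))
  has_ld <- length(unique(pair$block)) < length(pair$block)
  use_grid <- prune_iter > 1L && has_ld
  tabs <- with_seed(seed, {
    iters <- if (use_grid) prune_iter else 1L
    lapply(seq_len(iters), function(it) {
      idx <- if (use_grid) prune_indices(pair$block) else seq_along(p1)
      cfdr_table_once(p1[idx], p2[idx], grid1, grid2)
    })
  })
  tab <- apply(simplify2array(tabs), c(1, 2), mean, na.rm = TRUE)
  tab[is.nan(tab)] <- NA_real_
  # empty conditioning strata inherit the next coarser knot's values
  widened <- FALSE
  for (j in seq(2, ncol(tab))) {
    nas <- is.na(tab[, j])
    if (any(nas)) { tab[nas, j] <- tab[nas, j - 1L]; widened <- TRUE }
  }
  if (widened && use_grid) {
    warning("empty conditioning strata widened to the next coarser knot")
  }
  tab <- enforce_monotone(tab)
  fdr <- if (use_grid) {
    interp_table(tab, grid1, grid2, -log10(p1), -log10(p2))
  } else {
    cfdr_pointwise(p1, p2)
  }
  fdr <- pmin(1, pmax(fdr, p1))
  structure(list(fdr = fdr, table = tab, grid1 = grid1, grid2 = grid2,
                 prune_iter = if (use_grid) prune_iter else 1L, which = which),
            class = "cond_fdr")
}

#' @export
print.cond_fdr <- function(x, ...) {
  cat(sprintf("Conditional FDR (trait %d | other): %d variants, min = %.3g, %d pruning iteration(s)\n",
              x$which, length(x$fdr), min(x$fdr), x$prune_iter))
  invisible(x)
}

#' Conjunctional FDR of a harmonized pair
#'
#' The per-variant maximum of the two reciprocal conditional FDRs; a small
#' value indicates joint association with both traits.  Symmetric in trait
#' order by construction.
#'
#' @inheritParams cond_fdr
#' @return object of class `conj_fdr`: list with `fdr` (per-variant maxima),
#'   `cfdr12`, `cfdr21` (the two [cond_fdr()] objects).
#' @export
conj_fdr <- function(pair, grid1 = seq(0, 7.3, by = 0.1), grid2 = NULL,
                     prune_iter = 20L, seed = 1L) {
  c12 <- cond_fdr(pair, 1, grid1, grid2, prune_iter, seed)
  c21 <- cond_fdr(pair, 2, grid1, grid2, prune_iter, seed)
  structure(list(fdr = pmax(c12$fdr, c21$fdr), cfdr12 = c12, cfdr21 = c21),
            class = "conj_fdr")
}

#' @export
print.conj_fdr <- function(x, ...) {
  cat(sprintf("Conjunctional FDR: %d variants, %d below 0.05, %d below 0.01\n",
              length(x$fdr), sum(x$fdr < 0.05), sum(x$fdr < 0.01)))
  invisible(x)
}

#' Shared loci at a conjunctional FDR threshold
#'
#' Runs the locus-definition machinery with the conjunctional FDR in place of
#' the p-value (significance = conjFDR below `threshold`), takes the variant
#' with the smallest conjFDR as each locus' lead, and reports the effect
#' direction `sign(z1 * z2)` at the lead together with the fraction of loci
#' where the two traits agree in direction.
#'
#' @param pair a [harmonize_pair()] result.
#' @param conjfdr a [conj_fdr()] object (or numeric vector aligned with the
#'   pair).
#' @param panel the LD [genotype_panel()] for clumping.
#' @param threshold conjunctional FDR threshold (0.05 conventional; 0.01 when
#'   correcting for five primary phenotypes).
#' @param params [clump_params()] for the locus definition (its `p_threshold`
#'   is replaced by `threshold`).
#' @return object of class `shared_locus_report`: the locus table with a
#'   `direction` column (+1 same, -1 opposite) plus `frac_same_direction`;
#'   empty table when nothing passes.
#' @export
shared_loci <- function(pair, conjfdr, panel, threshold = 0.05,
                        params = clump_params()) {
  fdr <- if (inherits(conjfdr, "conj_fdr")) conjfdr$fdr else as.numeric(conjfdr)
  stopifnot(length(fdr) == nrow(pair$variants))
  params$p_threshold <- threshold
  pseudo <- data.frame(id = pair$variants$id, chr = pair$variants$chr,
                       pos = pair$variants$pos, p = fdr,
                       stringsAsFactors = FALSE)
  loci <- define_loci(clump_independent(pseudo, panel, params), pseudo, panel,
                      params)
  if (!nrow(loci)) {
    return(structure(list(loci = loci, frac_same_direction = NA_real_,
                          threshold = threshold),
                     class = "shared_locus_report"))
  }
  lead_id <- vapply(seq_len(nrow(loci)), function(i) {
    ids <- loci$ind_ids[[i]]
    ids[which.min(fdr[match(ids, pair$variants$id)])]
  }, "")
  li <- match(lead_id, pair$variants$id)
  zz <- pair$z1[li] * pair$z2[li]
  if (any(zz == 0)) stop("zero z-score at a shared-locus lead", call. = FALSE)
  loci$lead <- lead_id
  loci$direction <- sign(zz)
  structure(list(loci = loci,
                 frac_same_direction = mean(zz > 0),
                 threshold = threshold),
            class = "shared_locus_report")
}

#' @export
print.shared_locus_report <- function(x, ...) {
  cat(sprintf("Shared loci at conjFDR < %g: %d loci, %.0f%% same effect direction\n",
              x$threshold, nrow(x$loci),
              100 * x$frac_same_direction))
  invisible(x)
}
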