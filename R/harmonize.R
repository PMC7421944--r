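# Allele harmonization, inflation control, and long-range-LD region exclusion
# for two-trait analyses.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp1 <- function(a) unname(COMPLEMENT[a])

is_ambiguous <- function(a1, a2) a2 == revcomp1(a1)  # A/T and C/G pairs

#' Built-in long-range LD exclusion regions (hg19)
#'
#' The major extended histocompatibility complex (chr6:25119106-33854733) and
#' the 8p23.1 inversion region (chr8:7242715-12483982), the two regions whose
#' intricate LD can bias empirical FDR estimation.  MAPT and APOE regions have
#' no universally printed coordinates and are supplied by the caller when
#' needed.
#'
#' @return data.frame with `chr`, `start`, `end` (1-based inclusive), `label`.
#' @export
default_exclusion_regions <- function() {
  data.frame(chr = c(6L, 8L),
             start = c(25119106L, 7242715L),
             end = c(33854733L, 12483982L),
             label = c("MHC", "8p23.1"),
             stringsAsFactors = FALSE)
}

#' Remove variants inside exclusion regions
#'
#' Bounds are 1-based inclusive: a variant at exactly `start` or `end` is
#' removed.
#'
#' @param x a [sumstats()] table or `harmonized_pair`.
#' @param regions data.frame with `chr`, `start`, `end` (see
#'   [default_exclusion_regions()]).
#' @return `x` filtered, with attribute `n_removed`.
#' @export
exclude_regions <- function(x, regions = default_exclusion_regions()) {
  if (inherits(x, "harmonized_pair")) {
    keep <- !region_hit(x$variants$chr, x$variants$pos, regions)
    out <- x
    out$variants <- x$variants[keep, , drop = FALSE]
    for (f in c("z1", "z2", "p1", "p2", "block")) out[[f]] <- x[[f]][keep]
    attr(out, "n_removed") <- sum(!keep)
    return(out)
  }
  keep <- !region_hit(x$chr, x$pos, regions)
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

region_hit <- function(chr, pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (chr == regions$chr[k] & pos >= regions$start[k] &
                    pos <= regions$end[k])
  }
  hit
}

#' Genomic inflation control
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`; when `lambda > 1` the z-scores are
#' divided by `sqrt(lambda)` and p-values recomputed, otherwise the input is
#' returned unchanged (no deflation).
#'
#' @param ss a [sumstats()] table with at least 1000 variants.
#' @return the corrected table with attribute `lambda`.
#' @export
genomic_inflation_correct <- function(ss) {
  if (nrow(ss) < 1000) {
    warning("fewer than 1000 variants; lambda estimate may be unstable")
  }
  lam <- lambda_gc(ss)
  out <- ss
  if (lam > 1) {
    out$z <- ss$z / sqrt(lam)
    out$p <- p_from_z(out$z)
    if (!is.null(out$se)) out$se <- ss$se * sqrt(lam)
  }
  attr(out, "lambda") <- lam
  out
}

# classify an allele pair (x1,x2) against a reference pair (a1,a2):
# "same", "swap" (flip sign), "same_rc"/"swap_rc" via reverse complement,
# or "mismatch"
match_alleles <- function(a1, a2, x1, x2) {
  if (x1 == a1 && x2 == a2) return("same")
  if (x1 == a2 && x2 == a1) return("swap")
  if (x1 == revcomp1(a1) && x2 == revcomp1(a2)) return("same_rc")
  if (x1 == revcomp1(a2) && x2 == revcomp1(a1)) return("swap_rc")
  "mismatch"
}

#' Harmonize two summary-statistics tables to shared effect alleles
#'
#' Intersects the two tables on (chromosome, position); aligns the second
#' trait's z-score to the first trait's effect allele, flipping its sign when
#' the allele pair is swapped (directly or after reverse complement);
#' strand-ambiguous variants (A/T, C/G) and allele mismatches are dropped with
#' logged reasons.  LD-block labels are attached from the panel's variant map
#' when available (`block` column), enabling random-pruning iterations
#' downstream.
#'
#' @param ss1,ss2 [sumstats()] tables.
#' @param panel optional [genotype_panel()] whose `block` column assigns LD
#'   blocks; alternatively `blocks` gives them directly.
#' @param blocks optional integer vector of block labels aligned with the
#'   harmonized variants (overrides `panel`).
#' @return object of class `harmonized_pair`: list with `variants` (id, chr,
#'   pos, a1, a2), `z1`, `z2`, `p1`, `p2`, `n1`, `n2`, `block`, and a `log`
#'   data.frame of dropped variants.
#' @export
harmonize_pair <- function(ss1, ss2, panel = NULL, blocks = NULL) {
  s1 <- as.data.frame(ss1); s2 <- as.data.frame(ss2)
  if (!nrow(s1) || !nrow(s2)) stop("empty summary statistics", call. = FALSE)
  key1 <- paste(s1$chr, s1$pos, sep = ":")
  key2 <- paste(s2$chr, s2$pos, sep = ":")
  j <- match(key1, key2)
  keep <- !is.na(j)
  if (!any(keep)) stop("no variants shared between the two tables", call. = FALSE)
  i1 <- which(keep); i2 <- j[keep]
  reason <- rep(NA_character_, length(i1))
  flip <- rep(1, length(i1))
  amb <- is_ambiguous(s1$a1[i1], s1$a2[i1])
  reason[amb] <- "strand-ambiguous"
  for (k in which(!amb)) {
    m <- match_alleles(s1$a1[i1[k]], s1$a2[i1[k]], s2$a1[i2[k]], s2$a2[i2[k]])
    if (m == "mismatch") reason[k] <- "allele-mismatch"
    else if (m %in% c("swap", "swap_rc")) flip[k] <- -1
  }
  ok <- is.na(reason)
  v <- data.frame(id = s1$id[i1[ok]], chr = s1$chr[i1[ok]], pos = s1$pos[i1[ok]],
                  a1 = s1$a1[i1[ok]], a2 = s1$a2[i1[ok]], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(v$chr, v$pos))) {
    stop("duplicate positions after harmonization", call. = FALSE)
  }
  z1 <- s1$z[i1[ok]]
  z2 <- s2$z[i2[ok]] * flip[ok]
  blk <- NULL
  if (!is.null(blocks)) {
    blk <- blocks
    if (length(blk) != nrow(v)) stop("`blocks` length mismatch", call. = FALSE)
  } else if (!is.null(panel) && !is.null(panel$variants$block)) {
    blk <- panel$variants$block[match(v$id, panel$variants$id)]
  }
  if (is.null(blk)) blk <- seq_len(nrow(v))  # no LD info: every variant its own block
  log <- data.frame(id = s1$id[i1[!ok]], reason = reason[!ok],
                    stringsAsFactors = FALSE)
  structure(list(variants = v, z1 = z1, z2 = z2,
                 p1 = floor_p(s1$p[i1[ok]]), p2 = floor_p(s2$p[i2[ok]]),
                 n1 = stats::median(s1$n[i1[ok]]), n2 = stats::median(s2$n[i2[ok]]),
                 block = blk, log = log),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %d variants, %d LD blocks, %d dropped (%s)\n",
              nrow(x$variants), length(unique(x$block)), nrow(x$log),
              if (nrow(x$log)) paste(names(table(x$log$reason)), collapse = ", ")
              else "none"))
  invisible(x)
}

# swap the two traits of a harmonized pair
swap_pair <- function(pair) {
  out <- pair
  out$z1 <- pair$z2; out$z2 <- pair$z1
  out$p1 <- pair$p2; out$p2 <- pair$p1
  out$n1 <- pair$n2; out$n2 <- pair$n1
  out
}
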