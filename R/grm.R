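#' Genomic relationship matrix
#'
#' `A_jk = (1/M) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with allele frequencies estimated in-sample; the GCTA definition with a
#' single variance component.  Missing dosages are mean-imputed (equivalent to
#' a zero contribution on the standardized scale).
#'
#' @param panel a [genotype_panel()]; all variants must be polymorphic
#'   in-sample.
#' @return object of class `grm`: list with `A` (n x n symmetric matrix),
#'   `sample_ids`, `m_snps`.
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic variant present; run qc_filter first", call. = FALSE)
  }
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  A <- tcrossprod(W) / ncol(X)
  structure(list(A = A, sample_ids = panel$sample_ids, m_snps = ncol(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples from %d variants, mean diagonal %.3f\n",
              nrow(x$A), x$m_snps, mean(diag(x$A))))
  invisible(x)
}

#' Write a GRM in the GCTA binary triplet layout
#'
#' `prefix.grm.bin` (float32 lower triangle, row-major by individual),
#' `prefix.grm.N.bin` (float32 per-pair variant counts), `prefix.grm.id`
#' (tab-separated FID/IID).
#'
#' @param grm a [compute_grm()] result.
#' @param prefix output path prefix.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$A)
  # GCTA order: for i in 1..n, entries (i, 1..i)
  vals <- unlist(lapply(seq_len(n), function(i) grm$A[i, seq_len(i)]))
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m_snps), length(vals)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#'
#' @param prefix path prefix (expects `.grm.bin`, `.grm.N.bin`, `.grm.id`).
#' @return a `grm` object (see [compute_grm()]); `m_snps` is the rounded
#'   median per-pair count.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_pairs <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", n = n_pairs, size = 4L)
  close(con)
  if (length(vals) != n_pairs) stop("GRM binary size inconsistent with id file",
                                    call. = FALSE)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nvals <- readBin(con, "numeric", n = n_pairs, size = 4L)
  close(con)
  A <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    A[i, seq_len(i)] <- vals[k:(k + i - 1L)]
    k <- k + i
  }
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  structure(list(A = A, sample_ids = ids[[2]],
                 m_snps = round(stats::median(nvals))),
            class = "grm")
}
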