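# On-disk formats: tab-separated summary statistics with header, PLINK-1
# binary genotype triplets.  Internal coordinates are 1-based inclusive
# throughout; only BED region files (clump.R) are 0-based half-open.

# canonical column names and case-insensitive aliases
SUMSTATS_ALIASES <- list(
  id = c("SNP", "RSID", "MARKERNAME", "ID"),
  chr = c("CHR", "CHROM", "CHROMOSOME"),
  pos = c("BP", "POS", "POSITION"),
  a1 = c("A1", "EFFECT_ALLELE", "EA"),
  a2 = c("A2", "OTHER_ALLELE", "OA", "NEA"),
  z = c("Z", "ZSCORE"),
  beta = c("BETA", "B", "EFFECT"),
  se = c("SE", "STDERR"),
  p = c("P", "PVAL", "PVALUE", "P_VALUE"),
  n = c("N", "NEFF", "SAMPLESIZE"),
  freq = c("FREQ", "EAF", "MAF_COL", "FRQ"),
  info = c("INFO", "IMPINFO")
)

#' Read GWAS summary statistics from a tab-separated file
#'
#' Header required; common column aliases are mapped case-insensitively
#' (e.g. `PVAL` to `P`, `BP` to `POS`).  Rows failing the invariants
#' (chromosome outside 1-22, non-positive position, non-ACGT single-base
#' alleles, p outside (0, 1]) are dropped with per-reason counts in the
#' `drop_log` attribute; `z` is derived from `beta`/`se` when absent; p-values
#' of 0 are floored at 1e-300 and counted.
#'
#' @param path file path.
#' @return a [sumstats()] table with attribute `drop_log`.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  nm_up <- toupper(names(raw))
  out <- list()
  for (canon in names(SUMSTATS_ALIASES)) {
    hit <- which(nm_up %in% SUMSTATS_ALIASES[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  req <- c("id", "chr", "pos", "a1", "a2", "p", "n")
  miss <- setdiff(req, names(out))
  if (length(miss)) {
    stop("missing required column(s): ", paste(toupper(miss), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(out$z) && (is.null(out$beta) || is.null(out$se))) {
    stop("need Z or BETA+SE columns", call. = FALSE)
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$chr <- suppressWarnings(as.integer(df$chr))
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$a1 <- toupper(df$a1); df$a2 <- toupper(df$a2)
  drop_log <- c(chr = 0L, pos = 0L, allele = 0L, p = 0L, p_floored = 0L)
  bad_chr <- is.na(df$chr) | df$chr < 1 | df$chr > 22
  bad_pos <- is.na(df$pos) | df$pos < 1
  bad_allele <- !(df$a1 %in% names(COMPLEMENT)) | !(df$a2 %in% names(COMPLEMENT)) |
    df$a1 == df$a2
  bad_p <- is.na(df$p) | df$p < 0 | df$p > 1
  floored <- !bad_p & df$p == 0
  drop_log["chr"] <- sum(bad_chr)
  drop_log["pos"] <- sum(bad_pos & !bad_chr)
  drop_log["allele"] <- sum(bad_allele & !bad_chr & !bad_pos)
  drop_log["p"] <- sum(bad_p & !bad_chr & !bad_pos & !bad_allele)
  drop_log["p_floored"] <- sum(floored)
  keep <- !(bad_chr | bad_pos | bad_allele | bad_p)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("zero valid rows in ", path, call. = FALSE)
  df$p <- floor_p(df$p)
  rownames(df) <- NULL
  ss <- sumstats(df)
  attr(ss, "drop_log") <- drop_log
  ss
}

#' Write summary statistics to the tab-separated dialect
#'
#' Columns SNP, CHR, BP, A1, A2, BETA, SE, Z, P, N (+ FREQ, INFO when
#' present), tab-delimited with header, `NA` as missing token.
#'
#' @param ss a [sumstats()] table.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  df <- as.data.frame(ss)
  cols <- c(SNP = "id", CHR = "chr", BP = "pos", A1 = "a1", A2 = "a2",
            BETA = "beta", SE = "se", Z = "z", P = "p", N = "n",
            FREQ = "freq", INFO = "info")
  present <- cols[cols %in% names(df)]
  out <- df[, present, drop = FALSE]
  names(out) <- names(present)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a PLINK-1 binary triplet
#'
#' `.bed` in SNP-major layout (magic bytes 0x6c 0x1b 0x01; two bits per
#' genotype: 00 = two copies of A1, 10 = one copy, 11 = zero copies,
#' 01 = missing), `.bim` (chr, id, cM = 0, pos, A1, A2), `.fam` with dummy
#' pedigree columns.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @export
write_plink <- function(panel, prefix) {
  v <- panel$variants
  n <- nrow(panel$dosages); m <- ncol(panel$dosages)
  utils::write.table(
    data.frame(v$chr, v$id, 0L, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$sample_ids, panel$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  # dosage (copies of A1) -> 2-bit code
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # NA -> 1
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    g <- panel$dosages[, j]
    codes <- ifelse(is.na(g), 1L, code_of[as.character(g)])
    codes <- c(codes, rep(0L, pad))
    quads <- matrix(codes, nrow = 4)
    byte_vals <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Read a PLINK-1 binary triplet into a genotype panel
#'
#' Missing genotypes become `NA` dosages (excluded pairwise from correlation
#' and GRM computations).  Allele frequencies are computed in-sample.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(fam[[2]])) {
    stop("duplicate sample ids in .fam: ",
         paste(unique(fam[[2]][duplicated(fam[[2]])]), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  sz <- file.info(bed_path)$size
  bytes_per_snp <- ceiling(n / 4)
  if (is.na(sz) || sz != 3 + bytes_per_snp * m) {
    stop(sprintf(".bed size %s inconsistent with %d samples x %d variants",
                 sz, n, m), call. = FALSE)
  }
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK-1 .bed file (magic-byte mismatch)", call. = FALSE)
  }
  # decode lookup: byte -> 4 dosages
  codes_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  lut <- matrix(0, 256, 4)
  for (b in 0:255) {
    q <- c(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4)
    lut[b + 1, ] <- codes_to_dosage[as.character(q)]
  }
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(readBin(con, "raw", bytes_per_snp))
    vals <- t(lut[bytes + 1L, , drop = FALSE])
    dos[, j] <- as.vector(vals)[seq_len(n)]
  }
  freq <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(id = bim[[2]], chr = as.integer(bim[[1]]),
                         pos = as.integer(bim[[4]]), a1 = bim[[5]],
                         a2 = bim[[6]], freq = pmin(pmax(freq, 1e-6), 1 - 1e-6),
                         stringsAsFactors = FALSE)
  genotype_panel(dos, variants, fam[[2]])
}
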