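#' Clumping parameters
#'
#' Thresholds of the four-tier locus definition: variants below `p_threshold`
#' are significant; significant variants pairwise below `r2_independent`
#' within `window_bp` are independent significant variants; independent
#' significant variants pairwise below `r2_lead` within `window_bp` are lead
#' variants; candidate variants are all panel variants with r-squared at least
#' `r2_candidate` to an independent significant variant; loci whose lead
#' variants are closer than `merge_bp` are merged.
#'
#' @param p_threshold significance threshold (default 5e-8; 1e-8 is the
#'   multiple-volume-corrected alternative).
#' @param r2_independent,r2_lead,r2_candidate r-squared thresholds.
#' @param window_bp,merge_bp window and merge distances in base pairs.
#' @return an object of class `clump_params`.
#' @export
clump_params <- function(p_threshold = 5e-8, r2_independent = 0.6,
                         r2_lead = 0.1, window_bp = 1e6, merge_bp = 250000,
                         r2_candidate = 0.6) {
  check_fraction(p_threshold, "p_threshold", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_fraction(r2_independent, "r2_independent", 0, 1, lo_open = TRUE)
  check_fraction(r2_lead, "r2_lead", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_fraction(r2_candidate, "r2_candidate", 0, 1, lo_open = TRUE)
  if (!(r2_lead < r2_independent)) {
    stop_config("r2_lead", "must satisfy 0 < r2_lead < r2_independent")
  }
  check_count(window_bp, "window_bp"); check_count(merge_bp, "merge_bp")
  structure(list(p_threshold = p_threshold, r2_independent = r2_independent,
                 r2_lead = r2_lead, window_bp = window_bp,
                 merge_bp = merge_bp, r2_candidate = r2_candidate),
            class = "clump_params")
}

#' Squared dosage correlation between two panel variants
#'
#' @param panel a [genotype_panel()].
#' @param i,j variant ids or column indices.
#' @return r-squared in `[0, 1]` (squared Pearson correlation of the dosage
#'   columns, missing genotypes dropped pairwise).
#' @export
ld_r2 <- function(panel, i, j) {
  col_of <- function(k) {
    if (is.character(k)) {
      k2 <- match(k, panel$variants$id)
      if (is.na(k2)) stop("variant not in panel: ", k, call. = FALSE)
      k2
    } else k
  }
  gi <- panel$dosages[, col_of(i)]; gj <- panel$dosages[, col_of(j)]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  if (stats::var(gi) == 0 || stats::var(gj) == 0) {
    stop("zero-variance dosage column", call. = FALSE)
  }
  stats::cor(gi, gj)^2
}

# r2 of one column against a set of columns (vectorized, pairwise-complete)
ld_r2_vec <- function(panel, i, js) {
  if (!length(js)) return(numeric(0))
  g <- panel$dosages[, i]
  G <- panel$dosages[, js, drop = FALSE]
  suppressWarnings(as.vector(stats::cor(g, G, use = "pairwise.complete.obs"))^2)
}

# order rows by ascending p with (chr, pos) tie-break
order_by_p <- function(ss) order(ss$p, ss$chr, ss$pos)

#' Greedy selection of independent significant variants
#'
#' Significant variants (p below `params$p_threshold`) are scanned in order of
#' ascending p (ties broken by chromosome then position); a variant is
#' accepted iff its r-squared with every already-accepted variant within
#' `window_bp` on the same chromosome is below `r2_independent`.  Variants
#' absent from the panel are logged and accepted as their own clump seeds.
#'
#' @param ss a [sumstats()] table (any table with `id`, `chr`, `pos`, `p`).
#' @param panel a [genotype_panel()] providing LD.
#' @param params a [clump_params()].
#' @return character vector of independent significant variant ids, with an
#'   attribute `uncovered` listing ids missing from the panel.
#' @export
clump_independent <- function(ss, panel, params = clump_params()) {
  sig <- as.data.frame(ss)[!is.na(ss$p) & ss$p < params$p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  sig <- sig[order_by_p(sig), , drop = FALSE]
  covered <- sig$id %in% panel$variants$id
  accepted <- integer(0)
  acc_ids <- character(0)
  for (i in seq_len(nrow(sig))) {
    if (!covered[i]) { acc_ids <- c(acc_ids, sig$id[i]); next }
    near <- accepted[sig$chr[accepted] == sig$chr[i] &
                     abs(sig$pos[accepted] - sig$pos[i]) <= params$window_bp]
    dependent <- FALSE
    if (length(near)) {
      r2 <- ld_r2_vec(panel, match(sig$id[i], panel$variants$id),
                      match(sig$id[near], panel$variants$id))
      dependent <- any(r2 >= params$r2_independent, na.rm = TRUE)
    }
    if (!dependent) {
      accepted <- c(accepted, i)
      acc_ids <- c(acc_ids, sig$id[i])
    }
  }
  structure(acc_ids, uncovered = sig$id[!covered])
}

#' Define genomic risk loci from independent significant variants
#'
#' Lead variants are chosen greedily by ascending p among the independent
#' significant variants, requiring pairwise r-squared below `r2_lead` within
#' `window_bp`.  Every independent significant variant is attached to the lead
#' it is dependent on (first lead in p-order with r-squared at least
#' `r2_lead` within the window, else itself).  Candidate variants are all
#' panel variants with r-squared at least `r2_candidate` to one of the locus'
#' independent significant variants within the window; locus borders span the
#' candidate positions.  Loci whose lead positions are closer than `merge_bp`
#' (same chromosome) are merged transitively.
#'
#' @param independent_ids output of [clump_independent()].
#' @param ss the summary statistics the ids came from.
#' @param panel a [genotype_panel()].
#' @param params a [clump_params()].
#' @return data.frame of class `locus_table`: one row per locus with `chr`,
#'   `start`, `end`, `lead` (semicolon-joined lead ids), `n_ind`, `n_cand`,
#'   `top_p`, and list-columns `ind_ids`, `cand_ids`.
#' @export
define_loci <- function(independent_ids, ss, panel, params = clump_params()) {
  ss <- as.data.frame(ss)
  if (!length(independent_ids)) {
    out <- data.frame(chr = integer(0), start = integer(0), end = integer(0),
                      lead = character(0), n_ind = integer(0),
                      n_cand = integer(0), top_p = numeric(0))
    out$ind_ids <- list(); out$cand_ids <- list()
    class(out) <- c("locus_table", "data.frame")
    return(out)
  }
  ind <- ss[match(independent_ids, ss$id), , drop = FALSE]
  ind <- ind[order_by_p(ind), , drop = FALSE]
  in_panel <- ind$id %in% panel$variants$id
  # greedy lead selection at r2 < r2_lead
  leads <- integer(0)
  lead_of <- integer(nrow(ind))  # index into `ind` of the lead each row joins
  for (i in seq_len(nrow(ind))) {
    near <- leads[ind$chr[leads] == ind$chr[i] &
                  abs(ind$pos[leads] - ind$pos[i]) <= params$window_bp]
    joined <- 0L
    if (length(near) && in_panel[i]) {
      r2 <- ld_r2_vec(panel, match(ind$id[i], panel$variants$id),
                      match(ind$id[near], panel$variants$id))
      hit <- which(r2 >= params$r2_lead)
      if (length(hit)) joined <- near[hit[1]]
    }
    if (joined == 0L) { leads <- c(leads, i); lead_of[i] <- i }
    else lead_of[i] <- joined
  }
  pv <- panel$variants
  locus_rows <- lapply(leads, function(ld) {
    members <- which(lead_of == ld)
    cand <- character(0)
    for (i in members) {
      if (!in_panel[i]) next
      pi_ <- match(ind$id[i], pv$id)
      js <- which(pv$chr == ind$chr[i] &
                  abs(pv$pos - ind$pos[i]) <= params$window_bp)
      r2 <- ld_r2_vec(panel, pi_, js)
      cand <- union(cand, pv$id[js[!is.na(r2) & r2 >= params$r2_candidate]])
    }
    cand <- union(cand, ind$id[members])  # every member belongs to its locus
    cpos <- c(pv$pos[match(cand, pv$id)], ind$pos[members])
    cpos <- cpos[!is.na(cpos)]
    list(chr = ind$chr[ld], lead_id = ind$id[ld], lead_pos = ind$pos[ld],
         start = min(cpos), end = max(cpos),
         ind_ids = ind$id[members], cand_ids = cand,
         top_p = min(ind$p[members]))
  })
  # transitive merge of loci with lead positions < merge_bp apart
  k <- length(locus_rows)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && locus_rows[[i]]$chr == locus_rows[[j]]$chr &&
        abs(locus_rows[[i]]$lead_pos - locus_rows[[j]]$lead_pos) < params$merge_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(k), find, 1L)
  merged <- lapply(unique(root), function(r) {
    grp <- locus_rows[root == r]
    list(chr = grp[[1]]$chr,
         start = min(vapply(grp, `[[`, 1, "start")),
         end = max(vapply(grp, `[[`, 1, "end")),
         lead = paste(vapply(grp, `[[`, "", "lead_id"), collapse = ";"),
         ind_ids = unique(unlist(lapply(grp, `[[`, "ind_ids"))),
         cand_ids = unique(unlist(lapply(grp, `[[`, "cand_ids"))),
         top_p = min(vapply(grp, `[[`, 1, "top_p")))
  })
  out <- data.frame(
    chr = vapply(merged, `[[`, 1, "chr"),
    start = vapply(merged, `[[`, 1, "start"),
    end = vapply(merged, `[[`, 1, "end"),
    lead = vapply(merged, `[[`, "", "lead"),
    n_ind = vapply(merged, function(x) length(x$ind_ids), 1L),
    n_cand = vapply(merged, function(x) length(x$cand_ids), 1L),
    top_p = vapply(merged, `[[`, 1, "top_p"),
    stringsAsFactors = FALSE
  )
  out$ind_ids <- lapply(merged, `[[`, "ind_ids")
  out$cand_ids <- lapply(merged, `[[`, "cand_ids")
  out <- out[order(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  # second pass: collapse loci whose candidate spans still overlap (sweep over
  # sorted starts, transitive through the growing union span), so the
  # per-trait loci are pairwise non-overlapping
  i <- 1L
  while (i < nrow(out)) {
    if (out$chr[i + 1L] == out$chr[i] && out$start[i + 1L] <= out$end[i]) {
      out$end[i] <- max(out$end[i], out$end[i + 1L])
      out$lead[i] <- paste(out$lead[i], out$lead[i + 1L], sep = ";")
      out$ind_ids[[i]] <- unique(c(out$ind_ids[[i]], out$ind_ids[[i + 1L]]))
      out$cand_ids[[i]] <- unique(c(out$cand_ids[[i]], out$cand_ids[[i + 1L]]))
      out$n_ind[i] <- length(out$ind_ids[[i]])
      out$n_cand[i] <- length(out$cand_ids[[i]])
      out$top_p[i] <- min(out$top_p[i], out$top_p[i + 1L])
      out <- out[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  class(out) <- c("locus_table", "data.frame")
  out
}

#' One-call locus definition
#'
#' Convenience wrapper: [clump_independent()] then [define_loci()].
#' @inheritParams define_loci
#' @inheritParams clump_independent
#' @return a `locus_table` (see [define_loci()]).
#' @export
find_loci <- function(ss, panel, params = clump_params()) {
  define_loci(clump_independent(ss, panel, params), ss, panel, params)
}

#' Merge per-trait loci into unique cross-trait regions
#'
#' Loci from different traits whose `[start, end]` intervals overlap by at
#' least one base pair (same chromosome) are merged into one unique region;
#' overlap is resolved transitively by a sweep over sorted interval starts.
#'
#' @param loci_list named list of `locus_table`s, one per trait.
#' @return data.frame with `chr`, `start`, `end`, `n_traits`, and `traits`
#'   (semicolon-joined contributing trait names).
#' @export
cross_trait_unique_loci <- function(loci_list) {
  if (is.null(names(loci_list)) || any(names(loci_list) == "")) {
    names(loci_list) <- paste0("trait", seq_along(loci_list))
  }
  rows <- do.call(rbind, lapply(names(loci_list), function(tr) {
    x <- as.data.frame(loci_list[[tr]])
    if (!nrow(x)) return(NULL)
    data.frame(chr = x$chr, start = x$start, end = x$end, trait = tr,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(chr = integer(0), start = integer(0), end = integer(0),
                      n_traits = integer(0), traits = character(0)))
  }
  rows <- rows[order(rows$chr, rows$start, rows$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    trs <- sort(unique(cur$traits))
    out[[length(out) + 1L]] <- data.frame(
      chr = cur$chr, start = cur$start, end = cur$end,
      n_traits = length(trs), traits = paste(trs, collapse = ";"),
      stringsAsFactors = FALSE)
    out
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (is.null(cur) || r$chr != cur$chr || r$start > cur$end) {
      if (!is.null(cur)) out <- flush(cur, out)
      cur <- list(chr = r$chr, start = r$start, end = r$end, traits = r$trait)
    } else {
      cur$end <- max(cur$end, r$end)
      cur$traits <- c(cur$traits, r$trait)
    }
  }
  out <- flush(cur, out)
  do.call(rbind, out)
}

#' Write loci as a BED interval file
#'
#' Internal coordinates are 1-based inclusive; BED on disk is 0-based
#' half-open, so `start - 1` and `end` are written.
#'
#' @param loci a `locus_table` or any data.frame with `chr`, `start`, `end`.
#' @param path output path.
#' @export
write_loci_bed <- function(loci, path) {
  df <- as.data.frame(loci)
  name <- df$lead %||% rep(".", nrow(df))
  bed <- data.frame(chrom = paste0("chr", df$chr), chromStart = df$start - 1L,
                    chromEnd = df$end, name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file into 1-based inclusive regions
#'
#' @param path BED file path (first three columns used; `chr` prefixes are
#'   stripped; optional fourth column becomes the label).
#' @return data.frame with `chr`, `start`, `end`, `label` (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  chr <- as.integer(sub("^chr", "", bed[[1]]))
  data.frame(chr = chr, start = bed[[2]] + 1L, end = bed[[3]],
             label = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
             stringsAsFactors = FALSE)
}
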