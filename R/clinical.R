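#' Covariate-adjusted case-control contrast for one diagnosis and volume
#'
#' Linear model `volume ~ group + sex + age + age^2 + ICV (+ site) (+ whole
#' brainstem)` on the diagnosis group versus controls imaged at a shared
#' scanner site; site enters as a fixed effect when more than one site is
#' involved.  Cohen's d is derived from the group-term t statistic:
#' `d = t (n1 + n2) / (sqrt(n1 n2) sqrt(df))`, the standard conversion for
#' adjusted models; negative d means cases have smaller volumes.
#'
#' @param cohort a `cohort_table` (see [simulate_clinical_cohort()]): columns
#'   `diagnosis`, `sex`, `age`, `icv`, `site`, and the volume columns.
#' @param diagnosis diagnosis label to contrast against `"control"`.
#' @param volume one of `"wbs"`, `"midbrain"`, `"pons"`, `"scp"`, `"medulla"`.
#' @param adjust_wbs add whole-brainstem volume as a covariate (invalid for
#'   the whole-brainstem volume itself).
#' @return one-row data.frame of class `contrast_result` with `diagnosis`,
#'   `volume`, `adjusted_for_wbs`, `beta` (mm^3, cases minus controls), `t`,
#'   `df`, `p`, `cohens_d`, `n_cases`, `n_controls`.
#' @export
group_contrast <- function(cohort, diagnosis, volume, adjust_wbs = FALSE) {
  if (adjust_wbs && volume == "wbs") {
    stop("cannot adjust the whole-brainstem contrast for whole-brainstem volume",
         call. = FALSE)
  }
  if (!volume %in% names(cohort)) stop("unknown volume: ", volume, call. = FALSE)
  if (!diagnosis %in% cohort$diagnosis) {
    stop("diagnosis not present: ", diagnosis, call. = FALSE)
  }
  cases <- cohort[cohort$diagnosis == diagnosis, , drop = FALSE]
  ctrl <- cohort[cohort$diagnosis == "control" &
                   cohort$site %in% unique(cases$site), , drop = FALSE]
  if (nrow(ctrl) < 2) {
    stop("no same-site controls for diagnosis ", diagnosis, call. = FALSE)
  }
  dat <- rbind(cases, ctrl)
  dat$group <- as.integer(dat$diagnosis == diagnosis)
  dat$age2 <- dat$age^2
  form <- stats::as.formula(paste(
    volume, "~ group + sex + age + age2 + icv",
    if (length(unique(dat$site)) > 1) "+ site" else "",
    if (adjust_wbs) "+ wbs" else ""))
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; dropped terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  tval <- sm["group", "t value"]
  df <- fit$df.residual
  n1 <- nrow(cases); n2 <- nrow(ctrl)
  d <- tval * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
  out <- data.frame(diagnosis = diagnosis, volume = volume,
                    adjusted_for_wbs = adjust_wbs,
                    beta = sm["group", "Estimate"], t = tval, df = df,
                    p = sm["group", "Pr(>|t|)"], cohens_d = d,
                    n_cases = n1, n_controls = n2,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR over a p-value vector
#'
#' Step-up procedure: q-values are the cumulative minima of `m * p / rank`
#' from the largest rank downward; the rejection set is `{q <= level}`.
#'
#' @param p p-values in (0, 1].
#' @param level FDR level (default 0.05).
#' @return list with `q` (q-values in input order) and `reject` (logical).
#' @export
bh_fdr <- function(p, level = 0.05) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= level)
}

#' Full clinical contrast matrix with pooled FDR correction
#'
#' For each diagnosis: one whole-brainstem test, four regional tests without
#' whole-brainstem adjustment, and four with it — nine tests per diagnosis
#' (99 for the conventional set of eleven diagnoses).  Benjamini-Hochberg
#' q-values are computed over the pooled matrix.  Cells whose model fails
#' are kept with `NA` statistics and the error message in `note`.
#'
#' @param cohort a `cohort_table`.
#' @param level FDR level for the rejection flag.
#' @return data.frame of class `clinical_matrix`: one row per test, ordered
#'   by (diagnosis, volume, adjustment), with `q` and `significant` columns.
#' @export
clinical_matrix <- function(cohort, level = 0.05) {
  dx <- setdiff(unique(cohort$diagnosis), "control")
  vols <- c("wbs", "midbrain", "pons", "scp", "medulla")
  rows <- list()
  for (d in dx) {
    for (v in vols) {
      for (adj in if (v == "wbs") FALSE else c(FALSE, TRUE)) {
        res <- tryCatch(group_contrast(cohort, d, v, adjust_wbs = adj),
                        error = function(e) {
                          data.frame(diagnosis = d, volume = v,
                                     adjusted_for_wbs = adj, beta = NA_real_,
                                     t = NA_real_, df = NA_integer_,
                                     p = NA_real_, cohens_d = NA_real_,
                                     n_cases = NA_integer_,
                                     n_controls = NA_integer_,
                                     stringsAsFactors = FALSE)
                        })
        res$note <- if (is.na(res$p)) "model failed" else NA_character_
        rows[[length(rows) + 1L]] <- as.data.frame(res)
      }
    }
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok], level)$q
  out$significant <- !is.na(out$q) & out$q <= level
  rownames(out) <- NULL
  class(out) <- c("clinical_matrix", "data.frame")
  out
}

#' @export
print.clinical_matrix <- function(x, ...) {
  cat(sprintf("Clinical contrast matrix: %d tests over %d diagnoses; %d significant at BH q <= 0.05\n",
              nrow(x), length(unique(x$diagnosis)), sum(x$significant)))
  NextMethod()
}
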