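#' Simulate a clinical case-control cohort of brainstem volumes
#'
#' Generates per-subject volumes of four brainstem regions (midbrain, pons,
#' superior cerebellar peduncle, medulla oblongata) plus the whole brainstem,
#' with covariate structure (sex, age, age squared, intracranial volume, and
#' scanner-site intercepts) and per-diagnosis offsets expressed in residual-SD
#' units (Cohen's d of the injected group difference).  The whole-brainstem
#' volume is the sum of the four regional volumes plus independent noise, so
#' contrasts adjusted for whole-brainstem volume genuinely differ from
#' unadjusted ones.
#'
#' @param effects data.frame with columns `diagnosis`, `volume` (one of
#'   `"wbs"`, `"midbrain"`, `"pons"`, `"scp"`, `"medulla"`), `d` (offset in
#'   residual-SD units).  Diagnoses absent from `effects` get zero offsets.
#' @param diagnoses character vector of diagnosis labels to simulate.
#' @param n_cases,n_controls subjects per diagnosis group and shared control
#'   pool size (>= 2 each).
#' @param n_sites number of scanner sites; every diagnosis and the controls
#'   are spread over all sites.
#' @param seed integer seed.
#' @return a data.frame of class `cohort_table` with columns `id`,
#'   `diagnosis` (`"control"` for controls), `sex`, `age`, `icv`, `site`, and
#'   the five volume columns in cubic millimetres.
#' @export
simulate_clinical_cohort <- function(effects = NULL,
                                     diagnoses = c("ADHD", "ASD", "BD", "MDD",
                                                   "PSYMIX", "SCZRISK", "SCZ",
                                                   "DEM", "MCI", "MS", "PD"),
                                     n_cases = 300L, n_controls = 600L,
                                     n_sites = 3L, seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases", min = 2)
  n_controls <- check_count(n_controls, "n_controls", min = 2)
  n_sites <- check_count(n_sites, "n_sites")
  vols <- c("wbs", "midbrain", "pons", "scp", "medulla")
  if (!is.null(effects)) {
    if (!all(c("diagnosis", "volume", "d") %in% names(effects))) {
      stop("`effects` needs columns diagnosis, volume, d", call. = FALSE)
    }
    bad <- setdiff(effects$volume, vols)
    if (length(bad)) stop("unknown volume name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    bad <- setdiff(effects$diagnosis, diagnoses)
    if (length(bad)) stop("unknown diagnosis name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  # approximate adult means (mm^3) and residual SDs for the four regions
  mu <- c(midbrain = 6000, pons = 14000, scp = 270, medulla = 4500)
  sd_r <- c(midbrain = 500, pons = 1400, scp = 45, medulla = 420)
  with_seed(seed, {
    groups <- c("control", diagnoses)
    n_per <- c(n_controls, rep(n_cases, length(diagnoses)))
    n <- sum(n_per)
    diagnosis <- rep(groups, n_per)
    sex <- stats::rbinom(n, 1, 0.5)
    age <- stats::runif(n, 20, 80)
    icv <- stats::rnorm(n, 1.5e6, 1.2e5)
    site <- paste0("site", rep_len(seq_len(n_sites), n))
    # covariate effects common to all regions (arbitrary but fixed loadings)
    lin <- function(w_sex, w_age, w_age2, w_icv) {
      w_sex * sex + w_age * (age - 50) + w_age2 * (age - 50)^2 +
        w_icv * (icv - 1.5e6) / 1e5 +
        stats::rnorm(n_sites, 0, 0.3)[as.integer(factor(site))]
    }
    out <- data.frame(id = sprintf("sub%05d", seq_len(n)),
                      diagnosis = diagnosis, sex = sex, age = age,
                      icv = icv, site = site, stringsAsFactors = FALSE)
    offset_of <- function(vol) {
      off <- numeric(n)
      if (!is.null(effects)) {
        sel <- effects$volume == vol
        for (k in which(sel)) {
          off[diagnosis == effects$diagnosis[k]] <- off[diagnosis == effects$diagnosis[k]] +
            effects$d[k]
        }
      }
      off
    }
    for (vol in c("midbrain", "pons", "scp", "medulla")) {
      cov_part <- lin(-0.3, -0.02, -5e-4, 0.25) * sd_r[vol]
      out[[vol]] <- mu[vol] + cov_part +
        offset_of(vol) * sd_r[vol] + stats::rnorm(n, 0, sd_r[vol])
    }
    wbs_noise_sd <- 600
    # residual SD of the sum: regional noises plus the independent wbs noise,
    # so an injected wbs offset is in true residual-SD units too
    wbs_resid_sd <- sqrt(sum(sd_r^2) + wbs_noise_sd^2)
    out$wbs <- out$midbrain + out$pons + out$scp + out$medulla +
      offset_of("wbs") * wbs_resid_sd + stats::rnorm(n, 0, wbs_noise_sd)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
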