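#' Reference eicosanoid panel with baseline plasma scales
#'
#' The 67-analyte target list of the assay: metabolite short names, their
#' biosynthesis pathway assignment(s), and — for the 41 analytes detectable
#' in baseline plasma — the published mean and SD of the healthy-control
#' plasma concentration (ng/ml) used to anchor the simulator. Detection
#' limits are synthetic (the assay's true LODs are not published): one
#' fifth of the control mean for detected analytes, 0.005 ng/ml otherwise.
#'
#' @return A data frame with columns `metabolite`, `pathway`
#'   (`"/"`-separated), `ctrl_mean`, `ctrl_sd` (`NA` for analytes not
#'   detected in plasma) and `lod`.
#' @export
reference_panel_data <- function() {
  rows <- list(
    # metabolite, pathway, ctrl_mean, ctrl_sd
    list("12-HETE", "12-LOX", 0.503, 0.524),
    list("Tetranor-12-HETE", "12-LOX", 0.029, 0.014),
    list("12-oxoETE", "12-LOX", NA, NA),
    list("14-HDoHE", "12-LOX", 0.151, 0.207),
    list("Maresin 1", "12-LOX", NA, NA),
    list("12-HEPE", "12-LOX", 0.108, 0.154),
    list("15-HETE", "15-LOX", 0.277, 0.162),
    list("15-oxoETE", "15-LOX", 0.005, 0.012),
    list("8-HETE", "15-LOX", 0.045, 0.031),
    list("14,15-LTC4", "15-LOX", NA, NA),
    list("8,15-diHETE", "15-LOX", NA, NA),
    list("LXA4", "15-LOX", NA, NA),
    list("17-HDoHE", "15-LOX", 0.214, 0.164),
    list("10,17-DiHDoHE", "15-LOX", NA, NA),
    list("7,17-dihydroxy-DPA", "15-LOX", NA, NA),
    list("15-HEPE", "15-LOX", 0.032, 0.030),
    list("13-HODE", "15-LOX", 4.394, 4.625),
    list("5-HETE", "5-LOX", 0.141, 0.058),
    list("5-oxoETE", "5-LOX", 0.011, 0.010),
    list("LTE4", "5-LOX", 0.001, 0.001),
    list("20-carboxy-LTB4", "5-LOX", NA, NA),
    list("20-hydroxy-LTB4", "5-LOX", NA, NA),
    list("LTB4", "5-LOX", NA, NA),
    list("LTC4", "5-LOX", NA, NA),
    list("LTD4", "5-LOX", NA, NA),
    list("5,15-diHETE", "5-LOX/15-LOX", NA, NA),
    list("4-HDoHE", "5-LOX", 0.102, 0.104),
    list("7-HDoHE", "5-LOX", 0.015, 0.018),
    list("RvD2", "5-LOX/15-LOX", NA, NA),
    list("5-HEPE", "5-LOX", 0.032, 0.023),
    list("RvE1", "5-LOX", NA, NA),
    list("11-HETE", "COX", 0.042, 0.039),
    list("12-HHT", "COX", 0.259, 0.348),
    list("6-keto-PGF1a", "COX", 0.014, 0.013),
    list("PGA2", "COX", 0.005, 0.005),
    list("PGE2", "COX", 0.082, 0.402),
    list("PGF2a", "COX", 0.032, 0.013),
    list("Tetranor-PGEM", "COX", 0.075, 0.102),
    list("TXB2", "COX", 0.096, 0.177),
    list("11-dhTXB2", "COX", NA, NA),
    list("15-deoxy-PGJ2", "COX", NA, NA),
    list("6,15-diketo-13,14-dihydro-PGF1a", "COX", NA, NA),
    list("PGD2", "COX", NA, NA),
    list("PGF1a", "COX", 0.013, 0.011),
    list("17-keto-DPA", "COX", 0.021, 0.043),
    list("PGF3a", "COX", 0.008, 0.010),
    list("11-HEPE", "COX", NA, NA),
    list("PGD3", "COX", NA, NA),
    list("PGE3", "COX", NA, NA),
    list("TXB3", "COX", NA, NA),
    list("9-HODE", "COX", 2.179, 1.822),
    list("9-HpODE", "COX", NA, NA),
    list("11,12-DHET", "CYP", 0.283, 0.121),
    list("11,12-EET", "CYP", 0.003, 0.004),
    list("14,15-DHET", "CYP", 0.351, 0.285),
    list("18-HETE", "CYP", 0.148, 0.116),
    list("20-HETE", "CYP", NA, NA),
    list("14,15-diHETE", "CYP", 0.103, 0.047),
    list("12,13-diHOME", "CYP", 4.328, 4.238),
    list("12,13-EpOME", "CYP", 0.414, 0.478),
    list("9,10-diHOME", "CYP", 1.548, 2.013),
    list("18-HEPE", "CYP/COX", 0.027, 0.030),
    list("5-iso-PGF2a", "AUTOX", 0.051, 0.021),
    list("9-HETE", "AUTOX", 0.031, 0.018),
    list("10-HDoHE", "AUTOX", 0.029, 0.036),
    list("9-HEPE", "AUTOX", 0.004, 0.009),
    list("8-HEPE", "AUTOX", NA, NA))
  df <- data.frame(
    metabolite = vapply(rows, `[[`, "", 1L),
    pathway = vapply(rows, `[[`, "", 2L),
    ctrl_mean = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    ctrl_sd = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    stringsAsFactors = FALSE)
  df$lod <- ifelse(is.na(df$ctrl_mean), 0.005, signif(df$ctrl_mean / 5, 1))
  df
}

SUBGROUPS <- c("control", "moderate", "severe", "severe_ocs", "severe_no_ocs")

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Concentrations are
#' log-normal: each metabolite has a baseline log-median/log-sd and a
#' stimulated per-cell release log-median/log-sd (release in ng per 10^6
#' leukocytes). The stimulated value is baseline + wbc x release, so
#' baseline subtraction and WBC normalization are exactly the right
#' corrections under the generating model. Group effects multiply the
#' release median of a target subgroup.
#'
#' @param metabolites data frame with columns `metabolite`, `pathway`
#'   (`"/"`-separated), `lod`, `base_med`, `base_sd`, `rel_med`, `rel_sd`
#'   (medians on the concentration scale, sds on the log scale).
#' @param n named integer vector `c(control=, moderate=, severe=)`, each
#'   compared group >= 2.
#' @param n_severe_ocs number of OCS users among the severe group.
#' @param wbc named list per group of `c(mean, sd)` white-blood-cell
#'   moments in 10^6/ml; draws are normal truncated at `wbc_min`.
#' @param effects data frame with columns `metabolite`, `subgroup` (one of
#'   `r paste(SUBGROUPS, collapse = ", ")`) and `fold` (> 0, 1 = null),
#'   multiplicative fold-changes on the release median; effects hitting
#'   the same cell multiply.
#' @param seed integer RNG seed.
#' @param wbc_min truncation bound for the WBC draw, 10^6/ml.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(metabolites, n = c(control = 20, moderate = 20, severe = 0),
                       n_severe_ocs = 0, wbc = NULL, effects = NULL,
                       seed = 1L, wbc_min = 0.5) {
  need <- c("metabolite", "pathway", "lod", "base_med", "base_sd",
            "rel_med", "rel_sd")
  if (!all(need %in% names(metabolites)))
    stop("metabolites needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(metabolites$metabolite)) stop("duplicate metabolite id")
  with(metabolites, {
    if (any(lod <= 0) || any(base_med <= 0) || any(rel_med <= 0))
      stop("lod and medians must be > 0")
    if (any(base_sd < 0) || any(rel_sd < 0)) stop("log-sds must be >= 0")
  })
  n <- n[c("control", "moderate", "severe")]
  if (anyNA(n)) stop("n must name control, moderate and severe")
  if (any(n < 0) || any(n > 0 & n < 2))
    stop("each included group needs >= 2 subjects")
  if (n_severe_ocs < 0 || n_severe_ocs > n[["severe"]])
    stop("n_severe_ocs out of range")
  if (is.null(wbc))
    wbc <- list(control = c(6.02, 1.46), moderate = c(7.87, 2.61),
                severe = c(7.87, 2.61))
  if (!all(c("control", "moderate", "severe") %in% names(wbc)))
    stop("wbc needs entries for control, moderate and severe")
  if (is.null(effects))
    effects <- data.frame(metabolite = character(), subgroup = character(),
                          fold = numeric(), stringsAsFactors = FALSE)
  if (!all(c("metabolite", "subgroup", "fold") %in% names(effects)))
    stop("effects needs columns metabolite, subgroup, fold")
  bad <- setdiff(effects$metabolite, metabolites$metabolite)
  if (length(bad)) stop("effect references unknown metabolite: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(effects$subgroup, SUBGROUPS)
  if (length(bad)) stop("effect references unknown subgroup: ",
                        paste(bad, collapse = ", "))
  if (any(effects$fold <= 0)) stop("fold-changes must be > 0")
  structure(list(metabolites = metabolites, n = n,
                 n_severe_ocs = as.integer(n_severe_ocs), wbc = wbc,
                 effects = effects, seed = as.integer(seed),
                 wbc_min = wbc_min),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", nrow(x$metabolites), " metabolites; n = ",
      paste(names(x$n), x$n, sep = "=", collapse = ", "),
      " (", x$n_severe_ocs, " OCS among severe); ",
      nrow(x$effects), " planted effect(s); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# log-normal parameters matching a reported arithmetic mean m and sd s:
# sigma^2 = log(1 + (s/m)^2), median = m / sqrt(1 + (s/m)^2).
lnorm_from_moments <- function(m, s) {
  cv2 <- (s / m)^2
  list(median = m / sqrt(1 + cv2), sdlog = sqrt(log(1 + cv2)))
}

#' Packaged reference simulation configuration
#'
#' A [sim_config()] mirroring the study design the package targets: the
#' full reference panel ([reference_panel_data()]), group sizes 63
#' controls / 108 mild-to-moderate / 90 severe with 44 OCS users among the
#' severe, WBC moments 6.02 +/- 1.46 (controls) and 7.87 +/- 2.61
#' (asthma) x 10^6/ml, and planted release effects reproducing the
#' reported directions: LTE4 up in OCS-naive asthmatics, 15-HETE up in
#' mild-to-moderate but down in severe disease, and COX-pathway release
#' suppressed under permanent oral corticosteroid use.
#'
#' @param seed integer RNG seed stored in the config.
#' @return A [sim_config()].
#' @export
reference_config <- function(seed = 1L) {
  pd <- reference_panel_data()
  det <- !is.na(pd$ctrl_mean)
  base_med <- base_sd <- numeric(nrow(pd))
  lp <- lnorm_from_moments(pd$ctrl_mean[det], pmax(pd$ctrl_sd[det], 1e-4))
  base_med[det] <- lp$median
  base_sd[det] <- pmax(lp$sdlog, 0.2)
  base_med[!det] <- pd$lod[!det] / 10  # mostly below LOD, as observed
  base_sd[!det] <- 1.0
  # ten analytes undetectable in circulation are released on stimulation
  # (leukotriene intermediates and minor prostanoids); the remaining 16
  # stay below the LOD even after stimulation, leaving 51 of 67
  # detectable in the stimulated supernatant
  stim_induced <- c("LTB4", "LTC4", "LTD4", "20-hydroxy-LTB4",
                    "20-carboxy-LTB4", "PGD2", "11-dhTXB2",
                    "15-deoxy-PGJ2", "20-HETE", "12-oxoETE")
  silent <- !det & !(pd$metabolite %in% stim_induced)
  rel_med <- pmax(base_med, 2 * pd$lod) / 6
  rel_med[silent] <- pd$lod[silent] / 50
  mets <- data.frame(metabolite = pd$metabolite, pathway = pd$pathway,
                     lod = pd$lod,
                     base_med = base_med, base_sd = base_sd,
                     # stimulation drives the detectable analytes above
                     # their baseline scale; release is per 10^6 cells
                     # (wbc ~ 6-8 rescales it to the concentration scale)
                     rel_med = rel_med,
                     rel_sd = 1.0, stringsAsFactors = FALSE)
  cox <- pd$metabolite[grepl("(^|/)COX($|/)", pd$pathway)]
  effects <- rbind(
    data.frame(metabolite = "LTE4", subgroup = c("moderate", "severe_no_ocs"),
               fold = 3, stringsAsFactors = FALSE),
    data.frame(metabolite = "15-HETE", subgroup = c("moderate", "severe"),
               fold = c(2, 0.7), stringsAsFactors = FALSE),
    data.frame(metabolite = "LTB4", subgroup = "severe", fold = 0.7,
               stringsAsFactors = FALSE),
    data.frame(metabolite = cox, subgroup = "severe_ocs", fold = 0.4,
               stringsAsFactors = FALSE),
    data.frame(metabolite = c("12-HHT", "11-HETE"), subgroup = "severe_no_ocs",
               fold = 0.6, stringsAsFactors = FALSE),
    data.frame(metabolite = c("PGE2", "TXB2"), subgroup = "severe_no_ocs",
               fold = 0.8, stringsAsFactors = FALSE))
  sim_config(mets, n = c(control = 63, moderate = 108, severe = 90),
             n_severe_ocs = 44, effects = effects, seed = seed)
}

#' Null two-group simulation configuration
#'
#' A small all-null config (no planted effects, negligible censoring) used
#' for calibration studies of the permutation test: `m` independent
#' log-normal metabolites, `n` controls vs `n` mild-to-moderate patients.
#'
#' @param m number of metabolites.
#' @param n subjects per group.
#' @param lod detection limit applied to every metabolite; the default sits
#'   far below the concentration scale so essentially no cell is censored.
#' @param seed integer RNG seed.
#' @return A [sim_config()].
#' @export
null_config <- function(m = 10, n = 20, lod = 1e-6, seed = 1L) {
  mets <- data.frame(
    metabolite = sprintf("M%02d", seq_len(m)),
    pathway = rep(c("COX", "5-LOX", "15-LOX", "CYP"), length.out = m),
    lod = lod, base_med = 0.1, base_sd = 0.5, rel_med = 0.1, rel_sd = 1,
    stringsAsFactors = FALSE)
  sim_config(mets, n = c(control = n, moderate = n, severe = 0), seed = seed)
}

subgroup_of <- function(samples) {
  ifelse(samples$group == "severe",
         ifelse(samples$ocs, "severe_ocs", "severe_no_ocs"),
         samples$group)
}

# per-subject x per-metabolite fold multiplier from the effect list
effect_folds <- function(config, samples) {
  mets <- config$metabolites$metabolite
  fold <- matrix(1, nrow(samples), length(mets),
                 dimnames = list(samples$subject_id, mets))
  sub <- subgroup_of(samples)
  eff <- config$effects
  for (i in seq_len(nrow(eff))) {
    rows <- switch(eff$subgroup[i],
                   severe = samples$group == "severe",
                   sub == eff$subgroup[i])
    fold[rows, eff$metabolite[i]] <-
      fold[rows, eff$metabolite[i]] * eff$fold[i]
  }
  fold
}

rtruncnorm_pos <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  out <- rnorm(n, mean, sd)
  while (any(bad <- out < lower)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic cohort
#'
#' Draws a [cohort_dataset()] from a [sim_config()]: baseline
#' concentrations log-normal per metabolite; stimulated concentration =
#' baseline + wbc x per-cell release, with the release median multiplied
#' by any applicable subgroup fold-changes; WBC truncated-normal per
#' group. Every cell below its metabolite's LOD is flagged censored and
#' its stored value set to 0 (the zero-substitution default of the
#' pipeline). Bit-reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [cohort_dataset()]. The true pre-substitution draws of
#'   censored cells are kept in attributes `truth_baseline` /
#'   `truth_stimulated` for simulation diagnostics.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n
    grp <- rep(c("control", "moderate", "severe"), times = n)
    nsub <- sum(n)
    ocs <- rep(FALSE, nsub)
    if (n[["severe"]] > 0 && config$n_severe_ocs > 0) {
      sev <- which(grp == "severe")
      ocs[sev[seq_len(config$n_severe_ocs)]] <- TRUE
    }
    wbc <- numeric(nsub)
    for (g in c("control", "moderate", "severe")) {
      rows <- grp == g
      if (any(rows))
        wbc[rows] <- rtruncnorm_pos(sum(rows), config$wbc[[g]][1],
                                    config$wbc[[g]][2], config$wbc_min)
    }
    samples <- sample_meta(sprintf("S%03d", seq_len(nsub)), grp, ocs, wbc)
    mets <- config$metabolites
    m <- nrow(mets)
    dn <- list(samples$subject_id, mets$metabolite)
    base <- matrix(rlnorm(nsub * m,
                          meanlog = rep(log(mets$base_med), each = nsub),
                          sdlog = rep(mets$base_sd, each = nsub)),
                   nsub, m, dimnames = dn)
    percell <- matrix(rlnorm(nsub * m,
                             meanlog = rep(log(mets$rel_med), each = nsub),
                             sdlog = rep(mets$rel_sd, each = nsub)),
                      nsub, m, dimnames = dn)
    percell <- percell * effect_folds(config, samples)
    stim <- base + wbc * percell   # release scales with leukocyte count
    lod <- rep(mets$lod, each = nsub)
    censor_mat <- function(v) {
      cens <- matrix(v < lod, nsub, m, dimnames = dn)
      vals <- v
      vals[cens] <- 0
      list(values = vals, censored = cens)
    }
    b <- censor_mat(base)
    s <- censor_mat(stim)
    out <- cohort_dataset(
      panel(mets$metabolite, mets$pathway, mets$lod), samples,
      concentration_matrix("baseline", b$values, b$censored),
      concentration_matrix("stimulated", s$values, s$censored))
    attr(out, "truth_baseline") <- base
    attr(out, "truth_stimulated") <- stim
    out
  })
}

#' Serialize / read a simulation configuration as JSON
#'
#' @param config a [sim_config()].
#' @param path JSON file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$n <- as.list(x$n)   # keep group names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- if (length(x$effects)) x$effects else NULL
  sim_config(x$metabolites, unlist(x$n), x$n_severe_ocs,
             lapply(x$wbc, unlist), eff, x$seed, x$wbc_min)
}
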