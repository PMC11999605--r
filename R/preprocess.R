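#' Detection filter for a two-group contrast
#'
#' A metabolite is excluded when it is below the detection limit in at
#' least `threshold` (default 80%) of the samples in *both* groups of the
#' contrast; being well measured in either group keeps it. The filter is
#' contrast-specific and is evaluated on the matrix entering the analysis
#' (stimulated supernatant for the stimulation analysis, plasma for the
#' baseline analysis).
#'
#' @param matrix a [concentration_matrix()].
#' @param groups character/factor vector, one label per row of `matrix`,
#'   with exactly two distinct labels.
#' @param threshold censored-fraction cutoff in (0, 1]; "at least" the
#'   threshold excludes, so the boundary itself is excluded.
#' @return A list with `kept` (character vector of metabolite ids) and
#'   `report` (data frame of class `filter_report`: per metabolite the
#'   censored fraction in each group, the decision and the reason).
#' @examples
#' # 8/10 censored in both groups -> excluded; 8/10 and 7/10 -> kept
#' @export
detection_filter <- function(matrix, groups, threshold = 0.8) {
  stopifnot(inherits(matrix, "conc_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  groups <- as.character(groups)
  if (length(groups) != nrow(matrix$values))
    stop("groups must have one label per sample")
  gl <- unique(groups)
  if (length(gl) != 2L) stop("exactly two groups required, got ",
                             length(gl))
  if (any(table(groups) == 0L)) stop("empty group")
  frac <- function(g) {
    cens <- matrix$censored[groups == g, , drop = FALSE]
    colMeans(cens, na.rm = TRUE)   # missing cells don't count as censored
  }
  f1 <- frac(gl[1]); f2 <- frac(gl[2])
  excluded <- !is.na(f1) & !is.na(f2) & f1 >= threshold & f2 >= threshold
  report <- data.frame(
    metabolite = colnames(matrix$values),
    frac_censored_a = unname(f1), frac_censored_b = unname(f2),
    kept = !excluded,
    reason = ifelse(excluded,
                    sprintf("censored fraction >= %.2f in both groups",
                            threshold),
                    "detected"),
    stringsAsFactors = FALSE)
  attr(report, "groups") <- gl
  attr(report, "threshold") <- threshold
  class(report) <- c("filter_report", "data.frame")
  list(kept = report$metabolite[report$kept], report = report)
}

#' Reversed Kaplan-Meier estimate for left-censored concentrations
#'
#' Left-censored data (values known only to lie below the LOD) are turned
#' into a right-censored problem by flipping the sign, the standard
#' product-limit estimator is applied via [survival::survfit()], and the
#' result is flipped back. The product-limit identifies the distribution
#' above the smallest uncensored value; the unresolved mass below the LOD
#' is placed, by convention, at the midpoint `lod/2` of the censoring
#' interval `[0, lod)` when computing means (concentrations are bounded
#' below by zero, and the data carry no information about the shape of the
#' sub-LOD tail).
#'
#' @param values numeric vector of concentrations (censored entries hold
#'   any placeholder; they are ignored).
#' @param censored logical vector, `TRUE` = below LOD.
#' @param lod the common detection limit of the metabolite, > 0.
#' @return A list: `dist` (data frame `value`, `prob` of the estimated
#'   distribution, including the sub-LOD point mass at `lod/2`), `mean`
#'   (mean of that distribution), `mean_below_lod` (conditional mean below
#'   the LOD; `NA` when no mass lies below), and `p_below_lod`.
#' @export
km_left_censored <- function(values, censored, lod) {
  stopifnot(length(values) == length(censored), lod > 0)
  keep <- !is.na(values) & !is.na(censored)
  values <- values[keep]; censored <- as.logical(censored[keep])
  if (!length(values)) stop("no data")
  if (all(censored)) stop("all values censored; product-limit undefined")
  # flip: uncensored value x -> event at -x; censored -> censoring at -lod
  time <- ifelse(censored, -lod, -values)
  event <- as.integer(!censored)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv <- summary(fit, censored = FALSE)
  ev <- surv$n.event > 0
  t_ev <- surv$time[ev]
  s_ev <- surv$surv[ev]
  mass <- -diff(c(1, s_ev))            # probability mass at each event time
  vals <- -t_ev                        # back to the concentration scale
  tail_mass <- s_ev[length(s_ev)]      # unresolved: below every event & lod
  dist <- data.frame(value = vals, prob = mass)
  if (tail_mass > 1e-12)
    dist <- rbind(dist, data.frame(value = lod / 2, prob = tail_mass))
  dist <- dist[order(dist$value), ]
  rownames(dist) <- NULL
  below <- dist$value < lod
  p_below <- sum(dist$prob[below])
  list(dist = dist,
       mean = sum(dist$value * dist$prob),
       mean_below_lod = if (p_below > 0)
         sum(dist$value[below] * dist$prob[below]) / p_below else NA_real_,
       p_below_lod = p_below)
}

#' Substitute left-censored cells
#'
#' Replaces every censored cell of a concentration matrix according to the
#' chosen scheme: `"zero"` (the pipeline default), `"half_lod"` (LOD/2),
#' or `"km"` (the metabolite's conditional mean below the LOD under the
#' reversed Kaplan-Meier distribution, see [km_left_censored()]; falls
#' back to zero with a warning for metabolites whose cells are all
#' censored). Uncensored cells are untouched; the censored mask is kept so
#' that provenance survives.
#'
#' @param matrix a [concentration_matrix()].
#' @param panel the [panel()] supplying each metabolite's LOD.
#' @param scheme `"zero"`, `"half_lod"` or `"km"`.
#' @return A [concentration_matrix()] with substituted values and an
#'   attribute `scheme`.
#' @export
substitute_censored <- function(matrix, panel,
                                scheme = c("zero", "half_lod", "km")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(matrix, "conc_matrix"), inherits(panel, "eico_panel"))
  if (!identical(colnames(matrix$values), panel$metabolite))
    stop("matrix columns do not match panel")
  vals <- matrix$values
  for (j in seq_len(ncol(vals))) {
    cj <- which(matrix$censored[, j])
    if (!length(cj)) next
    vals[cj, j] <- switch(scheme,
      zero = 0,
      half_lod = panel$lod[j] / 2,
      km = {
        obs <- !is.na(matrix$censored[, j])
        if (all(matrix$censored[obs, j])) {
          warning("all cells censored for ", panel$metabolite[j],
                  "; km falls back to zero")
          0
        } else {
          km <- km_left_censored(matrix$values[, j], matrix$censored[, j],
                                 panel$lod[j])
          km$mean_below_lod
        }
      })
  }
  out <- concentration_matrix(matrix$condition, vals, matrix$censored)
  attr(out, "scheme") <- scheme
  out
}

#' Baseline subtraction
#'
#' Cell-wise stimulated minus baseline, correcting the stimulated
#' supernatant for the subject's basal circulating eicosanoid level.
#' Negative differences (stimulated below baseline) are retained: clipping
#' would create artificial ties and distort the downstream rank tests.
#' Censored cells must already have been substituted in both matrices.
#'
#' @param stimulated,baseline aligned [concentration_matrix()] objects.
#' @return A numeric matrix of differences, ng/ml; `NA` where either cell
#'   is missing.
#' @export
baseline_subtract <- function(stimulated, baseline) {
  stopifnot(inherits(stimulated, "conc_matrix"),
            inherits(baseline, "conc_matrix"))
  if (!identical(dimnames(stimulated$values), dimnames(baseline$values)))
    stop("matrices are not aligned on (subject, metabolite)")
  stimulated$values - baseline$values
}

#' Normalize net release to the white blood cell count
#'
#' Divides each subject's row of baseline-corrected differences by that
#' subject's total white blood cell count, removing the effect of
#' differential leukocyte numbers between groups. The result is the net
#' release in ng per 10^6 leukocytes.
#'
#' @param differences matrix from [baseline_subtract()].
#' @param samples a [sample_meta()] table aligned with the matrix rows.
#' @param provenance optional list recorded on the result (e.g. the
#'   substitution scheme used upstream).
#' @return An object of class `net_release`: list with `values` (matrix,
#'   ng per 10^6 cells), the `samples` table (carried along so contrasts
#'   can select subjects) and `provenance`.
#' @export
wbc_normalize <- function(differences, samples, provenance = list()) {
  stopifnot(is.matrix(differences), inherits(samples, "sample_meta"))
  if (!identical(rownames(differences), samples$subject_id))
    stop("rows must match samples$subject_id")
  if (any(samples$wbc <= 0)) stop("non-positive wbc")
  vals <- differences / samples$wbc
  structure(list(values = vals, samples = samples,
                 provenance = c(provenance,
                                list(normalization = "per 10^6 leukocytes",
                                     unit = "ng per 10^6 cells"))),
            class = "net_release")
}

#' @export
print.net_release <- function(x, ...) {
  cat("Net release matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " metabolites, ", x$provenance$unit, "\n", sep = "")
  if (!is.null(x$provenance$scheme))
    cat("  censored-value scheme:", x$provenance$scheme, "\n")
  invisible(x)
}

#' Preprocess a cohort into a net-release matrix
#'
#' Convenience wrapper chaining [substitute_censored()] (applied uniformly
#' to both matrices), [baseline_subtract()] and [wbc_normalize()].
#'
#' @param cohort a [cohort_dataset()].
#' @param scheme censored-value substitution scheme, see
#'   [substitute_censored()].
#' @return A `net_release` object with provenance recording the scheme.
#' @export
net_release <- function(cohort, scheme = c("zero", "half_lod", "km")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cohort, "cohort_dataset"))
  stim <- substitute_censored(cohort$stimulated, cohort$panel, scheme)
  base <- substitute_censored(cohort$baseline, cohort$panel, scheme)
  wbc_normalize(baseline_subtract(stim, base), cohort$samples,
                provenance = list(scheme = scheme,
                                  baseline_corrected = TRUE))
}
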