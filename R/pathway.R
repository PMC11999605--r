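#' Build pathway membership sets for functional class scoring
#'
#' One set per enzymatic biosynthesis pathway (COX, 5-LOX, 12-LOX, 15-LOX,
#' CYP) with at least one kept member. Auto-oxidation (AUTOX) products are
#' never included: they carry no enzymatic pathway signal. Dual-annotated
#' metabolites (e.g. `5-LOX/15-LOX`) are members of every pathway they
#' carry unless `dual = "drop"`.
#'
#' @param panel an [panel()] object.
#' @param kept character vector of metabolite ids that survived the
#'   detection filter.
#' @param dual `"all"` (default) puts dual-annotated metabolites in each
#'   of their pathways; `"drop"` excludes them from scoring.
#' @return Named list of character vectors (class `pathway_sets`); empty
#'   pathways are dropped with a message.
#' @export
build_pathway_sets <- function(panel, kept, dual = c("all", "drop")) {
  dual <- match.arg(dual)
  stopifnot(inherits(panel, "eico_panel"))
  bad <- setdiff(kept, panel$metabolite)
  if (length(bad)) stop("kept ids not in panel: ", paste(bad, collapse = ", "))
  idx <- panel$metabolite %in% kept
  sets <- list()
  for (pw in setdiff(PATHWAY_LABELS, "AUTOX")) {
    has <- vapply(panel$pathways, function(p) pw %in% p, TRUE) & idx
    if (dual == "drop")
      has <- has & vapply(panel$pathways, length, 1L) == 1L
    members <- panel$metabolite[has]
    if (length(members)) sets[[pw]] <- members
    else message("pathway ", pw, " has no kept members; dropped")
  }
  structure(sets, class = "pathway_sets")
}

#' Tippett combining function
#'
#' The pathway-level statistic: the minimum of the member metabolites'
#' p-values. Smaller = stronger pathway-level signal. Under k independent
#' uniform member p-values its null CDF is `1 - (1 - t)^k`; here the null
#' is instead calibrated on the joint permutation ensemble, which
#' preserves inter-metabolite correlation.
#'
#' @param p numeric vector of member p-values, each in (0, 1].
#' @return `min(p)`.
#' @examples
#' tippett_statistic(c(0.2, 0.05, 0.5))  # 0.05
#' @export
tippett_statistic <- function(p) {
  if (!length(p)) stop("empty p-value set")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  min(p)
}

#' Pathway-level permutation tests (functional class scoring)
#'
#' Self-contained pathway inference on the same joint permutation ensemble
#' as the metabolite-level tests: for every permutation b the member
#' metabolites' per-permutation p-values (each statistic double-ranked
#' within its full ensemble distribution) are combined with the Tippett
#' function, and the pathway p-value is the fraction of permutations whose
#' combined statistic is at least as small as the observed one,
#' `(1 + #{b >= 1 : min_b <= min_obs}) / (B + 1)`. A singleton pathway
#' therefore reproduces its member's raw permutation p-value exactly, and
#' duplicated (perfectly correlated) members do not change the result.
#' Pathway p-values are then adjusted across pathways with the same
#' step-down machinery as the metabolite level.
#'
#' @param fit a [run_contrast()] result (carries the ensemble).
#' @param sets a [build_pathway_sets()] result, or a named list of member
#'   id vectors; members must have been tested in `fit`.
#' @param method multiplicity adjustment across pathways, `"minp"` or
#'   `"bh"`.
#' @return An object of class `pathway_tests`: data frame with one row per
#'   pathway (`pathway`, `n_members`, `tippett` = observed min member raw
#'   p, `p_raw`, `p_adj`).
#' @export
run_pathway_fcs <- function(fit, sets, method = c("minp", "bh")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "metabolite_tests"))
  if (!length(sets)) stop("no pathway sets")
  perm_p <- attr(fit, "perm_p")
  sets <- lapply(sets, as.character)
  bad <- setdiff(unlist(sets), rownames(perm_p))
  if (length(bad))
    stop("pathway member(s) missing from the tested ensemble: ",
         paste(bad, collapse = ", "))
  N <- ncol(perm_p)
  # per-permutation Tippett statistics, one row per pathway
  mins <- t(vapply(sets, function(members) {
    pm <- perm_p[members, , drop = FALSE]
    do.call(pmin, lapply(seq_len(nrow(pm)), function(i) pm[i, ]))
  }, numeric(N)))
  # smaller min-p = more extreme; identity column counts itself
  pw_perm_p <- t(apply(mins, 1L, function(s) rank(s, ties.method = "max") / N))
  p_raw <- pw_perm_p[, 1]
  out <- data.frame(
    pathway = names(sets), contrast = attr(fit, "contrast")$name,
    n_members = vapply(sets, length, 1L),
    tippett = mins[, 1], p_raw = unname(p_raw),
    p_adj = unname(stepdown_adjust(p_raw, pw_perm_p, method)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pathway_tests", "data.frame"),
            contrast = attr(fit, "contrast"), method = method,
            sets = sets)
}

#' Adjust pathway-level p-values
#'
#' Exposed separately for completeness; [run_pathway_fcs()] already
#' returns adjusted p-values. Re-applies the chosen step-down adjustment
#' to the `p_raw` column of a `pathway_tests` object (minP requires the
#' per-permutation pathway statistics, so it recomputes through
#' [run_pathway_fcs()] internals; `"bh"` works on the p-values alone).
#'
#' @param results a `pathway_tests` data frame.
#' @param method `"bh"` or `"minp"`.
#' @return `results` with `p_adj` replaced.
#' @export
adjust_pathways <- function(results, method = c("bh", "minp")) {
  method <- match.arg(method)
  stopifnot(inherits(results, "pathway_tests"))
  if (method == "minp")
    stop("re-adjustment with minp needs the ensemble; call ",
         "run_pathway_fcs(fit, sets, method = 'minp') instead")
  results$p_adj <- stepdown_adjust(results$p_raw, method = "bh")
  results
}

#' @export
print.pathway_tests <- function(x, ...) {
  cat("Pathway functional class scoring (Tippett) - contrast ",
      attr(x, "contrast")$name, "\n", sep = "")
  df <- as.data.frame(x)
  df$stars <- p_stars(df$p_adj)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
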