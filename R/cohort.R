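#' Sample metadata table
#'
#' One row per subject: disease group (`control`, `moderate` =
#' mild-to-moderate asthma, `severe`), oral corticosteroid (OCS) use flag,
#' and total white blood cell count in 10^6 cells/ml. OCS use is only
#' meaningful in the severe group; mild-to-moderate patients are OCS-naive
#' by design, so `group == "moderate" & ocs` is rejected.
#'
#' @param subject_id character vector of unique subject ids.
#' @param group character vector in `c("control", "moderate", "severe")`
#'   (the alias `"mild-to-moderate"` is accepted and mapped to `moderate`).
#' @param ocs logical vector, permanent OCS use.
#' @param wbc numeric vector, white blood cell count, 10^6/ml, > 0.
#' @return A `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(subject_id, group, ocs, wbc) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject_id")
  group <- as.character(group)
  group[group == "mild-to-moderate"] <- "moderate"
  bad <- setdiff(unique(group), c("control", "moderate", "severe"))
  if (length(bad)) stop("invalid group label(s): ", paste(bad, collapse = ", "))
  ocs <- as.logical(ocs)
  if (anyNA(ocs)) stop("ocs must be TRUE/FALSE")
  if (any(ocs & group == "moderate"))
    stop("mild-to-moderate subjects cannot be OCS users")
  wbc <- as.numeric(wbc)
  if (anyNA(wbc) || any(wbc <= 0)) stop("wbc must be numeric and > 0")
  out <- data.frame(subject_id = subject_id, group = group, ocs = ocs,
                    wbc = wbc, stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Concentration matrix with censoring mask
#'
#' Samples x metabolites concentrations in ng/ml together with a logical
#' mask of left-censored cells (measured below the metabolite's limit of
#' detection). Cells that were not measured at all are `NA` in both
#' `values` and `censored` — missing is distinct from censored.
#'
#' @param condition `"baseline"` (unstimulated EDTA plasma) or
#'   `"stimulated"` (supernatant of zymosan-stimulated heparinized blood).
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   with dimnames; non-missing entries must be >= 0.
#' @param censored logical matrix of the same shape.
#' @return An object of class `conc_matrix`.
#' @export
concentration_matrix <- function(condition = c("baseline", "stimulated"),
                                 values, censored) {
  condition <- match.arg(condition)
  stopifnot(is.matrix(values), is.matrix(censored),
            identical(dim(values), dim(censored)))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have subject rownames and metabolite colnames")
  if (any(values < 0, na.rm = TRUE)) stop("negative concentrations")
  if (any(is.na(values) != is.na(censored)))
    stop("missing cells must be NA in both values and censored")
  structure(list(condition = condition, values = values,
                 censored = censored),
            class = "conc_matrix")
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat("Concentration matrix (", x$condition, "): ",
      nrow(x$values), " samples x ", ncol(x$values), " metabolites; ",
      sum(x$censored, na.rm = TRUE), " censored, ",
      sum(is.na(x$values)), " missing cells\n", sep = "")
  invisible(x)
}

#' Paired cohort dataset
#'
#' Bundles a panel, sample metadata and the paired baseline/stimulated
#' concentration matrices of a whole-blood stimulation assay. Matrices are
#' aligned by construction: rows follow `samples$subject_id`, columns the
#' panel's metabolite order.
#'
#' @param panel an [panel()] object.
#' @param samples a [sample_meta()] table.
#' @param baseline,stimulated [concentration_matrix()] objects aligned with
#'   `samples` and `panel`.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(panel, samples, baseline, stimulated) {
  stopifnot(inherits(panel, "eico_panel"), inherits(samples, "sample_meta"),
            inherits(baseline, "conc_matrix"),
            inherits(stimulated, "conc_matrix"))
  if (baseline$condition != "baseline" || stimulated$condition != "stimulated")
    stop("matrix conditions do not match their slots")
  for (m in list(baseline, stimulated)) {
    if (!identical(rownames(m$values), samples$subject_id))
      stop("matrix rows must match samples$subject_id (same order)")
    if (!identical(colnames(m$values), panel$metabolite))
      stop("matrix columns must match panel metabolite order")
  }
  structure(list(panel = panel, samples = samples, baseline = baseline,
                 stimulated = stimulated),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("Cohort dataset: ", nrow(x$samples), " subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      nrow(x$panel), " metabolites\n", sep = "")
  cat("  OCS users among severe:",
      sum(x$samples$ocs & x$samples$group == "severe"), "\n")
  print(x$baseline); print(x$stimulated)
  invisible(x)
}

parse_flag <- function(x, what) {
  out <- rep(NA, length(x))
  low <- tolower(trimws(as.character(x)))
  out[low %in% c("true", "t", "1", "yes")] <- TRUE
  out[low %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("unparseable ", what, " flag: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

read_long_conc <- function(path, condition, panel, subjects) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "metabolite", "concentration", "censored")
  if (!all(need %in% names(df)))
    stop("concentration CSV must have columns ", paste(need, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  bad <- setdiff(unique(df$metabolite), panel$metabolite)
  if (length(bad))
    stop("metabolite(s) not in panel: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$subject_id), subjects)
  if (length(bad))
    stop("subject(s) in concentrations but not metadata: ",
         paste(bad, collapse = ", "))
  vals <- matrix(NA_real_, length(subjects), nrow(panel),
                 dimnames = list(subjects, panel$metabolite))
  cens <- matrix(NA, length(subjects), nrow(panel),
                 dimnames = list(subjects, panel$metabolite))
  idx <- cbind(match(df$subject_id, subjects),
               match(df$metabolite, panel$metabolite))
  if (anyDuplicated(idx))
    stop("duplicate (subject, metabolite) rows in ", path)
  vals[idx] <- as.numeric(df$concentration)
  cens[idx] <- parse_flag(df$censored, "censored")
  concentration_matrix(condition, vals, cens)
}

#' Read a cohort dataset from CSV files
#'
#' Concentrations come in long (tidy) form with columns
#' `subject_id,metabolite,concentration,censored`; metadata with columns
#' `subject_id,group,ocs,wbc`. Subjects present in the metadata but
#' lacking a concentration row for some metabolite get a missing (`NA`)
#' cell, which downstream tests drop pairwise — missing is not censored.
#'
#' @param panel an [panel()] object; metabolites absent from it are an error.
#' @param meta_path,baseline_path,stimulated_path CSV paths.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(panel, meta_path, baseline_path, stimulated_path) {
  md <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "ocs", "wbc")
  if (!all(need %in% names(md)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  samples <- sample_meta(md$subject_id, md$group,
                         parse_flag(md$ocs, "ocs"), md$wbc)
  base <- read_long_conc(baseline_path, "baseline", panel,
                         samples$subject_id)
  stim <- read_long_conc(stimulated_path, "stimulated", panel,
                         samples$subject_id)
  cohort_dataset(panel, samples, base, stim)
}

conc_to_long <- function(m) {
  keep <- !is.na(m$values)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(subject_id = rownames(m$values)[idx[, 1]],
             metabolite = colnames(m$values)[idx[, 2]],
             concentration = m$values[idx],
             censored = tolower(as.character(m$censored[idx])),
             stringsAsFactors = FALSE)
}

#' Write a cohort dataset to CSV files
#'
#' Writes `panel.csv`, `meta.csv`, `baseline.csv` and `stimulated.csv`
#' (long format) into `dir`; the files round-trip through [read_panel()]
#' and [read_cohort()].
#'
#' @param cohort a [cohort_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             meta = file.path(dir, "meta.csv"),
             baseline = file.path(dir, "baseline.csv"),
             stimulated = file.path(dir, "stimulated.csv"))
  write_panel(cohort$panel, paths[["panel"]])
  md <- cohort$samples
  md$ocs <- tolower(as.character(md$ocs))
  write.csv_plain(md, paths[["meta"]])
  write.csv_plain(conc_to_long(cohort$baseline), paths[["baseline"]])
  write.csv_plain(conc_to_long(cohort$stimulated), paths[["stimulated"]])
  invisible(paths)
}
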