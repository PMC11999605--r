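#' Significance asterisk bands
#'
#' The banding convention of the study's figures: `*` p <= 0.05, `**`
#' p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return Character vector of asterisk strings (`""` when p > 0.05).
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi <= 1e-4) "****" else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**" else if (pi <= 0.05) "*" else ""
  }, "")
}

#' Pipeline run configuration
#'
#' Either `paths` (named list/vector with `panel`, `meta`, `baseline`,
#' `stimulated` CSV paths) or `sim` (a [sim_config()] to generate the
#' cohort from) must be given, not both.
#'
#' @param paths input CSV paths, or `NULL` to simulate.
#' @param sim a [sim_config()], or `NULL` to read from `paths`.
#' @param contrasts named list of [contrast_spec()] objects; defaults to
#'   every standard contrast applicable to the data.
#' @param B number of label permutations.
#' @param seed integer seed used for ensemble construction (and recorded
#'   in the manifest).
#' @param scheme censored-value substitution scheme.
#' @param threshold detection-filter censored-fraction cutoff.
#' @param method multiplicity adjustment method.
#' @param out_dir output directory for result files, or `NULL` to skip
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(paths = NULL, sim = NULL, contrasts = NULL,
                       B = 10000, seed = 1L,
                       scheme = c("zero", "half_lod", "km"),
                       threshold = 0.8, method = c("minp", "bh"),
                       out_dir = NULL) {
  if (is.null(paths) == is.null(sim))
    stop("exactly one of paths or sim must be given")
  if (!is.null(paths)) {
    need <- c("panel", "meta", "baseline", "stimulated")
    if (!all(need %in% names(paths)))
      stop("paths must name ", paste(need, collapse = ", "))
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(paths = paths, sim = sim, contrasts = contrasts,
                 B = B, seed = as.integer(seed),
                 scheme = match.arg(scheme), threshold = threshold,
                 method = match.arg(method), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline failed in stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

# contrasts that select >= 2 subjects per arm in this cohort
applicable_contrasts <- function(samples, contrasts = standard_contrasts()) {
  Filter(function(cs) {
    length(select_subjects(samples, cs$a)) >= 2 &&
      length(select_subjects(samples, cs$b)) >= 2
  }, contrasts)
}

#' Run the full analysis pipeline
#'
#' Read or simulate -> detection filter (per contrast, on the stimulated
#' matrix) -> censored-value substitution -> baseline subtraction -> WBC
#' normalization -> per-metabolite permutation tests -> pathway functional
#' class scoring -> result files plus a reproducibility manifest. Each
#' metabolite excluded by the filter is reported via [message()] with its
#' censored fractions.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `eicoperm_run`: list with the cohort, the
#'   net-release matrix, named lists `metabolites` ([run_contrast()]
#'   results) and `pathways` ([run_pathway_fcs()] results) per contrast,
#'   the filter reports, and the manifest. Files are written when
#'   `config$out_dir` is set; identical configs (including seed) produce
#'   byte-identical output trees.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- if (quiet) function(...) invisible() else
    function(...) message(...)
  cohort <- if (!is.null(config$sim)) {
    stage("generate_cohort", generate_cohort(config$sim))
  } else {
    pan <- stage("read_panel", read_panel(config$paths[["panel"]]))
    stage("read_cohort",
          read_cohort(pan, config$paths[["meta"]],
                      config$paths[["baseline"]],
                      config$paths[["stimulated"]]))
  }
  net <- stage("net_release", net_release(cohort, config$scheme))
  contrasts <- config$contrasts %||%
    applicable_contrasts(cohort$samples)
  if (!length(contrasts)) stop("no applicable contrast")
  names(contrasts) <- vapply(contrasts, `[[`, "", "name")
  met_res <- list(); pw_res <- list(); reports <- list()
  for (cs in contrasts) {
    ia <- select_subjects(cohort$samples, cs$a)
    ib <- select_subjects(cohort$samples, cs$b)
    sub <- c(ia, ib)
    stim_sub <- concentration_matrix(
      "stimulated", cohort$stimulated$values[sub, , drop = FALSE],
      cohort$stimulated$censored[sub, , drop = FALSE])
    flt <- stage("detection_filter",
                 detection_filter(stim_sub,
                                  rep(c("A", "B"),
                                      c(length(ia), length(ib))),
                                  config$threshold))
    for (i in which(!flt$report$kept))
      say(sprintf("[%s] excluding %s: censored fractions %.2f / %.2f",
                  cs$name, flt$report$metabolite[i],
                  flt$report$frac_censored_a[i],
                  flt$report$frac_censored_b[i]))
    if (!length(flt$kept)) {
      say("[", cs$name, "] no metabolite passes the detection filter")
      next
    }
    fit <- stage("run_contrast",
                 run_contrast(net, cs, B = config$B, seed = config$seed,
                              method = config$method,
                              metabolites = flt$kept))
    sets <- stage("build_pathway_sets",
                  suppressMessages(build_pathway_sets(cohort$panel,
                                                      flt$kept)))
    met_res[[cs$name]] <- fit
    reports[[cs$name]] <- flt$report
    if (length(sets))
      pw_res[[cs$name]] <- stage("run_pathway_fcs",
                                 run_pathway_fcs(fit, sets,
                                                 method = config$method))
  }
  manifest <- list(
    package = "eicoperm",
    version = as.character(utils::packageVersion("eicoperm")),
    seed = config$seed, permutations = config$B,
    substitution_scheme = config$scheme,
    detect_threshold = config$threshold,
    adjust_method = config$method,
    adjust_family = "within-contrast",
    contrasts = names(met_res),
    simulated = !is.null(config$sim))
  run <- structure(list(cohort = cohort, net = net, metabolites = met_res,
                        pathways = pw_res, filter_reports = reports,
                        manifest = manifest, config = config),
                   class = "eicoperm_run")
  if (!is.null(config$out_dir))
    run$files <- stage("write_results",
                       write_results(met_res, pw_res, config$out_dir,
                                     manifest = manifest,
                                     reports = reports))
  run
}

#' Write result tables and a reproducibility manifest
#'
#' One TSV per contrast for the metabolite-level results, one TSV for the
#' pathway-level results across contrasts, one TSV per contrast for the
#' detection-filter report, and `manifest.json` recording seed, number of
#' permutations, substitution scheme, filter threshold and adjustment
#' method. Column order is fixed; identical inputs give byte-identical
#' files.
#'
#' @param met_res named list of [run_contrast()] results (may be empty).
#' @param pw_res named list of [run_pathway_fcs()] results.
#' @param out_dir output directory, created if needed.
#' @param manifest list of run parameters to serialize.
#' @param reports optional named list of filter reports.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(met_res, pw_res, out_dir, manifest = list(),
                          reports = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  met_cols <- c("metabolite", "contrast", "n_a", "n_b", "statistic",
                "stat_centered", "direction", "p_raw", "p_adj")
  for (nm in names(met_res))
    files <- c(files, write_tsv(as.data.frame(met_res[[nm]])[met_cols],
                                file.path(out_dir,
                                          paste0("metabolites_", nm, ".tsv"))))
  pw_cols <- c("pathway", "contrast", "n_members", "tippett", "p_raw",
               "p_adj")
  pw_all <- if (length(pw_res)) {
    do.call(rbind, c(lapply(unname(pw_res), function(x)
      as.data.frame(x)[pw_cols]), list(make.row.names = FALSE)))
  } else {
    setNames(as.data.frame(matrix(numeric(0), nrow = 0,
                                  ncol = length(pw_cols))), pw_cols)
  }
  files <- c(files, write_tsv(pw_all, file.path(out_dir, "pathways.tsv")))
  for (nm in names(reports))
    files <- c(files, write_tsv(as.data.frame(reports[[nm]]),
                                file.path(out_dir,
                                          paste0("filter_", nm, ".tsv"))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mpath))
}

#' @export
print.eicoperm_run <- function(x, ...) {
  cat("eicoperm pipeline run (", if (x$manifest$simulated) "simulated"
      else "read from files", " cohort)\n", sep = "")
  cat("  B = ", x$manifest$permutations, ", seed = ", x$manifest$seed,
      ", scheme = ", x$manifest$substitution_scheme, ", adjust = ",
      x$manifest$adjust_method, "\n", sep = "")
  for (nm in names(x$metabolites)) {
    fit <- x$metabolites[[nm]]
    cat(sprintf("  %-20s %2d metabolites tested, %d with adj p <= 0.05\n",
                nm, nrow(fit), sum(fit$p_adj <= 0.05)))
  }
  invisible(x)
}

#' @export
summary.eicoperm_run <- function(object, ...) {
  for (fit in object$metabolites) summary(fit, ...)
  for (pw in object$pathways) print(pw)
  invisible(object)
}

#' Boxplots of net release by group
#'
#' Basic diagnostic figure: per-group boxplots of the net release (ng per
#' 10^6 leukocytes) of selected metabolites, severe group split by OCS
#' use when present.
#'
#' @param x an `eicoperm_run` object.
#' @param metabolites metabolite ids to plot (default: the four smallest
#'   adjusted p-values of the first contrast).
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.eicoperm_run <- function(x, metabolites = NULL, ...) {
  net <- x$net
  if (is.null(metabolites)) {
    fit <- x$metabolites[[1]]
    metabolites <- head(fit$metabolite[order(fit$p_adj)], 4L)
  }
  grp <- subgroup_of(net$samples)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(metabolites)))
  on.exit(graphics::par(old))
  for (m in metabolites)
    graphics::boxplot(net$values[, m] ~ grp, xlab = "", las = 2,
                      ylab = "net release [ng / 10^6 cells]", main = m, ...)
  invisible(x)
}

#' Human-readable summary of a results directory
#'
#' Reads the TSVs written by [write_results()] and prints, per contrast,
#' the metabolites ordered by adjusted p-value with asterisk bands
#' (0.05 / 0.01 / 0.001 / 0.0001) and the pathway table.
#'
#' @param results_dir directory containing the result TSVs.
#' @param max_rows metabolite rows shown per contrast.
#' @return Invisibly, a list with the metabolite and pathway tables
#'   (asterisk column added).
#' @export
summarize <- function(results_dir, max_rows = 20L) {
  mfiles <- sort(list.files(results_dir, "^metabolites_.*\\.tsv$",
                            full.names = TRUE))
  pfile <- file.path(results_dir, "pathways.tsv")
  if (!length(mfiles) && !file.exists(pfile))
    stop("no result files in ", results_dir)
  mets <- list()
  for (f in mfiles) {
    df <- read.delim(f, stringsAsFactors = FALSE)
    df <- df[order(df$p_adj, df$p_raw), ]
    df$stars <- p_stars(df$p_adj)
    nm <- sub("^metabolites_(.*)\\.tsv$", "\\1", basename(f))
    mets[[nm]] <- df
    cat("== Contrast ", nm, " (", nrow(df), " metabolites) ==\n", sep = "")
    print(head(df[c("metabolite", "direction", "p_raw", "p_adj", "stars")],
               max_rows), row.names = FALSE, digits = 4)
    cat("\n")
  }
  pw <- NULL
  if (file.exists(pfile)) {
    pw <- read.delim(pfile, stringsAsFactors = FALSE)
    if (nrow(pw)) {
      pw$stars <- p_stars(pw$p_adj)
      cat("== Pathway functional class scoring ==\n")
      print(pw, row.names = FALSE, digits = 4)
    } else cat("== No pathway results ==\n")
  }
  invisible(list(metabolites = mets, pathways = pw))
}
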