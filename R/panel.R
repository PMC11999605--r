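#' Construct an eicosanoid panel
#'
#' A panel is the target list of a quantitative LC-MS/MS assay: one row per
#' metabolite with its biosynthesis pathway assignment(s) and its limit of
#' detection (LOD). Pathway labels come from the fixed vocabulary
#' `r paste(PATHWAY_LABELS, collapse = ", ")`; a metabolite may belong to
#' several pathways (e.g. `"5-LOX/15-LOX"` dual annotation).
#'
#' @param metabolite character vector of unique metabolite short names.
#' @param pathway list of character vectors (one per metabolite) or a
#'   character vector with `"/"`-separated multiple labels.
#' @param lod numeric vector of strictly positive detection limits, ng/ml.
#' @return An object of class `eico_panel`: a data frame with columns
#'   `metabolite` (character), `pathways` (list of character vectors) and
#'   `lod` (numeric), plus a fixed `unit` attribute `"ng/ml"`.
#' @examples
#' panel(c("LTE4", "PGE2"), c("5-LOX", "COX"), c(0.0005, 0.01))
#' @export
panel <- function(metabolite, pathway, lod) {
  metabolite <- as.character(metabolite)
  if (length(metabolite) == 0L) stop("panel is empty")
  if (anyDuplicated(metabolite))
    stop("duplicate metabolite id: ",
         paste(unique(metabolite[duplicated(metabolite)]), collapse = ", "))
  if (is.character(pathway)) pathway <- strsplit(pathway, "/", fixed = TRUE)
  if (length(lod) == 1L) lod <- rep(lod, length(metabolite))
  if (length(pathway) != length(metabolite) || length(lod) != length(metabolite))
    stop("metabolite, pathway and lod must have equal length")
  pathway <- lapply(pathway, function(p) unique(trimws(p)))
  bad <- setdiff(unique(unlist(pathway)), PATHWAY_LABELS)
  if (length(bad))
    stop("unknown pathway label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(PATHWAY_LABELS, collapse = ", "), ")")
  if (any(vapply(pathway, length, 1L) == 0L))
    stop("every metabolite needs at least one pathway label")
  lod <- as.numeric(lod)
  if (anyNA(lod) || any(lod <= 0)) stop("lod must be numeric and > 0")
  if (all(vapply(pathway, function(p) identical(p, "AUTOX"), TRUE)))
    warning("panel contains only auto-oxidation (AUTOX) metabolites; ",
            "pathway analysis will be empty")
  out <- data.frame(metabolite = metabolite, lod = lod,
                    stringsAsFactors = FALSE)
  out$pathways <- pathway
  out <- out[c("metabolite", "pathways", "lod")]
  attr(out, "unit") <- "ng/ml"
  class(out) <- c("eico_panel", "data.frame")
  out
}

#' Read a panel definition from CSV
#'
#' Expects a header `metabolite,pathway,lod`; the `pathway` cell may hold
#' several `"/"`-separated labels. Row order is preserved.
#'
#' @param path path to a CSV file (RFC-4180, UTF-8, `.` decimal separator).
#' @return An [panel()] object.
#' @examples
#' p <- read_panel(system.file("extdata", "panel_synthetic_lod.csv",
#'                             package = "eicoperm"))
#' nrow(p)
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("read_panel: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "pathway", "lod")
  if (!all(need %in% names(df)))
    stop("read_panel: CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("read_panel: empty panel file")
  panel(df$metabolite, df$pathway, df$lod)
}

#' Write a panel definition to CSV
#'
#' Inverse of [read_panel()]: dual pathway annotations are re-joined with
#' `"/"`.
#'
#' @param x an [panel()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "eico_panel"))
  df <- data.frame(
    metabolite = x$metabolite,
    pathway = vapply(x$pathways, paste, "", collapse = "/"),
    lod = x$lod, stringsAsFactors = FALSE)
  write.csv_plain(df, path)
  invisible(path)
}

# write.csv without row names; character fields quoted (metabolite names
# may contain commas, e.g. "14,15-DHET"); deterministic output.
write.csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' @export
print.eico_panel <- function(x, ...) {
  pw <- vapply(x$pathways, paste, "", collapse = "/")
  cat("Eicosanoid panel: ", nrow(x), " metabolites (",
      sum(pw != "AUTOX"), " non-AUTOX), unit ng/ml\n", sep = "")
  tab <- table(unlist(x$pathways))
  cat("  pathway counts:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
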