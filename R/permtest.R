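#' Define a two-group contrast
#'
#' A contrast names the two subject sets compared by the rank-sum
#' permutation test. Each selector restricts on disease group and,
#' optionally, on OCS use (only meaningful within the severe group).
#'
#' @param name short contrast label used in file names and reports.
#' @param a,b selectors: a list with `group` (character vector of group
#'   labels) and optional `ocs` (logical scalar).
#' @return An object of class `contrast_spec`.
#' @seealso [standard_contrasts()]
#' @export
contrast_spec <- function(name, a, b) {
  for (s in list(a, b)) {
    if (is.null(s$group)) stop("selector needs a group field")
    bad <- setdiff(s$group, c("control", "moderate", "severe"))
    if (length(bad)) stop("invalid group label: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, a = a, b = b), class = "contrast_spec")
}

select_subjects <- function(samples, sel) {
  keep <- samples$group %in% sel$group
  if (!is.null(sel$ocs)) keep <- keep & samples$ocs == sel$ocs
  which(keep)
}

#' The five contrasts of the study design
#'
#' Controls vs mild-to-moderate, controls vs severe, mild-to-moderate vs
#' severe, and controls vs the severe subgroups split by permanent oral
#' corticosteroid use.
#'
#' @return A named list of [contrast_spec()] objects.
#' @export
standard_contrasts <- function() {
  cs <- list(
    contrast_spec("ctrl_vs_mod", list(group = "control"),
                  list(group = "moderate")),
    contrast_spec("ctrl_vs_sev", list(group = "control"),
                  list(group = "severe")),
    contrast_spec("mod_vs_sev", list(group = "moderate"),
                  list(group = "severe")),
    contrast_spec("ctrl_vs_sev_no_ocs", list(group = "control"),
                  list(group = "severe", ocs = FALSE)),
    contrast_spec("ctrl_vs_sev_ocs", list(group = "control"),
                  list(group = "severe", ocs = TRUE)))
  setNames(cs, vapply(cs, `[[`, "", "name"))
}

#' Wilcoxon rank-sum statistic
#'
#' Sum of the pooled-sample midranks of group A. Ties get average ranks.
#' Two-sided evidence is measured downstream as `|W - n_A (n + 1) / 2|`,
#' the absolute deviation from the null expectation.
#'
#' @param x,y numeric vectors (groups A and B), each non-empty and finite.
#' @return The rank sum `W` of group A.
#' @examples
#' rank_sum(c(1, 2, 3), c(4, 5, 6))  # 6, the minimum possible
#' rank_sum(c(1, 1), c(1, 2))        # midranks (2,2,2,4) -> 4
#' @export
rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  r <- rank(c(x, y))
  sum(r[seq_along(x)])
}

#' Build a joint permutation ensemble of group labels
#'
#' The ensemble is the single source of randomness shared by every
#' metabolite of a contrast (joint resampling, preserving inter-metabolite
#' correlation under the null). Row 1 is the identity assignment; rows
#' 2..B+1 are uniformly random re-assignments of the labels (sampled
#' independently, so repeats are possible), each preserving the group
#' sizes. In exhaustive mode all `choose(n, n_A)` distinct assignments are
#' enumerated instead (identity first).
#'
#' @param is_a logical vector: `TRUE` for subjects in group A, in the row
#'   order of the data the ensemble will be applied to.
#' @param B number of random permutations (ignored in exhaustive mode).
#' @param seed integer seed; the ensemble is reproducible from it.
#' @param exhaustive enumerate the full assignment space.
#' @return An object of class `perm_ensemble`: list with `labels` (N x n
#'   logical matrix, row 1 = identity), `B`, `seed`, `exhaustive`.
#' @export
build_ensemble <- function(is_a, B = 10000, seed = NULL, exhaustive = FALSE) {
  stopifnot(is.logical(is_a))
  n <- length(is_a)
  na <- sum(is_a)
  if (na == 0L || na == n) stop("two non-empty groups required")
  if (!exhaustive && B < 1) stop("B must be >= 1")
  labels <- if (exhaustive) {
    sets <- utils::combn(n, na)
    L <- matrix(FALSE, ncol(sets), n)
    L[cbind(rep(seq_len(ncol(sets)), each = na), as.vector(sets))] <- TRUE
    id <- which(apply(L, 1L, function(r) all(r == is_a)))[1]
    L[c(id, setdiff(seq_len(nrow(L)), id)), , drop = FALSE]
  } else {
    with_seed(seed, {
      L <- matrix(FALSE, B + 1L, n)
      L[1, ] <- is_a
      for (b in seq_len(B) + 1L) L[b, sample.int(n, na)] <- TRUE
      L
    })
  }
  structure(list(labels = labels, B = nrow(labels) - 1L, seed = seed,
                 exhaustive = exhaustive),
            class = "perm_ensemble")
}

#' @export
print.perm_ensemble <- function(x, ...) {
  cat("Permutation ensemble: ",
      if (x$exhaustive) "exhaustive, " else "random, ",
      nrow(x$labels), " assignments (incl. identity) of ",
      sum(x$labels[1, ]), "+", sum(!x$labels[1, ]), " labels\n", sep = "")
  invisible(x)
}

#' Permutation p-value
#'
#' `p = (1 + #{b : T_b >= T_obs}) / (B + 1)` over the `B` permuted
#' statistics: the identity counts itself, so `p >= 1/(B+1) > 0` and the
#' test is exactly valid. Ties between permuted and observed statistics
#' count as at least as extreme (conservative). With the exhaustive
#' ensemble this equals the exact enumeration p-value
#' `#{assignments at least as extreme} / choose(n, n_A)` when the
#' enumerated non-identity rows are passed as `permuted`.
#'
#' @param observed observed (centered, two-sided) statistic.
#' @param permuted vector of permuted statistics, excluding the identity.
#' @return The p-value.
#' @export
perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (length(permuted) + 1)
}

# Centered absolute rank-sum statistics for one metabolite across all
# ensemble rows. x: values (may contain NA = missing, dropped pairwise);
# L: N x n logical label matrix. Returns vector of length N.
ensemble_stats <- function(x, L) {
  obs <- !is.na(x)
  x <- x[obs]
  L <- L[, obs, drop = FALSE]
  r <- rank(x)
  W <- as.vector(L %*% r)
  nA <- rowSums(L)
  abs(W - nA * (length(x) + 1) / 2)
}

# Per-permutation p-values by double ranking: p_b = #{b' : S_b' >= S_b}/N,
# so column 1 (identity) is exactly the raw permutation p-value.
perm_p_row <- function(S) {
  N <- length(S)
  (N + 1 - rank(S, ties.method = "min")) / N
}

#' Step-down multiplicity adjustment
#'
#' `method = "minp"` (default): resampling-based Westfall-Young step-down
#' minP. Hypotheses are ordered by raw p-value; for each permutation the
#' successive minima of the per-permutation p-values over the remaining
#' hypotheses are formed, the adjusted p-value is the fraction of
#' permutations (identity included) whose min-p undercuts the observed
#' one, and monotonicity is enforced along the ordering. Because the
#' per-permutation p-values come from the joint ensemble, the adjustment
#' respects the correlation between metabolites; for perfectly correlated
#' (duplicated) metabolites it reduces to no adjustment at all.
#' `method = "bh"`: Benjamini-Hochberg step-up via [stats::p.adjust()], as
#' a standard cross-check. Both satisfy `raw p <= adjusted p <= 1`.
#'
#' @param p vector of raw permutation p-values.
#' @param perm_p m x N matrix of per-permutation p-values (rows = the
#'   hypotheses in the order of `p`, column 1 = identity); required for
#'   `"minp"`.
#' @param method `"minp"` or `"bh"`.
#' @return Vector of adjusted p-values, same order as `p`.
#' @export
stepdown_adjust <- function(p, perm_p = NULL, method = c("minp", "bh")) {
  method <- match.arg(method)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (method == "bh") return(p.adjust(p, method = "BH"))
  if (is.null(perm_p) || nrow(perm_p) != m)
    stop("minp needs a perm_p matrix with one row per hypothesis")
  ord <- order(p)
  q <- perm_p[ord, , drop = FALSE]
  if (m > 1L)
    for (i in (m - 1L):1L) q[i, ] <- pmin(q[i, ], q[i + 1L, ])
  adj <- vapply(seq_len(m), function(i) mean(q[i, ] <= p[ord][i]), 0)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Per-metabolite permutation tests for one contrast
#'
#' Runs the Wilcoxon rank-sum permutation test for every metabolite of a
#' net-release matrix under one contrast, reusing a single joint
#' permutation ensemble, and adjusts the p-values across metabolites
#' (step-down minP by default). Subjects missing a metabolite's value are
#' dropped pairwise for that metabolite, with the ensemble labels
#' re-subset accordingly. Selected subjects are ordered by id before the
#' ensemble is built, so results do not depend on the row order of the
#' input. When the total sample size is at most
#' `exhaustive_max_n` the full assignment space is enumerated instead of
#' sampled, giving exact enumeration p-values.
#'
#' @param net a [net_release()] object (or any object with `values` matrix
#'   and `samples` table).
#' @param contrast a [contrast_spec()].
#' @param B number of random label permutations.
#' @param seed integer seed for the ensemble.
#' @param method multiplicity adjustment, `"minp"` or `"bh"`.
#' @param metabolites optional character vector restricting (and ordering)
#'   the metabolites tested, e.g. the kept set of [detection_filter()].
#' @param exhaustive_max_n total-n threshold below which enumeration
#'   replaces random sampling.
#' @return An object of class `metabolite_tests`: a data frame with one
#'   row per metabolite (`metabolite`, `n_a`, `n_b`, `statistic` = rank
#'   sum of group A on the identity labels, `stat_centered`, `direction` =
#'   sign of the A-B median difference, `p_raw`, `p_adj`), with the
#'   ensemble and the per-permutation p-value matrix kept in attributes
#'   for pathway-level scoring.
#' @export
run_contrast <- function(net, contrast, B = 10000, seed = NULL,
                         method = c("minp", "bh"), metabolites = NULL,
                         exhaustive_max_n = 12) {
  method <- match.arg(method)
  stopifnot(inherits(contrast, "contrast_spec"))
  samples <- net$samples
  ia <- select_subjects(samples, contrast$a)
  ib <- select_subjects(samples, contrast$b)
  if (length(intersect(ia, ib))) stop("contrast selectors overlap")
  if (length(ia) < 2L || length(ib) < 2L)
    stop("contrast '", contrast$name, "' selects < 2 subjects per group")
  # canonicalize subject order so results are invariant to row shuffles
  ia <- ia[order(samples$subject_id[ia])]
  ib <- ib[order(samples$subject_id[ib])]
  vals <- net$values[c(ia, ib), , drop = FALSE]
  if (!is.null(metabolites)) {
    missing_m <- setdiff(metabolites, colnames(vals))
    if (length(missing_m)) stop("metabolite(s) not in matrix: ",
                                paste(missing_m, collapse = ", "))
    vals <- vals[, metabolites, drop = FALSE]
  }
  is_a <- rep(c(TRUE, FALSE), c(length(ia), length(ib)))
  exhaustive <- (length(is_a) <= exhaustive_max_n)
  ens <- build_ensemble(is_a, B = B, seed = seed, exhaustive = exhaustive)
  m <- ncol(vals)
  N <- nrow(ens$labels)
  S <- matrix(NA_real_, m, N)
  perm_p <- matrix(NA_real_, m, N,
                   dimnames = list(colnames(vals), NULL))
  n_a <- n_b <- integer(m)
  direction <- numeric(m)
  for (j in seq_len(m)) {
    x <- vals[, j]
    obs <- !is.na(x)
    n_a[j] <- sum(is_a & obs); n_b[j] <- sum(!is_a & obs)
    if (n_a[j] < 1L || n_b[j] < 1L)
      stop("metabolite ", colnames(vals)[j], ": empty group after ",
           "dropping missing values")
    S[j, ] <- ensemble_stats(x, ens$labels)
    perm_p[j, ] <- perm_p_row(S[j, ])
    direction[j] <- sign(median(x[is_a & obs]) - median(x[!is_a & obs]))
  }
  p_raw <- perm_p[, 1]
  out <- data.frame(
    metabolite = colnames(vals), contrast = contrast$name,
    n_a = n_a, n_b = n_b,
    statistic = vapply(seq_len(m), function(j) {
      x <- vals[, j]; obs <- !is.na(x)
      rank_sum(x[is_a & obs], x[!is_a & obs])
    }, 0),
    stat_centered = S[, 1], direction = direction,
    p_raw = unname(p_raw),
    p_adj = unname(stepdown_adjust(p_raw, perm_p, method)),
    stringsAsFactors = FALSE)
  structure(out, class = c("metabolite_tests", "data.frame"),
            contrast = contrast, ensemble = ens, perm_p = perm_p,
            method = method, B = B, seed = seed, exhaustive = exhaustive)
}

#' @export
print.metabolite_tests <- function(x, ...) {
  ens <- attr(x, "ensemble")
  cat("Metabolite permutation tests - contrast ",
      attr(x, "contrast")$name, "\n", sep = "")
  cat("  ", nrow(x), " metabolites; ",
      if (attr(x, "exhaustive")) "exhaustive enumeration of " else
        "random ensemble of ",
      nrow(ens$labels), " assignments; adjustment: ",
      attr(x, "method"), "\n", sep = "")
  df <- as.data.frame(x)[order(x$p_adj, x$p_raw), ]
  df$stars <- p_stars(df$p_adj)
  print(head(df, 15), row.names = FALSE, digits = 4)
  if (nrow(df) > 15) cat("  ... ", nrow(df) - 15, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolite_tests <- function(object, alpha = 0.05, ...) {
  cat("Contrast ", attr(object, "contrast")$name, ": ",
      sum(object$p_adj <= alpha), " of ", nrow(object),
      " metabolites with adjusted p <= ", alpha, "\n", sep = "")
  sig <- object[object$p_adj <= alpha, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$p_adj), ]
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-20s dir %+d  p_raw %.4g  p_adj %.4g %s\n",
                  sig$metabolite[i], sig$direction[i], sig$p_raw[i],
                  sig$p_adj[i], p_stars(sig$p_adj[i])))
  }
  invisible(object)
}
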