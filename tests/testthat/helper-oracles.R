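# Independent oracles and small fixture builders, kept deliberately
# separate from the package's own code paths.

# Brute-force two-sided rank-sum permutation p-value by full enumeration
# of all choose(n, n_A) label assignments.
enum_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  E <- na * (n + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - E)
  sets <- combn(n, na)
  stats <- apply(sets, 2, function(ix) abs(sum(r[ix]) - E))
  mean(stats >= obs - 1e-12)
}

# Hand-rolled product-limit estimator for left-censored data via the
# flip-sign construction; unresolved sub-LOD mass placed at lod/2 (the
# same convention the package documents).
oracle_km <- function(values, censored, lod) {
  time <- ifelse(censored, -lod, -values)
  event <- !censored
  ut <- sort(unique(time[event]))
  S <- 1
  vals <- numeric(0)
  mass <- numeric(0)
  for (tt in ut) {
    atrisk <- sum(time >= tt)
    d <- sum(time == tt & event)
    Snew <- S * (1 - d / atrisk)
    vals <- c(vals, -tt)
    mass <- c(mass, S - Snew)
    S <- Snew
  }
  if (S > 1e-12) {
    vals <- c(vals, lod / 2)
    mass <- c(mass, S)
  }
  list(values = vals, mass = mass, mean = sum(vals * mass))
}

# Minimal net_release-like object from a samples x metabolites matrix.
make_net <- function(values, groups, ocs = NULL, wbc = 6) {
  n <- nrow(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%02d", seq_len(ncol(values)))
  samples <- sample_meta(rownames(values), groups,
                         ocs %||% rep(FALSE, n), rep(wbc, length.out = n))
  structure(list(values = values, samples = samples,
                 provenance = list(unit = "ng per 10^6 cells")),
            class = "net_release")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-group net matrix from explicit per-group vectors (one metabolite).
toy_net <- function(x, y, groups = c("control", "moderate")) {
  make_net(matrix(c(x, y), ncol = 1),
           rep(groups, c(length(x), length(y))))
}

CTRL_VS_MOD <- standard_contrasts()$ctrl_vs_mod
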