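#' Distance-based redundancy analysis of reef indicators on drivers
#'
#' Constrained ordination of the (transformed, normalized) indicator matrix
#' on the normalized driver matrix. With the Euclidean distance measure the
#' procedure is redundancy analysis: the indicators are regressed on the
#' drivers and the fitted covariance eigen-decomposed. Highly correlated
#' drivers (|r| > `corr_threshold`) are pruned greedily in column order - the
#' later member of each offending pair is dropped. Per constrained axis the
#' percent of fitted variation (eigenvalue over the sum of constrained
#' eigenvalues) and percent of total variation (eigenvalue over the total
#' variance) are reported; a fitted fraction above 70% of total variance is
#' flagged as a good fit.
#'
#' @param Y indicator matrix (rows = samples), already transformed (sqrt
#'   benthic, fourth-root fish); z-scored internally.
#' @param X driver matrix; z-scored internally.
#' @param corr_threshold pairwise |r| above which the later driver is dropped.
#' @return an object of class `reef_rda`: `scores` (site scores on
#'   constrained axes), `pct_fitted`, `pct_total`, `loadings` (driver biplot
#'   scores), `retained`, `dropped`, `fitted_fraction`, `good_fit`, and the
#'   underlying vegan model as `model`.
#' @export
dbrda_reef <- function(Y, X, corr_threshold = 0.7) {
  Y <- as.matrix(Y); X <- as.data.frame(X)
  if (any(vapply(X, stats::sd, 0) == 0)) stop("constant driver column")
  if (any(apply(Y, 2, stats::sd) == 0)) stop("constant indicator column")
  keep <- prune_correlated(X, corr_threshold)
  Xk <- X[, keep, drop = FALSE]
  if (nrow(Y) <= ncol(Xk)) stop("n must exceed the number of retained drivers")
  Ys <- scale(Y)
  Xs <- scale(as.matrix(Xk))
  mod <- vegan::rda(Ys ~ ., data = as.data.frame(Xs))
  eig <- mod$CCA$eig
  tot <- mod$tot.chi
  pct_fitted <- 100 * eig / sum(eig)
  pct_total <- 100 * eig / tot
  structure(list(
    scores = vegan::scores(mod, display = "sites",
                           choices = seq_along(eig), scaling = 1),
    loadings = vegan::scores(mod, display = "bp",
                             choices = seq_along(eig), scaling = 1),
    pct_fitted = pct_fitted, pct_total = pct_total,
    eig = eig, total_variance = tot,
    fitted_fraction = 100 * sum(eig) / tot,
    good_fit = 100 * sum(eig) / tot > 70,
    retained = names(Xk), dropped = setdiff(names(X), names(Xk)),
    model = mod), class = "reef_rda")
}

# greedy pruning in column order: drop the later driver of each |r| > thr pair
prune_correlated <- function(X, thr) {
  nm <- names(X)
  keep <- character(0)
  for (cand in nm) {
    ok <- TRUE
    for (k in keep) {
      if (abs(stats::cor(X[[cand]], X[[k]])) > thr) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, cand)
  }
  keep
}

#' @export
print.reef_rda <- function(x, ...) {
  cat("<reef_rda>", length(x$eig), "constrained axes;",
      sprintf("fitted fraction %.1f%% of total variance%s\n", x$fitted_fraction,
              if (x$good_fit) " (good fit)" else ""))
  for (k in seq_along(x$eig))
    cat(sprintf("  axis %d: %.1f%% of fitted, %.1f%% of total variation\n",
                k, x$pct_fitted[k], x$pct_total[k]))
  if (length(x$dropped))
    cat("  dropped correlated drivers:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
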