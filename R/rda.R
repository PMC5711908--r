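#' Orthogonal third-degree spatial polynomials from coordinates
#'
#' Z-standardizes longitude and latitude and builds the nine monomials
#' `x, y, x^2, xy, y^2, x^3, x^2y, xy^2, y^3`, orthogonalized sequentially
#' (Gram-Schmidt against the intercept and all previous terms, in that fixed
#' order) and scaled to unit standard deviation — the trend-surface basis of
#' spatial community ecology.
#'
#' @param lon,lat Coordinate vectors (>= 10 values, non-degenerate).
#' @return Numeric matrix with columns named after the monomials; degenerate
#'   (zero-variance after projection) columns are dropped with a warning.
#' @export
standardize_and_polynomials <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  if (length(lon) < 10) stop("need >= 10 samples")
  if (stats::sd(lon) == 0 || stats::sd(lat) == 0) {
    warning("degenerate coordinates: constant lon or lat")
  }
  zx <- if (stats::sd(lon) > 0) (lon - mean(lon)) / stats::sd(lon) else lon * 0
  zy <- if (stats::sd(lat) > 0) (lat - mean(lat)) / stats::sd(lat) else lat * 0
  raw <- cbind(x = zx, y = zy, `x^2` = zx^2, `xy` = zx * zy, `y^2` = zy^2,
               `x^3` = zx^3, `x^2y` = zx^2 * zy, `xy^2` = zx * zy^2,
               `y^3` = zy^3)
  n <- length(zx)
  basis <- matrix(numeric(0), nrow = n)
  kept <- character(0)
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j] - mean(raw[, j])
    if (ncol(basis) > 0) {
      v <- v - basis %*% crossprod(basis, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8 * sqrt(n)) {
      warning("dropping degenerate spatial term: ", colnames(raw)[j])
      next
    }
    basis <- cbind(basis, v / nv)
    kept <- c(kept, colnames(raw)[j])
  }
  colnames(basis) <- kept
  # unit-sd scaling (columns are orthonormal; rescale to sd 1)
  basis * sqrt(n - 1)
}

#' Pairwise correlation screen for climate covariates
#'
#' Flags covariate pairs whose absolute Pearson correlation reaches the
#' threshold. Nothing is dropped automatically — the report supports a
#' retention decision by the analyst.
#'
#' @param climate Numeric matrix/data.frame of covariates.
#' @param threshold Absolute correlation threshold (default 0.5).
#' @return List with `r` (correlation matrix), `flagged` (data.frame of
#'   offending pairs) and `retained` (all column names; retention is a
#'   reporting decision).
#' @export
correlation_screen <- function(climate, threshold = 0.5) {
  cm <- as.matrix(climate)
  r <- stats::cor(cm)
  idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(r)[idx[, 1L]],
                        var2 = colnames(r)[idx[, 2L]],
                        r = r[idx], stringsAsFactors = FALSE)
  list(r = r, flagged = flagged, retained = colnames(cm))
}

# residualize columns of M on [1, Z]
resid_on <- function(M, Z = NULL) {
  M <- as.matrix(M)
  X <- if (is.null(Z) || NCOL(Z) == 0) {
    matrix(1, nrow(M), 1)
  } else {
    cbind(1, as.matrix(Z))
  }
  qr_ <- qr(X)
  M - qr.fitted(qr_, M)
}

#' Partial redundancy analysis
#'
#' Both the multivariate response `Y` and the predictors `X` are residualized
#' on the conditioning variables `Z` (plus intercept); the constrained
#' variance is the variance of the fitted values of the residualized
#' regression, and the eigen-decomposition of the fitted matrix yields the
#' constrained axes. Variance components (conditional, constrained,
#' residual) are reported as percent of the total variance of centered `Y`
#' and sum to 100 exactly.
#'
#' @param Y Response matrix (e.g. significant PCoA axes), n x q.
#' @param X Predictor matrix (terms as columns), or NULL for a
#'   condition-only fit.
#' @param Z Conditioning matrix (e.g. binary gene-pool indicator), or NULL
#'   for plain RDA.
#' @return An `rda_fit`: list with `components` (percent: conditional,
#'   constrained, residual), `var` (absolute variances incl. total),
#'   `axes` (per-axis constrained variance and percent of constrained),
#'   `F_whole` (pseudo-F with dfs), `scores` (site scores on constrained
#'   axes), plus the inputs needed by the permutation machinery.
#' @export
partial_rda <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tot_ss <- sum(Yc^2)
  Yr <- resid_on(Yc, Z)
  cond_ss <- tot_ss - sum(Yr^2)
  df_cond <- if (is.null(Z)) 0L else qr(cbind(1, as.matrix(Z)))$rank - 1L
  if (is.null(X) || NCOL(X) == 0) {
    fit_ss <- 0
    df_model <- 0L
    Yhat <- matrix(0, n, ncol(Y))
    ax_var <- numeric(0)
    scores <- matrix(numeric(0), nrow = n)
  } else {
    Xr <- resid_on(as.matrix(X), Z)
    qr_x <- qr(Xr)
    df_model <- qr_x$rank
    Yhat <- qr.fitted(qr_x, Yr)
    fit_ss <- sum(Yhat^2)
    sv <- svd(Yhat)
    keep <- sv$d^2 > 1e-10 * max(sv$d^2, 1e-300)
    ax_var <- (sv$d^2 / (n - 1))[keep]
    scores <- (sv$u %*% diag(sv$d, length(sv$d)))[, keep, drop = FALSE]
    if (NCOL(scores)) colnames(scores) <- paste0("RDA", seq_len(ncol(scores)))
  }
  resid_ss <- tot_ss - cond_ss - fit_ss
  df_resid <- n - 1L - df_cond - df_model
  F_whole <- if (df_model > 0 && df_resid > 0 && resid_ss > 1e-12 * tot_ss) {
    (fit_ss / df_model) / (resid_ss / df_resid)
  } else if (df_model > 0) {
    Inf
  } else NA_real_
  structure(list(
    components = c(conditional = 100 * cond_ss / tot_ss,
                   constrained = 100 * fit_ss / tot_ss,
                   residual = 100 * resid_ss / tot_ss),
    var = c(conditional = cond_ss, constrained = fit_ss,
            residual = resid_ss, total = tot_ss) / (n - 1),
    axes = if (length(ax_var)) {
      data.frame(axis = paste0("RDA", seq_along(ax_var)),
                 variance = ax_var,
                 pct_constrained = 100 * ax_var / sum(ax_var),
                 stringsAsFactors = FALSE)
    } else NULL,
    F_whole = c(F = F_whole, df1 = df_model, df2 = df_resid),
    scores = scores,
    n = n, tot_ss = tot_ss, df_cond = df_cond, df_model = df_model,
    df_resid = df_resid, fit_ss = fit_ss, resid_ss = resid_ss),
    class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("partial RDA: conditional %.2f%% | constrained %.2f%% | residual %.2f%%\n",
              x$components[1], x$components[2], x$components[3]))
  cat(sprintf("  whole-model pseudo-F(%d, %d) = %.3f\n",
              x$F_whole["df1"], x$F_whole["df2"], x$F_whole["F"]))
  invisible(x)
}

#' Whole-model pseudo-F
#'
#' `F = (constrained SS / df_model) / (residual SS / df_resid)`; recomputed
#' from a fitted model's variance table.
#'
#' @param fit An `rda_fit`.
#' @return Named vector `F`, `df1`, `df2`.
#' @export
pseudo_F <- function(fit) {
  fit$F_whole
}

# core permutation engine: F' distribution by permuting rows of the
# Z-residualized response (permutation of residuals under the reduced model)
perm_F <- function(Y, X, Z, n_perm, seed, scheme = c("reduced", "rows")) {
  scheme <- match.arg(scheme)
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  Yr <- resid_on(Yc, Z)
  Xr <- resid_on(as.matrix(X), Z)
  qr_x <- qr(Xr)
  df_model <- qr_x$rank
  n <- nrow(Yc)
  df_cond <- if (is.null(Z)) 0L else qr(cbind(1, as.matrix(Z)))$rank - 1L
  df_resid <- n - 1L - df_cond - df_model
  fstat <- function(Yp) {
    fit_ss <- sum(qr.fitted(qr_x, Yp)^2)
    resid_ss <- sum(Yp^2) - fit_ss
    if (resid_ss <= 1e-12 * max(sum(Yp^2), 1e-300)) return(Inf)
    (fit_ss / df_model) / (resid_ss / df_resid)
  }
  F_obs <- fstat(Yr)
  set.seed(seed)
  F_perm <- numeric(n_perm)
  base <- if (scheme == "reduced") Yr else Yc
  for (b in seq_len(n_perm)) {
    Yp <- base[sample.int(n), , drop = FALSE]
    if (scheme == "rows") Yp <- resid_on(Yp, Z)
    F_perm[b] <- fstat(Yp)
  }
  list(F = F_obs, F_perm = F_perm, df = c(df_model, df_resid))
}

#' Permutation test for (partial) RDA
#'
#' Permutes rows of the response residualized on the conditioning variables
#' (permutation of residuals under the reduced model; simple row permutation
#' available via `scheme = "rows"`) and reports
#' `p = (#(F' >= F) + 1) / (n_perm + 1)`.
#'
#' @param Y,X,Z As in [partial_rda()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param scheme `"reduced"` (default) or `"rows"`.
#' @return List with `F`, `p`, `df`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 1000L, seed = 1L,
                             scheme = c("reduced", "rows")) {
  pf <- perm_F(Y, X, Z, n_perm, seed, match.arg(scheme))
  list(F = pf$F, p = (sum(pf$F_perm >= pf$F) + 1) / (n_perm + 1), df = pf$df)
}

#' Forward selection of RDA terms by permutation
#'
#' Greedy addition: at each step every remaining candidate is tested for its
#' marginal effect conditional on the already-selected terms plus the
#' conditioning variables (selected terms are folded into the condition);
#' the candidate with the largest marginal pseudo-F whose permutation
#' p-value is `<= alpha` enters. Selection stops when no candidate
#' qualifies. Before any term is considered, the full candidate set is
#' tested jointly (global gate); if that omnibus test is not significant at
#' `alpha`, selection returns empty. The gate is the standard guard against
#' the multiplicity inflation of testing many candidates at the first step.
#'
#' @param Y Response matrix.
#' @param candidates Named list or matrix of candidate term columns.
#' @param Z Conditioning matrix (or NULL).
#' @param alpha Entry threshold on the permutation p-value (default 0.01).
#' @param n_perm Permutations per test (default 1000).
#' @param seed Integer seed.
#' @param global_gate Require the joint test of all candidates to pass
#'   `alpha` before stepwise entry begins (default TRUE).
#' @return data.frame of selected terms in order, with their marginal F and
#'   p at entry (zero rows if nothing qualifies).
#' @export
forward_select <- function(Y, candidates, Z = NULL, alpha = 0.01,
                           n_perm = 1000L, seed = 1L, global_gate = TRUE) {
  cand <- as.matrix(candidates)
  stopifnot(!is.null(colnames(cand)))
  if (global_gate) {
    gl <- permutation_test(Y, cand, Z, n_perm = n_perm, seed = seed)
    if (gl$p > alpha) {
      return(data.frame(term = character(), F = numeric(), p = numeric(),
                        stringsAsFactors = FALSE))
    }
  }
  selected <- character(0)
  log <- data.frame(term = character(), F = numeric(), p = numeric(),
                    stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    remaining <- setdiff(colnames(cand), selected)
    if (!length(remaining)) break
    Zfull <- cbind(if (!is.null(Z)) as.matrix(Z),
                   cand[, selected, drop = FALSE])
    if (NCOL(Zfull) == 0) Zfull <- NULL
    step <- step + 1L
    res <- lapply(seq_along(remaining), function(k) {
      permutation_test(Y, cand[, remaining[k], drop = FALSE], Zfull,
                       n_perm = n_perm,
                       seed = seed + 1000L * step + k)
    })
    Fs <- vapply(res, `[[`, numeric(1), "F")
    ps <- vapply(res, `[[`, numeric(1), "p")
    ok <- which(ps <= alpha)
    if (!length(ok)) break
    best <- ok[which.max(Fs[ok])]
    selected <- c(selected, remaining[best])
    log <- rbind(log, data.frame(term = remaining[best], F = Fs[best],
                                 p = ps[best], stringsAsFactors = FALSE))
  }
  log
}

#' Build the candidate term set for forward selection
#'
#' Spatial main terms, climate main terms, and all pairwise spatial-by-climate
#' interaction columns (named `spatial:climate`).
#'
#' @param spatial Matrix of (orthogonalized) spatial terms.
#' @param climate Matrix of Z-standardized climate covariates.
#' @return Matrix of candidate columns.
#' @export
candidate_terms <- function(spatial, climate) {
  spatial <- as.matrix(spatial); climate <- as.matrix(climate)
  inter <- do.call(cbind, lapply(colnames(spatial), function(s) {
    m <- spatial[, s] * climate
    colnames(m) <- paste0(s, ":", colnames(climate))
    m
  }))
  cbind(spatial, climate, inter)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each term on the remaining
#' terms (conditioning variables included as covariates throughout).
#' Aliased columns get `Inf`.
#'
#' @param X Matrix of selected model terms.
#' @param Z Optional conditioning matrix included in every regression.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X, Z = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("t", seq_len(ncol(X)))
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    others <- cbind(X[, -j, drop = FALSE], if (!is.null(Z)) as.matrix(Z))
    xj <- X[, j] - mean(X[, j])
    r <- if (NCOL(others) == 0) xj else resid_on(xj, others)
    r2 <- 1 - sum(r^2) / sum(xj^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Per-axis permutation tests for constrained axes
#'
#' Marginal test of each constrained axis with all earlier axes added to the
#' conditioning set, so axis k is tested on the variance it adds beyond axes
#' `1..k-1`.
#'
#' @param Y,X,Z As in [partial_rda()].
#' @param n_perm Permutations per axis (default 999).
#' @param seed Integer seed.
#' @return data.frame: axis, variance, percent of constrained variance, F, p.
#' @export
axis_tests <- function(Y, X, Z = NULL, n_perm = 999L, seed = 1L) {
  fit <- partial_rda(Y, X, Z)
  if (is.null(fit$axes)) return(NULL)
  k <- nrow(fit$axes)
  ps <- numeric(k); Fs <- numeric(k)
  for (a in seq_len(k)) {
    Zaug <- cbind(if (!is.null(Z)) as.matrix(Z),
                  fit$scores[, seq_len(a - 1L), drop = FALSE])
    if (NCOL(Zaug) == 0) Zaug <- NULL
    pt <- permutation_test(Y, fit$scores[, a, drop = FALSE], Zaug,
                           n_perm = n_perm, seed = seed + a)
    ps[a] <- pt$p; Fs[a] <- pt$F
  }
  cbind(fit$axes, F = Fs, p = ps)
}

#' Sequential term table for a fitted model
#'
#' Variance attributed to each term in the given order (each term's
#' contribution conditional on the preceding ones and the condition), in the
#' layout of a variance-partitioning report: df, variance, percent of total,
#' and optionally a permutation p-value per term.
#'
#' @param Y Response matrix.
#' @param X Matrix of model terms in their selection order.
#' @param Z Conditioning matrix (or NULL).
#' @param n_perm Permutations per term (0 to skip p-values).
#' @param seed Integer seed.
#' @return data.frame with rows for each term, the condition, the residual
#'   and the total.
#' @export
rda_term_table <- function(Y, X, Z = NULL, n_perm = 0L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(as.matrix(Y))
  fit_full <- partial_rda(Y, X, Z)
  tot_var <- fit_full$var["total"]
  rows <- list()
  for (j in seq_len(ncol(X))) {
    Zaug <- cbind(if (!is.null(Z)) as.matrix(Z), X[, seq_len(j - 1L), drop = FALSE])
    if (NCOL(Zaug) == 0) Zaug <- NULL
    f <- partial_rda(Y, X[, j, drop = FALSE], Zaug)
    p <- if (n_perm > 0) {
      permutation_test(Y, X[, j, drop = FALSE], Zaug, n_perm = n_perm,
                       seed = seed + j)$p
    } else NA_real_
    rows[[j]] <- data.frame(term = colnames(X)[j], df = 1L,
                            variance = unname(f$var["constrained"]),
                            pct_total = unname(100 * f$var["constrained"] / tot_var),
                            p = p, stringsAsFactors = FALSE)
  }
  cond_row <- data.frame(term = "condition", df = fit_full$df_cond,
                         variance = unname(fit_full$var["conditional"]),
                         pct_total = unname(fit_full$components["conditional"]),
                         p = NA_real_, stringsAsFactors = FALSE)
  resid_row <- data.frame(term = "residual", df = fit_full$df_resid,
                          variance = unname(fit_full$var["residual"]),
                          pct_total = unname(fit_full$components["residual"]),
                          p = NA_real_, stringsAsFactors = FALSE)
  total_row <- data.frame(term = "total", df = n - 1L,
                          variance = unname(tot_var), pct_total = 100,
                          p = NA_real_, stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(cond_row, resid_row, total_row)))
}
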