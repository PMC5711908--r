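#' Read an AFLP presence/absence matrix with metadata and replicate map
#'
#' @param matrix_path CSV/TSV, rows = samples (first column `sample_id`),
#'   columns = loci, entries 0/1/NA.
#' @param metadata_path TSV with `sample_id` plus grouping columns (`region`,
#'   `year`, `batch`, ...).
#' @param replicates_path Optional TSV with columns `sample_id`,
#'   `replicate_id` naming replicate pairs.
#' @return An `aflp_matrix`: list with `data` (integer matrix, NA allowed),
#'   `meta` (data.frame) and `replicates` (two-column data.frame or NULL).
#' @export
read_aflp <- function(matrix_path, metadata_path, replicates_path = NULL) {
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  reps <- if (!is.null(replicates_path)) {
    utils::read.delim(replicates_path, stringsAsFactors = FALSE)
  } else NULL
  new_aflp(m, meta, reps)
}

#' Construct an aflp_matrix from in-memory parts
#'
#' @param data Integer/numeric matrix of 0/1/NA, rownames = sample ids,
#'   colnames = locus ids.
#' @param meta data.frame with `sample_id` (reordered to match `data`).
#' @param replicates Optional two-column data.frame of replicate sample-id
#'   pairs.
#' @return An `aflp_matrix`.
#' @export
new_aflp <- function(data, meta, replicates = NULL) {
  vals <- unique(as.vector(data))
  bad <- setdiff(vals[!is.na(vals)], c(0L, 1L))
  if (length(bad)) {
    stop("input error: AFLP entries must be 0/1/NA, found: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(rownames(data))) stop("input error: AFLP rows must be named")
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("L", seq_len(ncol(data)))
  }
  if (!"sample_id" %in% names(meta)) stop("input error: metadata needs sample_id")
  miss <- setdiff(rownames(data), meta$sample_id)
  if (length(miss)) {
    stop("input error: samples absent from metadata: ",
         paste(miss, collapse = ", "))
  }
  meta <- meta[match(rownames(data), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(replicates)) {
    orphans <- setdiff(unlist(replicates[, 1:2]), rownames(data))
    if (length(orphans)) {
      stop("input error: replicate ids not in matrix: ",
           paste(orphans, collapse = ", "))
    }
  }
  structure(list(data = data, meta = meta, replicates = replicates),
            class = "aflp_matrix")
}

#' @export
print.aflp_matrix <- function(x, ...) {
  cat("aflp_matrix:", nrow(x$data), "samples x", ncol(x$data), "loci;",
      if (is.null(x$replicates)) 0L else nrow(x$replicates),
      "replicate pair(s)\n")
  invisible(x)
}

#' Write an aflp_matrix to disk
#'
#' @param m An `aflp_matrix`.
#' @param matrix_path,metadata_path,replicates_path Output paths
#'   (`replicates_path` optional).
#' @return Invisibly, the paths written.
#' @export
write_aflp <- function(m, matrix_path, metadata_path, replicates_path = NULL) {
  df <- data.frame(sample_id = rownames(m$data), m$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, matrix_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(m$meta, metadata_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(replicates_path) && !is.null(m$replicates)) {
    utils::write.table(m$replicates, replicates_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(c(matrix_path, metadata_path, replicates_path))
}

#' Replicate-pair genotyping error rate
#'
#' Pooled over all replicate pairs: mismatching scored loci divided by
#' mutually scored loci.
#'
#' @param m An `aflp_matrix` with a replicate map.
#' @return Error rate in `[0, 1]`.
#' @export
replicate_error_rate <- function(m) {
  if (is.null(m$replicates) || nrow(m$replicates) == 0) {
    stop("no replicate pairs available")
  }
  mm <- 0L; tot <- 0L
  for (r in seq_len(nrow(m$replicates))) {
    a <- m$data[m$replicates[[1L]][r], ]
    b <- m$data[m$replicates[[2L]][r], ]
    ok <- !is.na(a) & !is.na(b)
    mm <- mm + sum(a[ok] != b[ok])
    tot <- tot + sum(ok)
  }
  mm / tot
}

#' Per-sample fragment counts
#'
#' @param m An `aflp_matrix`.
#' @return Named integer vector of per-sample band counts over non-missing
#'   loci.
#' @export
fragment_counts <- function(m) {
  rowSums(m$data == 1L, na.rm = TRUE)
}

#' Brown-Forsythe homogeneity-of-variance test
#'
#' One-way ANOVA on absolute deviations from the group medians — the robust
#' (median-centred) variant of Levene's test.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values), or a numeric vector together with `g`.
#' @param g Optional grouping factor when `groups` is a single vector.
#' @return List with `F`, `df` (length 2) and `p`.
#' @export
brown_forsythe <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(groups, g)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ f))
  list(F = a$`F value`[1L], df = a$Df, p = a$`Pr(>F)`[1L])
}

#' Filter samples on fragment counts relative to a reference band
#'
#' Degraded (typically old herbarium) samples yield fewer scored fragments.
#' The mean and standard deviation of per-sample fragment counts are
#' estimated on a reference subset (default: samples collected in or after
#' `ref_year`), and samples whose count falls outside
#' `[mu - k_sigma*sd, mu + k_sigma*sd]` are removed. The two-sided band is
#' deliberate: degradation loses fragments, scoring artifacts can add them.
#' Removal and band re-estimation are iterated to a fixed point so the
#' filter is idempotent on its own output (the first iteration is the usual
#' single-pass screen; further iterations rarely remove more than a sample
#' or two).
#'
#' @param m An `aflp_matrix` whose metadata has a `year` column.
#' @param ref_year First collection year included in the reference subset
#'   (default 2003).
#' @param k_sigma Width of the band in standard deviations (default 2).
#' @return The filtered `aflp_matrix` with a `filter_report` attribute
#'   (data.frame: sample_id, count, removed flag, and the final band).
#' @export
fragment_filter <- function(m, ref_year = 2003, k_sigma = 2) {
  if (!"year" %in% names(m$meta)) stop("metadata needs a 'year' column")
  cnt <- fragment_counts(m)
  ref0 <- !is.na(m$meta$year) & m$meta$year >= ref_year
  if (!any(ref0)) stop("reference subset (year >= ", ref_year, ") is empty")
  removed <- rep(FALSE, nrow(m$data))
  repeat {
    ref <- ref0 & !removed
    if (!any(ref)) stop("no reference samples survive the count filter")
    mu <- mean(cnt[ref]); sdv <- stats::sd(cnt[ref])
    if (is.na(sdv)) sdv <- 0
    lo <- mu - k_sigma * sdv; hi <- mu + k_sigma * sdv
    new_removed <- !removed & (cnt < lo | cnt > hi)
    if (!any(new_removed)) break
    removed <- removed | new_removed
  }
  report <- data.frame(sample_id = rownames(m$data), count = cnt,
                       removed = removed, lower = lo, upper = hi,
                       row.names = NULL, stringsAsFactors = FALSE)
  keep <- !removed
  reps <- m$replicates
  if (!is.null(reps)) {
    ok <- reps[[1L]] %in% rownames(m$data)[keep] &
      reps[[2L]] %in% rownames(m$data)[keep]
    reps <- reps[ok, , drop = FALSE]
  }
  out <- new_aflp(m$data[keep, , drop = FALSE],
                  m$meta[keep, , drop = FALSE], reps)
  attr(out, "filter_report") <- report
  out
}

#' Euclidean distances between AFLP profiles
#'
#' `d(i,j) = sqrt(sum_l (x_il - x_jl)^2)` over mutually scored loci.
#'
#' @param m An `aflp_matrix` (or a plain 0/1 matrix).
#' @return Symmetric numeric distance matrix.
#' @export
euclidean_distance <- function(m) {
  x <- if (inherits(m, "aflp_matrix")) m$data else m
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (!anyNA(x)) {
    d[] <- as.matrix(stats::dist(x))
    return(d)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    d[i, j] <- d[j, i] <- sqrt(sum((x[i, ok] - x[j, ok])^2))
  }
  d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities) are
#' reported but excluded from the explained-variance denominator; an
#' eigenvalue counts as positive when it exceeds `1e-8` times the largest.
#'
#' @param d Square symmetric nonnegative distance matrix with zero diagonal.
#' @return A `pcoa_result`: list with `eigenvalues` (descending), `coordinates`
#'   (samples x positive axes), `explained` (percent per positive axis),
#'   `broken_stick` (expected proportions for the positive axes) and
#'   `n_positive`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) ||
      any(diag(d) != 0) || any(d < 0)) {
    stop("d must be a symmetric nonnegative matrix with zero diagonal")
  }
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- ev > 1e-8 * max(ev)
  npos <- sum(pos)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), npos, npos)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(npos))
  structure(list(eigenvalues = ev,
                 coordinates = coords,
                 explained = 100 * ev[pos] / sum(ev[pos]),
                 broken_stick = broken_stick(npos),
                 n_positive = npos),
            class = "pcoa_result")
}

#' Broken-stick expected eigenvalue proportions
#'
#' `b_k = (1/p) * sum_{i=k}^p 1/i`: the null expectation for ordination
#' eigenvalue proportions; observed axes above it are deemed interpretable.
#'
#' @param p Number of axes.
#' @return Numeric vector of proportions summing to 1.
#' @export
broken_stick <- function(p) {
  stopifnot(p >= 1)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' Number of PCoA axes above the broken-stick expectation
#'
#' Leading axes whose explained proportion exceeds the broken-stick value;
#' counting stops at the first axis that falls below.
#'
#' @param p A `pcoa_result`.
#' @return Integer number of retained axes.
#' @export
significant_axes <- function(p) {
  above <- (p$explained / 100) > p$broken_stick
  if (!above[1L]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

#' Per-region band statistics
#'
#' Fragments per region, private (unique) fragments, percent polymorphic
#' loci and Nei's gene diversity under the dominant-marker convention
#' (band frequencies treated as phenotype frequencies: per-locus diversity
#' `2 f (1-f)` with `f` the band frequency, averaged over scored loci).
#'
#' @param m An `aflp_matrix`.
#' @param group_by Metadata column defining regions (default `"region"`).
#' @return data.frame with one row per region.
#' @export
band_statistics <- function(m, group_by = "region") {
  g <- m$meta[[group_by]]
  if (is.null(g)) stop("metadata has no column '", group_by, "'")
  regions <- unique(g)
  present <- vapply(regions, function(r) {
    colSums(m$data[g == r, , drop = FALSE] == 1L, na.rm = TRUE) > 0
  }, logical(ncol(m$data)))
  n_regions_with <- rowSums(present)
  out <- lapply(regions, function(r) {
    sub <- m$data[g == r, , drop = FALSE]
    f <- colMeans(sub, na.rm = TRUE)
    scored <- !is.nan(f)
    poly <- f > 0 & f < 1 & scored
    data.frame(
      region = r,
      n = sum(g == r),
      fragments = sum(f > 0, na.rm = TRUE),
      unique_fragments = sum(present[, r] & n_regions_with == 1L),
      pct_polymorphic = 100 * sum(poly) / sum(scored),
      gene_diversity = mean(2 * f[scored] * (1 - f[scored])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' One-level AMOVA from a distance matrix
#'
#' Among/within sums of squares derived from squared pairwise distances
#' (`SS_total = sum d^2 / N` over all pairs, `SS_within` analogously within
#' groups); variance components via the usual expected mean squares with
#' `n0 = (N - sum n_g^2 / N) / (k - 1)`, and `Phi_ST` tested by permuting
#' group labels.
#'
#' @param d Square symmetric distance matrix.
#' @param groups Group label per sample (same order as `d`).
#' @param permutations Number of label permutations for the p-value
#'   (default 999).
#' @param seed Integer seed.
#' @return List with `Phi_ST`, `sigma2_among`, `sigma2_within`, `df`, `SS`,
#'   and `p`.
#' @export
amova <- function(d, groups, permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  N <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == N)
  d2 <- d^2
  phi_stat <- function(g) {
    SS_total <- sum(d2[upper.tri(d2)]) / N
    SS_within <- 0
    for (lab in unique(g)) {
      idx <- which(g == lab)
      if (length(idx) > 1) {
        sub <- d2[idx, idx, drop = FALSE]
        SS_within <- SS_within + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    SS_among <- SS_total - SS_within
    k <- length(unique(g))
    ng <- table(g)
    n0 <- (N - sum(ng^2) / N) / (k - 1)
    MS_among <- SS_among / (k - 1)
    MS_within <- SS_within / (N - k)
    s2w <- MS_within
    s2a <- (MS_among - MS_within) / n0
    list(phi = s2a / (s2a + s2w), s2a = s2a, s2w = s2w,
         SS = c(among = SS_among, within = SS_within, total = SS_total),
         df = c(among = k - 1, within = N - k))
  }
  obs <- phi_stat(groups)
  set.seed(seed)
  perm_phi <- replicate(permutations, phi_stat(sample(groups))$phi)
  p <- (sum(perm_phi >= obs$phi) + 1) / (permutations + 1)
  list(Phi_ST = obs$phi, sigma2_among = obs$s2a, sigma2_within = obs$s2w,
       df = obs$df, SS = obs$SS, p = p)
}

#' Evanno delta-K from clustering log-likelihood replicates
#'
#' `DeltaK(K) = mean_r |L(K+1) - 2 L(K) + L(K-1)| / sd_r L(K)`: the
#' second-order rate of change of the clustering log-probability across K,
#' normalised by the replicate standard deviation; the K maximising it is
#' the usual heuristic for the number of gene pools. Undefined at boundary K
#' and where the replicate standard deviation is zero (warned).
#'
#' @param lnP data.frame with columns `K`, `rep`, `lnP` (log-probability of
#'   the data for each replicate run at each K).
#' @return data.frame with columns `K`, `mean_lnP`, `sd_lnP`, `delta_K`
#'   (NA at boundaries / zero-variance K).
#' @export
evanno_delta_k <- function(lnP) {
  need <- c("K", "rep", "lnP")
  if (!all(need %in% names(lnP))) {
    stop("lnP needs columns: ", paste(need, collapse = ", "))
  }
  Ks <- sort(unique(lnP$K))
  if (length(Ks) < 3) stop("need >= 3 consecutive K values")
  stats_k <- lapply(Ks, function(k) {
    v <- lnP$lnP[lnP$K == k]
    if (length(v) < 2) stop("need >= 2 replicates at K=", k)
    c(mean = mean(v), sd = stats::sd(v))
  })
  mu <- vapply(stats_k, `[[`, numeric(1), "mean")
  sdv <- vapply(stats_k, `[[`, numeric(1), "sd")
  dk <- rep(NA_real_, length(Ks))
  for (i in seq(2, length(Ks) - 1)) {
    if (Ks[i + 1] - Ks[i] != Ks[i] - Ks[i - 1]) next  # non-consecutive
    if (sdv[i] == 0) {
      warning("zero replicate variance at K=", Ks[i], "; delta-K undefined")
      next
    }
    # mean over replicates of |L''|; replicates are unpaired across K, so
    # the mean second difference equals the second difference of means
    dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
  }
  data.frame(K = Ks, mean_lnP = mu, sd_lnP = sdv, delta_K = dk)
}
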