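#' Count segregating (polymorphic) sites
#'
#' @param aln A `hap_alignment` (n >= 2 samples); masked columns are ignored,
#'   `N` treated as missing.
#' @return Integer count of unmasked columns with at least two distinct
#'   non-missing states.
#' @export
segregating_sites <- function(aln) {
  if (nrow(aln$seq) < 2L) stop("need at least 2 sequences")
  seqm <- aln$seq[, !aln$mask, drop = FALSE]
  sum(apply(seqm, 2L, function(col) {
    length(unique(col[col != "N"])) >= 2L
  }))
}

#' Unbiased haplotype (gene) diversity
#'
#' Nei's unbiased estimator `Hd = n/(n-1) * (1 - sum(p_i^2))` from haplotype
#' counts.
#'
#' @param counts Vector of positive haplotype counts.
#' @return Hd in `[0, 1]`, or `NA` if `n < 2`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# pairwise difference counts and comparable-site lengths for all unordered
# pairs; pairwise deletion of N and masked columns.
pairwise_diffs <- function(aln) {
  seqm <- aln$seq[, !aln$mask, drop = FALSE]
  n <- nrow(seqm)
  miss <- seqm == "N"
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  diffs <- integer(nrow(idx))
  lens <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ok <- !miss[i, ] & !miss[j, ]
    lens[r] <- sum(ok)
    diffs[r] <- sum(seqm[i, ok] != seqm[j, ok])
  }
  list(i = idx[, 1L], j = idx[, 2L], diffs = diffs, lens = lens)
}

#' Nucleotide diversity
#'
#' Mean number of pairwise differences per sequence (`k_bar`) and per site
#' (`pi_site`), with pairwise deletion of missing data: each pair is compared
#' over its mutually scored unmasked sites and `pi_site` averages the per-pair
#' fraction of differing sites.
#'
#' @param aln A `hap_alignment` with n >= 2 samples.
#' @return List with `pi_site`, `k_bar` and `pi_percent` (= 100 * pi_site, the
#'   convention used in summary tables).
#' @export
nucleotide_diversity <- function(aln) {
  pd <- pairwise_diffs(aln)
  if (any(pd$lens == 0)) warning("some pairs share no scored sites")
  per_pair <- ifelse(pd$lens > 0, pd$diffs / pd$lens, NA_real_)
  pi_site <- mean(per_pair, na.rm = TRUE)
  list(pi_site = pi_site, k_bar = mean(pd$diffs), pi_percent = 100 * pi_site)
}

#' Tajima's D test statistic
#'
#' Contrasts the mean pairwise difference estimate of theta with the
#' segregating-sites (Watterson) estimate:
#' `D = (k_bar - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the standard
#' coefficients as functions of sample size.
#'
#' @param n Sample size (>= 4 for a meaningful test).
#' @param S Number of segregating sites.
#' @param k_bar Mean pairwise differences per sequence.
#' @return D, or `NA` when `S == 0` (undefined, not zero).
#' @export
tajimas_D <- function(n, S, k_bar) {
  if (n < 2) stop("n must be >= 2")
  if (S == 0) return(NA_real_)
  cc <- tajima_constants(n)
  (k_bar - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Coefficients of Tajima's D
#'
#' @param n Sample size (>= 2).
#' @return List with `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-group molecular diversity summary
#'
#' One row per group with n, segregating sites S, haplotype count h, haplotype
#' diversity Hd, nucleotide diversity (percent per site) and Tajima's D.
#' Group definitions may carry exclusion rules dropping samples of a named
#' haplotype from a named group (used e.g. to remove a genetically
#' intermediate accession from a refuge-area group).
#'
#' @param aln A masked `hap_alignment`.
#' @param hset Matching `haplotype_set`.
#' @param grouping Metadata column defining groups.
#' @param exclude Optional named list: group label -> haplotype ids to drop
#'   from that group.
#' @return data.frame with columns group, n, S, h, Hd, pi_percent, D.
#' @export
group_summary <- function(aln, hset, grouping = "region", exclude = NULL) {
  g <- aln$meta[[grouping]]
  if (is.null(g)) stop("metadata has no column '", grouping, "'")
  out <- lapply(unique(g), function(lab) {
    ids <- aln$meta$sample_id[g == lab]
    if (!is.null(exclude[[lab]])) {
      drop <- names(hset$assignment)[hset$assignment %in% exclude[[lab]]]
      ids <- setdiff(ids, drop)
    }
    sub <- subset_alignment(aln, ids)
    n <- length(ids)
    haps <- hset$assignment[ids]
    h <- length(unique(haps))
    if (n >= 2) {
      S <- segregating_sites(sub)
      nd <- nucleotide_diversity(sub)
      Hd <- haplotype_diversity(as.vector(table(haps)))
      D <- if (n >= 4) tajimas_D(n, S, nd$k_bar) else NA_real_
      data.frame(group = lab, n = n, S = S, h = h, Hd = Hd,
                 pi_percent = nd$pi_percent, D = D,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = lab, n = n, S = NA_integer_, h = h, Hd = NA_real_,
                 pi_percent = NA_real_, D = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Serialize a diversity summary in table form
#'
#' Writes the group summary as TSV with undefined D printed as an em dash,
#' Hd and pi to 3 decimals.
#'
#' @param summary data.frame from [group_summary()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_diversity_table <- function(summary, path) {
  fmt <- summary
  fmt$Hd <- sprintf("%.3f", summary$Hd)
  fmt$pi_percent <- sprintf("%.3f", summary$pi_percent)
  fmt$D <- ifelse(is.na(summary$D), "—", sprintf("%.4f", summary$D))
  utils::write.table(fmt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
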