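#' Pairwise difference matrix between haplotypes
#'
#' Hamming distances between haplotype representative sequences over unmasked,
#' mutually non-missing sites.
#'
#' @param hset A `haplotype_set`.
#' @return Symmetric integer matrix with zero diagonal, dimnames = haplotype
#'   ids.
#' @export
pairwise_difference_matrix <- function(hset) {
  seqs <- strsplit(hset$haplotypes$sequence, "")
  h <- length(seqs)
  d <- matrix(0L, h, h,
              dimnames = list(hset$haplotypes$haplotype_id,
                              hset$haplotypes$haplotype_id))
  if (h < 2) return(d)
  for (i in 1:(h - 1)) for (j in (i + 1):h) {
    a <- seqs[[i]]; b <- seqs[[j]]
    ok <- a != "N" & b != "N"
    d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
  }
  d
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the estimated probability
#' that two haplotypes `j` visible differences apart are separated by exactly
#' `j` mutations (i.e. connected parsimoniously) is at least `alpha`.
#'
#' The probability model: the true number of mutations `H` separating a random
#' pair of haplotypes under the neutral coalescent is geometric,
#' `P(H = h) = (1-r) r^h` with `r = M/(1+M)` and `M` the expected pairwise
#' mutation count, here estimated from the pair itself by Jukes-Cantor
#' correction of the observed fraction `j/L`. Mutations hit sites uniformly,
#' so the number of visibly different sites after `h` hits follows the
#' occupancy recursion `f(h+1, d) = f(h, d-1)(L-d+1)/L + f(h, d) d/L`. The
#' probability of parsimony is the posterior `P(H = j | d = j)`.
#'
#' @param L Number of comparable sites.
#' @param alpha Confidence level for the connection (default 0.95).
#' @param max_steps Cap on the search (default 50).
#' @return Integer connection limit `j`.
#' @export
connection_limit <- function(L, alpha = 0.95, max_steps = 50L) {
  if (L < 1) stop("L must be >= 1")
  j <- 0L
  while (j < max_steps &&
         parsimony_probability(j + 1L, L) >= alpha) {
    j <- j + 1L
  }
  j
}

#' Probability that j visible differences reflect exactly j mutations
#'
#' @param j Observed number of differing sites (>= 1).
#' @param L Number of comparable sites.
#' @param h_extra Tail length for the posterior sum over true mutation counts.
#' @return Probability in `[0, 1]`.
#' @keywords internal
#' @export
parsimony_probability <- function(j, L, h_extra = 80L) {
  if (j == 0L) return(1)
  if (j >= L) return(0)
  q <- j / L
  if (q >= 3 / 4) return(0)
  M <- -3 / 4 * L * log(1 - 4 * q / 3)  # JC-corrected expected mutations
  r <- M / (1 + M)
  hmax <- j + h_extra
  # occupancy: f[h, d] = P(d distinct sites hit | h mutations), log scale not
  # needed as probabilities stay in [0,1]
  f <- numeric(j + 1L)  # f[d+1] for current h
  f[1L] <- 1            # h = 0: zero sites hit
  num <- 0
  den <- 0
  for (h in seq_len(hmax)) {
    fn <- numeric(j + 1L)
    for (d in seq_len(j)) {
      fn[d + 1L] <- f[d] * (L - d + 1) / L + f[d + 1L] * d / L
    }
    f <- fn
    if (h >= j) {
      w <- r^h * f[j + 1L]
      den <- den + w
      if (h == j) num <- w
    }
  }
  if (den == 0) return(0)
  num / den
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are linked in increasing order of mutational distance;
#' links longer than the connection limit `j95` are refused, so clusters
#' further apart remain separate components. Within a distance class, links
#' joining components that were distinct at the start of the class are all
#' retained (ties become reticulations); ties are ordered by higher combined
#' haplotype frequency, then lexicographic id pair. Multi-step links are
#' materialised with `k - 1` inferred intermediate nodes so that every edge in
#' the final graph is a single mutational step.
#'
#' @param hset A `haplotype_set`.
#' @param dmat Distance matrix from [pairwise_difference_matrix()].
#' @param j95 Connection limit (steps), e.g. from [connection_limit()].
#' @return A `hap_network`: list with `nodes` (data.frame: id, type
#'   observed/inferred, freq), `edges` (data.frame: from, to, steps = 1),
#'   `links` (the accepted haplotype-to-haplotype links with their step
#'   counts) and `j95`.
#' @export
build_network <- function(hset, dmat, j95) {
  ids <- hset$haplotypes$haplotype_id
  freq <- stats::setNames(hset$haplotypes$n_members, ids)
  h <- length(ids)
  nodes <- data.frame(id = ids, type = "observed", freq = as.integer(freq),
                      stringsAsFactors = FALSE)
  links <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  if (h >= 2) {
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    cand <- data.frame(i = pr[, 1L], j = pr[, 2L],
                       d = dmat[pr], stringsAsFactors = FALSE)
    cand <- cand[cand$d <= j95, , drop = FALSE]
    cand$fsum <- freq[ids[cand$i]] + freq[ids[cand$j]]
    o <- order(cand$d, -cand$fsum, ids[cand$i], ids[cand$j])
    cand <- cand[o, , drop = FALSE]
    comp <- seq_len(h)  # union-find by relabel
    for (dval in unique(cand$d)) {
      cls <- cand[cand$d == dval, , drop = FALSE]
      comp_at_start <- comp
      for (r in seq_len(nrow(cls))) {
        ci <- comp_at_start[cls$i[r]]; cj <- comp_at_start[cls$j[r]]
        if (ci != cj) {
          links <- rbind(links, data.frame(
            from = ids[cls$i[r]], to = ids[cls$j[r]],
            steps = as.integer(dval), stringsAsFactors = FALSE))
          cc <- comp[cls$j[r]]
          comp[comp == cc] <- comp[cls$i[r]]
        }
      }
    }
  }
  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  n_inf <- 0L
  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      k <- links$steps[r]
      if (k == 1L) {
        edges <- rbind(edges, data.frame(from = links$from[r],
                                         to = links$to[r], steps = 1L,
                                         stringsAsFactors = FALSE))
      } else {
        chain <- c(links$from[r],
                   paste0("i", n_inf + seq_len(k - 1L)),
                   links$to[r])
        n_inf <- n_inf + k - 1L
        edges <- rbind(edges, data.frame(
          from = chain[-length(chain)], to = chain[-1L], steps = 1L,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (n_inf > 0L) {
    nodes <- rbind(nodes, data.frame(id = paste0("i", seq_len(n_inf)),
                                     type = "inferred", freq = 0L,
                                     stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges, links = links, j95 = j95),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("hap_network:", sum(x$nodes$type == "observed"), "observed +",
      sum(x$nodes$type == "inferred"), "inferred nodes,",
      nrow(x$edges), "unit edges; connection limit", x$j95, "steps\n")
  invisible(x)
}

#' Connected components of a haplotype network
#'
#' @param net A `hap_network`.
#' @return Named integer vector: observed node id -> component index.
#' @export
network_components <- function(net) {
  ids <- net$nodes$id
  comp <- stats::setNames(seq_along(ids), ids)
  for (r in seq_len(nrow(net$edges))) {
    a <- comp[net$edges$from[r]]; b <- comp[net$edges$to[r]]
    if (a != b) comp[comp == b] <- a
  }
  comp <- comp[net$nodes$id[net$nodes$type == "observed"]]
  stats::setNames(match(comp, unique(comp)), names(comp))
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net A `hap_network`.
#' @param edge_path TSV output (source, target, steps, inferred flag).
#' @param graphml_path Optional GraphML output for viewers.
#' @return Invisibly, the path(s).
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  inferred <- net$nodes$id[net$nodes$type == "inferred"]
  e <- net$edges
  e$inferred <- e$from %in% inferred | e$to %in% inferred
  utils::write.table(e, edge_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml_path)) {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="freq" for="node" attr.name="freq" attr.type="int"/>',
      '<graph edgedefault="undirected">',
      sprintf('<node id="%s"><data key="freq">%d</data></node>',
              net$nodes$id, net$nodes$freq),
      sprintf('<edge source="%s" target="%s"/>', e$from, e$to),
      '</graph>', '</graphml>')
    writeLines(lines, graphml_path)
  }
  invisible(c(edge_path, graphml_path))
}
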