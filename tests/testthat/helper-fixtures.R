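# small in-code fixtures shared across test files

toy_alignment <- function(seqs, region = "X", status = "native",
                          year = NA_integer_) {
  seqm <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(seqm) <- names(seqs)
  meta <- data.frame(sample_id = names(seqs),
                     region = rep_len(region, length(seqs)),
                     status = rep_len(status, length(seqs)),
                     year = rep_len(year, length(seqs)),
                     stringsAsFactors = FALSE)
  new_alignment(seqm, meta)
}

random_alignment <- function(n, L, n_var = 5, seed = 1) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqm <- matrix(rep(anc, each = n), nrow = n,
                 dimnames = list(paste0("s", seq_len(n)), NULL))
  sites <- sample.int(L, n_var)
  for (s in sites) {
    carriers <- sample.int(n, sample(1:(n - 1), 1))
    seqm[carriers, s] <- sample(setdiff(c("A", "C", "G", "T"), anc[s]), 1)
  }
  meta <- data.frame(sample_id = rownames(seqm),
                     region = sample(c("A", "B", "C"), n, replace = TRUE),
                     status = "native", stringsAsFactors = FALSE)
  new_alignment(seqm, meta)
}

toy_aflp <- function(data, year = NULL, pool = NULL, replicates = NULL) {
  if (is.null(rownames(data))) rownames(data) <- paste0("s", seq_len(nrow(data)))
  meta <- data.frame(sample_id = rownames(data),
                     region = if (is.null(pool)) "X" else pool,
                     year = if (is.null(year)) 2010L else year,
                     stringsAsFactors = FALSE)
  new_aflp(data, meta, replicates)
}

# independent Prim MST oracle on a distance matrix (test-side implementation)
prim_mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(integer(0), ncol = 2)
  while (sum(in_tree) < n) {
    best <- c(NA, NA); bw <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (d[i, j] < bw) { bw <- d[i, j]; best <- c(i, j) }
    }
    edges <- rbind(edges, sort(best))
    in_tree[best[2]] <- TRUE
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}
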