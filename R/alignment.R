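#' Read an aligned plastid FASTA plus sample metadata
#'
#' Joins an aligned multi-FASTA with a tab-separated metadata table keyed by
#' `sample_id` into a `hap_alignment` object. Every FASTA record must have a
#' metadata row; records without one are rejected (the alignment is assumed to
#' be the final, curated sample set).
#'
#' @param fasta_path Path to an aligned FASTA file (equal-length records).
#' @param metadata_path Path to a TSV with columns `sample_id`, `region`,
#'   `status`, and optionally `year`, `lon`, `lat`.
#' @return A `hap_alignment`: list with `seq` (character matrix, samples x
#'   sites, uppercase), `meta` (data.frame) and `mask` (logical vector of
#'   excluded columns, all `FALSE` on read).
#' @seealso [mask_homopolymer_variation()], [collapse_haplotypes()]
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  recs <- ape::read.FASTA(fasta_path)
  if (length(recs) == 0L) stop("empty FASTA: ", fasta_path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: unequal sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  seq <- toupper(do.call(rbind, as.character(recs)))
  rownames(seq) <- names(recs)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  new_alignment(seq, meta)
}

#' Construct a hap_alignment from in-memory parts
#'
#' @param seq Character matrix (samples x sites) over `A,C,G,T,-,N`
#'   (lower case accepted).
#' @param meta data.frame with at least `sample_id`; row order is reconciled
#'   to the sequence rows.
#' @param mask Optional logical vector of masked (excluded) columns.
#' @return A `hap_alignment` object.
#' @export
new_alignment <- function(seq, meta, mask = NULL) {
  seq <- toupper(seq)
  ids <- rownames(seq)
  if (is.null(ids)) stop("input error: sequences must be named by sample_id")
  if (anyDuplicated(ids)) {
    stop("input error: duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- setdiff(unique(as.vector(seq)), c("A", "C", "G", "T", "-", "N", "?"))
  if (length(bad)) {
    stop("input error: unknown alignment character(s): ",
         paste(bad, collapse = ", "))
  }
  seq[seq == "?"] <- "N"
  if (!"sample_id" %in% names(meta)) {
    stop("input error: metadata lacks a sample_id column")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("input error: duplicate sample ids in metadata")
  }
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("input error: samples absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(meta$lon) &&
      any(stats::na.omit(meta$lon) < -180 | stats::na.omit(meta$lon) > 180)) {
    stop("input error: longitude outside [-180, 180]")
  }
  if (!is.null(meta$lat) &&
      any(stats::na.omit(meta$lat) < -90 | stats::na.omit(meta$lat) > 90)) {
    stop("input error: latitude outside [-90, 90]")
  }
  if (is.null(mask)) mask <- rep(FALSE, ncol(seq))
  stopifnot(length(mask) == ncol(seq))
  structure(list(seq = seq, meta = meta, mask = mask),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment:", nrow(x$seq), "samples x", ncol(x$seq), "sites;",
      sum(x$mask), "masked column(s)\n")
  invisible(x)
}

#' Subset an alignment to a set of samples
#'
#' @param aln A `hap_alignment`.
#' @param ids Character vector of sample ids (or logical/integer index).
#' @return A `hap_alignment` restricted to the selected samples, mask kept.
#' @export
subset_alignment <- function(aln, ids) {
  if (is.character(ids)) {
    miss <- setdiff(ids, rownames(aln$seq))
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    idx <- match(ids, rownames(aln$seq))
  } else idx <- ids
  new_alignment(aln$seq[idx, , drop = FALSE],
                aln$meta[idx, , drop = FALSE], aln$mask)
}

#' Drop alignment columns below a completeness cutoff
#'
#' Trims columns whose fraction of non-missing (`A/C/G/T/-` vs `N`) characters
#' falls below `min_complete`, emulating the usual curation step that reduces a
#' raw concatenated alignment to its well-covered core before haplotyping.
#'
#' @param aln A `hap_alignment`.
#' @param min_complete Minimum fraction of non-`N` characters per column
#'   (default 1: only fully scored columns kept).
#' @return A trimmed `hap_alignment` (mask subset accordingly).
#' @export
trim_alignment <- function(aln, min_complete = 1) {
  frac <- colMeans(aln$seq != "N")
  keep <- frac >= min_complete
  new_alignment(aln$seq[, keep, drop = FALSE], aln$meta, aln$mask[keep])
}

#' Write a hap_alignment back to FASTA + metadata TSV
#'
#' @param aln A `hap_alignment`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path) {
  seqs <- apply(aln$seq, 1L, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)
  utils::write.table(aln$meta, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Mask homopolymer length variation
#'
#' Plastid mononucleotide runs (poly-A/T/G/C) mutate by replication slippage at
#' rates far above the substitution rate, so run-length differences are noise
#' for haplotyping. A variable column is flagged as excluded when (a) its
#' non-missing states are exactly one base plus the gap character (pure
#' length variation) and (b) in at least one sequence the column sits inside a
#' run of that base of length >= `min_run` (gaps inside the stretch do not
#' count towards the run length but do not break it). Substitutions inside
#' runs (two different bases observed) are always retained.
#'
#' Masking is idempotent: the flags are a pure function of the sequences.
#'
#' @param aln A `hap_alignment`.
#' @param min_run Minimum run length (>= 2) that triggers masking; default 3.
#' @return The alignment with an updated `mask`.
#' @export
mask_homopolymer_variation <- function(aln, min_run = 3L) {
  if (min_run < 2L) stop("min_run must be >= 2")
  seq <- aln$seq
  L <- ncol(seq)
  mask <- aln$mask
  for (j in seq_len(L)) {
    col <- seq[, j]
    states <- unique(col[col != "N"])
    if (length(states) != 2L || !("-" %in% states)) next
    b <- setdiff(states, "-")
    # pure base/gap variation: check run context in every sequence carrying b
    hit <- FALSE
    for (i in which(col == b)) {
      row <- seq[i, ]
      lo <- j
      while (lo > 1L && row[lo - 1L] %in% c(b, "-")) lo <- lo - 1L
      hi <- j
      while (hi < L && row[hi + 1L] %in% c(b, "-")) hi <- hi + 1L
      if (sum(row[lo:hi] == b) >= min_run) { hit <- TRUE; break }
    }
    if (hit) mask[j] <- TRUE
  }
  aln$mask <- mask
  aln
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical over all unmasked sites are grouped into one haplotype;
#' ids are assigned `H1`, `H2`, ... in order of first appearance, so the
#' labelling is deterministic under re-runs. With `treat_N_as = "missing"`
#' (default) a sequence containing `N` joins an existing haplotype iff it is
#' compatible (equal wherever both are non-`N`) with exactly one; ambiguous
#' multi-way compatibility triggers a warning and the sequence founds its own
#' haplotype. With `treat_N_as = "state"`, `N` is compared literally.
#'
#' @param aln A (typically masked) `hap_alignment`.
#' @param treat_N_as Either `"missing"` or `"state"`.
#' @return A `haplotype_set`: list with `haplotypes` (data.frame: id,
#'   representative sequence string), `members` (named list id -> sample ids)
#'   and `assignment` (named character vector sample_id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, treat_N_as = c("missing", "state")) {
  treat_N_as <- match.arg(treat_N_as)
  use <- !aln$mask
  seqm <- aln$seq[, use, drop = FALSE]
  ids <- rownames(aln$seq)
  n <- nrow(seqm)
  reps <- list()        # representative character vectors
  members <- list()
  assignment <- character(n)
  for (i in seq_len(n)) {
    s <- seqm[i, ]
    if (treat_N_as == "state") {
      key <- paste0(s, collapse = "")
      hit <- which(vapply(reps, function(r) identical(paste0(r, collapse = ""), key),
                          logical(1)))
    } else {
      compat <- vapply(reps, function(r) {
        cmp <- s != "N" & r != "N"
        all(s[cmp] == r[cmp])
      }, logical(1))
      hit <- which(compat)
      if (length(hit) > 1L) {
        # exact matches take precedence over N-wildcard compatibility
        exact <- hit[vapply(hit, function(h) all(reps[[h]] == s), logical(1))]
        if (length(exact) == 1L) hit <- exact
      }
    }
    if (length(hit) == 1L) {
      members[[hit]] <- c(members[[hit]], ids[i])
      # fill N's in the representative where this member is scored
      r <- reps[[hit]]
      fill <- r == "N" & s != "N"
      if (any(fill)) { r[fill] <- s[fill]; reps[[hit]] <- r }
      assignment[i] <- names(members)[hit]
    } else {
      if (length(hit) > 1L) {
        warning("sample ", ids[i], " is N-compatible with ", length(hit),
                " haplotypes; assigning it its own haplotype")
      }
      hid <- paste0("H", length(reps) + 1L)
      reps[[length(reps) + 1L]] <- s
      members[[hid]] <- ids[i]
      assignment[i] <- hid
    }
  }
  names(assignment) <- ids
  hap <- data.frame(
    haplotype_id = names(members),
    sequence = vapply(reps, paste0, character(1), collapse = ""),
    n_members = lengths(members),
    stringsAsFactors = FALSE
  )
  structure(list(haplotypes = hap, members = members, assignment = assignment),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haplotypes), "haplotypes over",
      length(x$assignment), "samples\n")
  invisible(x)
}

#' Haplotype frequency table per group
#'
#' Cross-tabulates haplotype membership against a metadata grouping, the
#' per-region haplotype frequency summary of a phylogeographic survey.
#'
#' @param hset A `haplotype_set` from [collapse_haplotypes()].
#' @param aln The `hap_alignment` the set was derived from.
#' @param group_by Metadata column to group by (e.g. `"region"` or `"status"`).
#' @return An integer matrix, groups x haplotypes; row sums equal group sizes.
#' @export
frequency_table <- function(hset, aln, group_by = "region") {
  if (!group_by %in% names(aln$meta)) {
    stop("metadata has no column '", group_by, "'")
  }
  g <- aln$meta[[group_by]][match(names(hset$assignment), aln$meta$sample_id)]
  tab <- table(group = g, haplotype = hset$assignment)
  hap_order <- hset$haplotypes$haplotype_id
  m <- matrix(0L, nrow = nrow(tab), ncol = length(hap_order),
              dimnames = list(rownames(tab), hap_order))
  m[, colnames(tab)] <- tab
  m
}
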