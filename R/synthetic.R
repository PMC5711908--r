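#' Default synthetic study specification
#'
#' Conditions emulating the structure of a two-gene-pool Eurasian
#' phylogeography survey: an old, diverse refuge-area pool with a deep
#' expansion signal, a younger derived pool with a shallow one, recently
#' colonized regions sampled from the derived pool, a two-pool
#' dominant-marker (AFLP) panel with replicate pairs and herbarium-style
#' degradation, and a landscape with a planted variance partition.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return Nested list understood by [make_sequence_dataset()],
#'   [make_aflp_dataset()] and [make_landscape()].
#' @export
synthetic_spec <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sequences = list(
      L = 1512,
      pool_divergence = 10,  # fixed differences between gene pools
      groups = list(
        list(name = "Caucasus-Irano-Turanian", pool = "CIT", n = 25,
             tau = 11.34, theta0 = 1, theta1 = 1000, status = "native"),
        list(name = "Europe", pool = "EU", n = 52,
             tau = 2.84, theta0 = 0.5, theta1 = 1000, status = "invasive"),
        list(name = "Scandinavia", pool = "EU", n = 41,
             tau = 1, theta0 = 0.1, theta1 = 100, status = "invasive"),
        list(name = "North America", pool = "EU", n = 19,
             tau = 2, theta0 = 0.5, theta1 = 500, status = "exotic")
      )
    ),
    aflp = list(
      n_per_pool = c(CIT = 40, EU = 94), loci = 404,
      replicate_pairs = 50, error_rate = 0.011,
      year_range = c(1950, 2015), ref_year = 2003,
      degradation_slope = 0.0015  # per-year band-loss probability before cutoff
    ),
    landscape = list(
      n = 400, q_axes = 4,
      fractions = c(condition = 0.25, spatial = 0.25, climate = 0,
                    noise = 0.50)
    )
  )
}

#' Simulate a two-pool plastid sequence dataset
#'
#' Per-group coalescent samples (each group under its own sudden-expansion
#' history) with the two gene pools separated by a fixed number of planted
#' differences; truth labels (`pool`) are embedded in the metadata. Groups
#' in the same pool share ancestry only through the planted pool haplotype,
#' which keeps pool separation exact while within-pool variation follows the
#' coalescent.
#'
#' @param spec A spec list (see [synthetic_spec()]); `spec$sequences` used.
#' @param seed Optional override of `spec$seed`.
#' @return List with `alignment` (a `hap_alignment` whose metadata carries
#'   `region`, `status`, `pool`) and `truth` (the group parameters).
#' @export
make_sequence_dataset <- function(spec = synthetic_spec(), seed = NULL) {
  sq <- spec$sequences
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  L <- sq$L
  pools <- unique(vapply(sq$groups, `[[`, character(1), "pool"))
  # planted fixed differences between consecutive pools
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pool_seq <- list()
  pool_seq[[pools[1]]] <- anc
  if (length(pools) > 1) {
    div_sites <- sample.int(L, sq$pool_divergence * (length(pools) - 1))
    for (k in seq(2, length(pools))) {
      s <- pool_seq[[pools[k - 1]]]
      sites <- div_sites[seq((k - 2) * sq$pool_divergence + 1,
                             (k - 1) * sq$pool_divergence)]
      for (site in sites) {
        s[site] <- sample(setdiff(c("A", "C", "G", "T"), s[site]), 1)
      }
      pool_seq[[pools[k]]] <- s
    }
  }
  seqs <- list(); metas <- list()
  used_sites <- if (length(pools) > 1) div_sites else integer(0)
  for (g in sq$groups) {
    sub <- coalescent_simulate(g$n, g$theta0, g$theta1, g$tau, L,
                               ids = paste0(gsub("[^A-Za-z]", "", g$name),
                                            "_", seq_len(g$n)),
                               region = g$name, status = g$status)
    # re-base the group's simulated variation onto its pool sequence:
    # mutated sites keep their derived/ancestral pattern, unmutated sites
    # take the pool background; avoid colliding with planted pool sites
    base <- pool_seq[[g$pool]]
    varying <- which(apply(sub$seq, 2, function(col) length(unique(col)) > 1))
    varying <- setdiff(varying, used_sites)
    m <- matrix(rep(base, each = g$n), nrow = g$n,
                dimnames = list(rownames(sub$seq), NULL))
    for (site in varying) {
      col <- sub$seq[, site]
      major <- names(sort(table(col), decreasing = TRUE))[1]
      m[col != major, site] <- vapply(which(col != major), function(i) {
        sample(setdiff(c("A", "C", "G", "T"), base[site]), 1)
      }, character(1))
    }
    used_sites <- c(used_sites, varying)
    meta <- sub$meta
    meta$pool <- g$pool
    seqs[[g$name]] <- m
    metas[[g$name]] <- meta
  }
  seqm <- do.call(rbind, seqs)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  list(alignment = new_alignment(seqm, meta), truth = sq)
}

#' Simulate a two-pool AFLP dataset with replicates and degradation
#'
#' Band frequencies per pool are drawn per locus (Beta-distributed allele
#' frequencies under the dominant-marker convention: presence probability
#' `1 - (1-p)^2` for null-allele frequency `1-p`); replicate copies of a
#' subset of samples are rescored with a per-locus flip probability equal to
#' the target error rate; samples collected before the reference year lose
#' bands (1 -> 0 flips only) with probability proportional to their age
#' before the cutoff.
#'
#' @param spec A spec list (see [synthetic_spec()]); `spec$aflp` used.
#' @param seed Optional override of `spec$seed`.
#' @return List with `aflp` (an `aflp_matrix` whose metadata carries `pool`,
#'   `year`, `batch`) and `truth` (generator parameters incl. the planted
#'   degraded sample ids).
#' @export
make_aflp_dataset <- function(spec = synthetic_spec(), seed = NULL) {
  af <- spec$aflp
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed + 1L)
  loci <- af$loci
  pools <- names(af$n_per_pool)
  # pool-specific allele frequencies; shared base with pool-specific shifts
  base_q <- stats::rbeta(loci, 2, 1.2)   # null-allele freq q
  rows <- list(); metas <- list()
  for (p in pools) {
    qp <- base_q
    shift <- sample.int(loci, round(loci / 3))
    qp[shift] <- stats::rbeta(length(shift), 2, 1.2)
    pres <- 1 - qp^2  # band presence probability 1-(1-p)^2 with p = 1-q
    n <- af$n_per_pool[[p]]
    m <- matrix(stats::rbinom(n * loci, 1L, rep(pres, each = n)), nrow = n)
    rownames(m) <- paste0(p, "_", seq_len(n))
    rows[[p]] <- m
    metas[[p]] <- data.frame(
      sample_id = rownames(m), pool = p,
      region = p, stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  colnames(data) <- paste0("L", seq_len(loci))
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  n_all <- nrow(data)
  meta$year <- sample(seq(af$year_range[1], af$year_range[2]), n_all,
                      replace = TRUE)
  meta$batch <- sample(c("plate1", "plate2"), n_all, replace = TRUE)
  # degradation: pre-cutoff samples lose bands, linear in years before cutoff
  old <- which(meta$year < af$ref_year)
  for (i in old) {
    p_loss <- min(1, af$degradation_slope * (af$ref_year - meta$year[i]))
    on <- which(data[i, ] == 1L)
    flip <- on[stats::runif(length(on)) < p_loss]
    data[i, flip] <- 0L
  }
  # replicate copies with symmetric flip noise
  n_rep <- min(af$replicate_pairs, n_all)
  rep_of <- sample.int(n_all, n_rep)
  rep_ids <- paste0(rownames(data)[rep_of], "_rep")
  rep_rows <- data[rep_of, , drop = FALSE]
  flips <- matrix(stats::runif(n_rep * loci) < af$error_rate, nrow = n_rep)
  rep_rows[flips] <- 1L - rep_rows[flips]
  rownames(rep_rows) <- rep_ids
  rep_meta <- meta[rep_of, , drop = FALSE]
  rep_meta$sample_id <- rep_ids
  data <- rbind(data, rep_rows)
  meta <- rbind(meta, rep_meta)
  rownames(meta) <- NULL
  replicates <- data.frame(sample_id = rownames(data)[rep_of],
                           replicate_id = rep_ids, stringsAsFactors = FALSE)
  list(aflp = new_aflp(data, meta, replicates),
       truth = c(af, list(degraded_ids = rownames(data)[old])))
}

#' Simulate a landscape with a planted RDA variance partition
#'
#' Builds a multivariate response as the sum of mutually orthogonalized
#' components — a binary gene-pool (condition) effect, a smooth degree-2
#' polynomial spatial surface in Z-standardized coordinates, optional climate
#' effects, and white noise — each rescaled so its share of the total sum of
#' squares equals the planted fraction exactly at the sample level.
#'
#' @param spec A spec list (see [synthetic_spec()]); `spec$landscape` used.
#' @param seed Optional override of `spec$seed`.
#' @return List with `Y` (response matrix), `coords` (lon/lat data.frame),
#'   `climate` (4 standardized covariates), `condition` (0/1 vector) and
#'   `truth` (planted fractions).
#' @export
make_landscape <- function(spec = synthetic_spec(), seed = NULL) {
  ls <- spec$landscape
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed + 2L)
  n <- ls$n; q <- ls$q_axes
  fr <- ls$fractions
  stopifnot(abs(sum(fr) - 1) < 1e-8)
  lon <- stats::runif(n, -10, 60)
  lat <- stats::runif(n, 35, 70)
  zx <- scale(lon)[, 1]; zy <- scale(lat)[, 1]
  condition <- stats::rbinom(n, 1L, 0.5)
  climate <- scale(matrix(stats::rnorm(n * 4), n,
                          dimnames = list(NULL, paste0("bio", c(10, 11, 18, 19)))))
  # raw components in response space
  load <- function(v) outer(as.vector(v), stats::rnorm(q))
  comp_cond <- load(condition - mean(condition))
  surf <- zx + 0.8 * zy - 0.6 * zx * zy + 0.5 * zy^2   # degree-2 surface
  comp_space <- load(surf - mean(surf))
  comp_clim <- load(climate %*% stats::rnorm(4))
  comp_noise <- matrix(stats::rnorm(n * q), n)
  # orthogonalize sequentially so the planted shares are exact
  comps <- list(cond = comp_cond, space = comp_space, clim = comp_clim,
                noise = comp_noise)
  basis <- matrix(1, n, 1)
  for (k in seq_along(comps)) {
    comps[[k]] <- resid_on(comps[[k]], basis[, -1, drop = FALSE])
    basis <- cbind(basis, comps[[k]])
  }
  target <- c(fr["condition"], fr["spatial"], fr["climate"], fr["noise"])
  Y <- matrix(0, n, q)
  for (k in seq_along(comps)) {
    ss <- sum(comps[[k]]^2)
    if (target[k] > 0 && ss > 0) {
      Y <- Y + comps[[k]] * sqrt(target[k] / ss)
    }
  }
  colnames(Y) <- paste0("axis", seq_len(q))
  list(Y = Y, coords = data.frame(lon = lon, lat = lat),
       climate = climate, condition = condition, truth = fr)
}

#' Write a synthetic bundle to a directory
#'
#' Emits the sequence dataset (FASTA + metadata TSV), the AFLP dataset
#' (matrix CSV + metadata TSV + replicate TSV) and the landscape tables in
#' the formats the analysis functions consume.
#'
#' @param spec A spec list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_synthetic_bundle <- function(spec = synthetic_spec(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    seq_meta = file.path(dir, "sequence_metadata.tsv"),
    aflp = file.path(dir, "aflp_matrix.csv"),
    aflp_meta = file.path(dir, "aflp_metadata.tsv"),
    replicates = file.path(dir, "aflp_replicates.tsv"),
    response = file.path(dir, "landscape_response.tsv"),
    coords = file.path(dir, "landscape_coords.tsv"),
    climate = file.path(dir, "landscape_climate.tsv"),
    condition = file.path(dir, "landscape_condition.tsv"),
    truth = file.path(dir, "truth.json")
  )
  sq <- make_sequence_dataset(spec)
  write_alignment(sq$alignment, paths["fasta"], paths["seq_meta"])
  af <- make_aflp_dataset(spec)
  write_aflp(af$aflp, paths["aflp"], paths["aflp_meta"], paths["replicates"])
  lsc <- make_landscape(spec)
  utils::write.table(lsc$Y, paths["response"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(lsc$coords, paths["coords"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(lsc$climate), paths["climate"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(condition = lsc$condition),
                     paths["condition"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(landscape = as.list(lsc$truth),
                            aflp_error_rate = spec$aflp$error_rate),
                       paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
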