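#' Default pipeline configuration
#'
#' @param out_dir Output directory for stage results.
#' @param seed Global seed; per-stage seeds are derived from it by a stable
#'   offset per stage name so that toggling one stage does not perturb the
#'   randomness of the others.
#' @return Config list; paths are NULL until filled in.
#' @export
pipeline_config <- function(out_dir = "hapdemog_run", seed = 1L) {
  list(
    alignment = NULL, metadata = NULL,          # sequence inputs
    aflp_matrix = NULL, aflp_metadata = NULL, aflp_replicates = NULL,
    out_dir = out_dir, seed = as.integer(seed),
    min_run = 3L, group_by = "region", exclude = NULL,
    mu = 2.004e-9, seq_len = 1512, gen_time = 2,
    bootstrap = 1000L, alpha = 0.95,
    filter_ref_year = 2003, k_sigma = 2,
    stages = c(haplotypes = TRUE, diversity = TRUE, network = TRUE,
               mismatch = TRUE, aflp = FALSE)
  )
}

# stable per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  (seed + sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))) %% .Machine$integer.max
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes haplotyping, diversity statistics, the parsimony network and the
#' mismatch analysis (and optionally the AFLP stage) on the configured
#' inputs, writing per-stage TSV/JSON outputs, a JSON manifest with seeds,
#' parameters and file checksums, and a log. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config Config list from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  st <- cfg$stages
  if (isTRUE(st[["haplotypes"]]) &&
      (is.null(cfg$alignment) || is.null(cfg$metadata))) {
    stop("config error: haplotype stage enabled but alignment/metadata missing")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), sprintf(...),
                            "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, file.path(cfg$out_dir, name))
    file.path(cfg$out_dir, name)
  }
  logf("time conversion: T = tau/(2*mu*k*g), mu=%g, k=%d, g=%g",
       cfg$mu, cfg$seq_len, cfg$gen_time)
  run_stage <- function(stage, f) {
    logf("stage %s: start", stage)
    res <- tryCatch(f(), error = function(e) {
      logf("stage %s: FAILED: %s", stage, conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage %s: done", stage)
    res
  }
  aln <- hset <- NULL
  if (isTRUE(st[["haplotypes"]])) {
    hap <- run_stage("haplotypes", function() {
      a <- read_alignment(cfg$alignment, cfg$metadata)
      a <- mask_homopolymer_variation(a, cfg$min_run)
      h <- collapse_haplotypes(a)
      utils::write.table(
        data.frame(sample_id = names(h$assignment),
                   haplotype_id = unname(h$assignment)),
        emit("haplotype_assignment.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      ft <- frequency_table(h, a, cfg$group_by)
      utils::write.table(cbind(group = rownames(ft), as.data.frame(ft)),
                         emit("haplotype_frequencies.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(aln = a, hset = h)
    })
    aln <- hap$aln; hset <- hap$hset
  }
  if (isTRUE(st[["diversity"]])) {
    run_stage("diversity", function() {
      gs <- group_summary(aln, hset, cfg$group_by, cfg$exclude)
      write_diversity_table(gs, emit("diversity.tsv"))
    })
  }
  if (isTRUE(st[["network"]])) {
    run_stage("network", function() {
      dmat <- pairwise_difference_matrix(hset)
      j95 <- connection_limit(sum(!aln$mask), cfg$alpha)
      net <- build_network(hset, dmat, j95)
      write_network(net, emit("network_edges.tsv"), emit("network.graphml"))
    })
  }
  if (isTRUE(st[["mismatch"]])) {
    run_stage("mismatch", function() {
      rate <- rate_model(cfg$mu, cfg$seq_len, cfg$gen_time)
      groups <- unique(aln$meta[[cfg$group_by]])
      rows <- lapply(groups, function(gname) {
        ids <- aln$meta$sample_id[aln$meta[[cfg$group_by]] == gname]
        if (!is.null(cfg$exclude[[gname]])) {
          drop <- names(hset$assignment)[hset$assignment %in% cfg$exclude[[gname]]]
          ids <- setdiff(ids, drop)
        }
        if (length(ids) < 3) return(NULL)
        fit <- mismatch_analysis(subset_alignment(aln, ids), rate,
                                 B = cfg$bootstrap,
                                 seed = stage_seed(cfg$seed, paste0("mismatch.", gname)))
        data.frame(group = gname, SSD = fit$SSD, p_SSD = fit$p_SSD,
                   HRag = fit$HRag, p_HRag = fit$p_HRag,
                   tau = fit$tau, tau_lo = fit$tau_CI[1],
                   tau_hi = fit$tau_CI[2],
                   T_years = fit$T_years, T_lo = fit$T_CI[1],
                   T_hi = fit$T_CI[2], stringsAsFactors = FALSE)
      })
      utils::write.table(do.call(rbind, rows), emit("mismatch.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    })
  }
  if (isTRUE(st[["aflp"]])) {
    run_stage("aflp", function() {
      m <- read_aflp(cfg$aflp_matrix, cfg$aflp_metadata, cfg$aflp_replicates)
      err <- if (!is.null(m$replicates)) replicate_error_rate(m) else NA_real_
      mf <- fragment_filter(m, cfg$filter_ref_year, cfg$k_sigma)
      pc <- pcoa(euclidean_distance(mf))
      utils::write.table(
        data.frame(sample_id = rownames(pc$coordinates),
                   pc$coordinates[, seq_len(min(5, ncol(pc$coordinates)))]),
        emit("aflp_pcoa.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(error_rate = err, n_retained = nrow(mf$data),
             n_positive_eigenvalues = pc$n_positive,
             explained_first3 = pc$explained[seq_len(min(3, pc$n_positive))]),
        emit("aflp_summary.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("hapdemog")),
    seed = cfg$seed,
    parameters = cfg[c("min_run", "group_by", "mu", "seq_len", "gen_time",
                       "bootstrap", "alpha", "filter_ref_year", "k_sigma")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
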