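#' End-to-end pipeline
#'
#' Orchestrates simulate -> build -> metrics -> asymmetry -> stats as one
#' reproducible run: given a run configuration it either reads an existing
#' cohort directory or simulates one, computes the hemispheric metric
#' table (with optional small-world normalization), the per-subject
#' asymmetry table, and the statistical report tables, writing everything
#' as tab-separated files plus a manifest with content digests.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' @param out_dir output directory for the run
#' @param cohort_dir existing cohort directory (see [read_cohort()]);
#'   `NULL` to simulate from `spec`
#' @param spec a [synthetic_spec()] used when `cohort_dir` is `NULL`
#' @param fn_threshold fiber-count cutoff, default 3
#' @param n_nulls matched random networks per hemisphere (0 disables the
#'   small-world normalization), default 100
#' @param alpha significance level, default 0.05
#' @param seed master seed for null ensembles (and, when simulating, the
#'   cohort unless `spec` sets its own)
#' @param verbose print per-stage progress to standard error
#' @return a `run_config` list
#' @export
run_config <- function(out_dir, cohort_dir = NULL, spec = synthetic_spec(),
                       fn_threshold = 3, n_nulls = 100, alpha = 0.05,
                       seed = 1L, verbose = TRUE) {
  stopifnot(fn_threshold >= 0, n_nulls >= 0, alpha > 0, alpha < 1)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir, spec = spec,
                 fn_threshold = fn_threshold, n_nulls = n_nulls,
                 alpha = alpha, seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

#' Execute a full pipeline run
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the in-memory stage outputs (`cohort`,
#'   `metrics`, `asymmetry`, `stats`) and the manifest data.frame
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_msg <- function(...) if (config$verbose) message("[hemiasym] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$cohort_dir)) {
    log_msg("simulating cohort (seed ", config$spec$seed, ")")
    cohort <- generate_cohort(config$spec)
    write_cohort(file.path(config$out_dir, "cohort"), cohort)
  } else {
    log_msg("reading cohort from ", config$cohort_dir)
    cohort <- read_cohort(config$cohort_dir)
  }

  log_msg("computing metrics (FN > ", config$fn_threshold, ", ",
          config$n_nulls, " nulls)")
  metrics <- cohort_metrics(cohort$connectomes, cohort$parcellation,
                            threshold = config$fn_threshold,
                            n_nulls = config$n_nulls, seed = config$seed)
  log_msg("computing asymmetry scores")
  asym <- cohort_asymmetry(metrics)
  log_msg("running statistics")
  stats_out <- run_statistics(metrics, asym, cohort$metadata,
                              alpha = config$alpha)

  write_tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(write_tsv(metrics, "metrics.tsv"),
             write_tsv(asym, "asymmetry.tsv"),
             write_tsv(cohort$metadata, "metadata.tsv"),
             vapply(names(stats_out), function(nm)
               write_tsv(stats_out[[nm]], paste0(nm, ".tsv")),
               character(1)))
  manifest <- data.frame(
    file = basename(paths),
    rows = vapply(c(list(metrics, asym, cohort$metadata), stats_out),
                  nrow, integer(1)),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE)
  cfg_lines <- c(sprintf("fn_threshold\t%s", config$fn_threshold),
                 sprintf("n_nulls\t%s", config$n_nulls),
                 sprintf("alpha\t%s", config$alpha),
                 sprintf("seed\t%s", config$seed),
                 sprintf("n_subjects\t%s", nrow(cohort$metadata)))
  writeLines(cfg_lines, file.path(config$out_dir, "config.tsv"))
  write_tsv(manifest, "manifest.tsv")
  log_msg(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, "secs")))
  invisible(list(cohort = cohort, metrics = metrics, asymmetry = asym,
                 stats = stats_out, manifest = manifest))
}

#' Build the miniature packaged test cohort
#'
#' A deterministic six-subject cohort with 10 regions per hemisphere that
#' exercises every code path quickly: both groups, spurious low-count
#' edges, one edge with fiber count exactly 3 (removed by the default
#' filter), and one region (`R10`) isolated in both hemispheres of every
#' subject, producing a zero-denominator asymmetry score.
#'
#' @param out_dir directory to write the cohort into
#' @return the cohort list, invisibly
#' @export
make_fixtures <- function(out_dir) {
  spec <- synthetic_spec(n_patients = 3, n_controls = 3,
                         n_regions_per_hemisphere = 10,
                         edge_density = 0.5, noise_sd = 0.03,
                         delta_right_control = 0.1,
                         clinical_link = default_clinical_link("R03"),
                         spurious_edge_rate = 0.1, seed = 42L)
  cohort <- generate_cohort(spec)
  # fixed balanced demographics keep the tiny covariate design full rank
  cohort$metadata$age <- c(25, 32, 41, 28, 36, 47)
  cohort$metadata$gender <- c("M", "F", "M", "F", "M", "F")
  parc <- cohort$parcellation
  iso <- parc$index[parc$abbrev == "R10"] + 1L  # both hemispheres
  for (id in names(cohort$connectomes)) {
    sc <- cohort$connectomes[[id]]
    sc$fn[iso, ] <- 0L; sc$fn[, iso] <- 0L
    sc$fa[iso, ] <- 0;  sc$fa[, iso] <- 0
    cohort$connectomes[[id]] <- sc
  }
  # guarantee a fiber count of exactly 3 on an absent intra-L pair
  sc <- cohort$connectomes[[1]]
  li <- parc$index[parc$hemisphere == "L"] + 1L
  li <- setdiff(li, iso)
  cand <- which(sc$fn[li, li] == 0 & upper.tri(sc$fn[li, li]),
                arr.ind = TRUE)[1, ]
  i <- li[cand[1]]; j <- li[cand[2]]
  sc$fn[i, j] <- sc$fn[j, i] <- 3L
  sc$fa[i, j] <- sc$fa[j, i] <- 0.1
  cohort$connectomes[[1]] <- sc
  write_cohort(out_dir, cohort)
  invisible(cohort)
}
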