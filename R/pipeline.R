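#' Run the full two-scale analysis over sites and taxon groups
#'
#' End-to-end orchestration: for every taxon group, prepares the table
#' (percent cover is discretised to pseudo-individuals; counts tables are
#' optionally prevalence-filtered), then runs [run_site_taxon_analysis()] for
#' every site and collects the metric, effect and classification tables.
#' When `out_dir` is given, writes `metrics.csv`, `effects.csv`,
#' `classification.csv`, `filter_report.csv` and a JSON run manifest
#' (configuration echo, seeds, package version, timestamp). With fixed seeds
#' the outputs are byte-identical across reruns.
#'
#' @param tables named list of [community_table()] objects, one per taxon
#'   group (e.g. `list(plants = ..., fungi = ...)`).
#' @param filter `NULL` to skip prevalence filtering, or a list with
#'   `min_count` and `min_sample_fraction` applied to counts tables.
#' @param n_perm permutations for pooled-scale tests (default 199).
#' @param alpha_level significance threshold (default 0.05).
#' @param cap maximum standardized replicates per site.
#' @param seed master seed; per-(site, group) seeds derive from it.
#' @param out_dir optional output directory, created if needed.
#' @param skip_errors if `TRUE`, a failing site x taxon stratum is logged and
#'   skipped instead of aborting the run.
#' @return List with `metrics`, `effects`, `classification`,
#'   `filter_reports`, `errors` and `manifest`, invisibly written to
#'   `out_dir` when given.
#' @export
run_pipeline <- function(tables, filter = NULL, n_perm = 199,
                         alpha_level = 0.05, cap = 200, seed = 1,
                         out_dir = NULL, skip_errors = FALSE) {
  if (inherits(tables, "community_table")) tables <- list(all = tables)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list (one community_table per taxon group)")
  }
  if (!is.null(filter)) {
    stopifnot(is.list(filter), all(c("min_count", "min_sample_fraction") %in% names(filter)))
  }

  metrics <- list(); effects <- list(); classification <- list()
  filter_reports <- list(); errors <- list()

  set.seed(seed)
  for (grp in names(tables)) {
    tab <- tables[[grp]]
    stopifnot(inherits(tab, "community_table"))
    if (tab$abundance_kind == "percent_cover") {
      tab <- cover_to_counts(tab)
    } else if (!is.null(filter)) {
      tab <- filter_rare_otus(tab, filter$min_count, filter$min_sample_fraction)
      rep <- attr(tab, "filter_report")
      rep$taxon_group <- grp
      filter_reports[[grp]] <- rep
    }
    for (site in unique(tab$samples$site)) {
      site_seed <- sample.int(.Machine$integer.max, 1L)
      res <- tryCatch(
        run_site_taxon_analysis(tab, site, taxon_group = grp,
                                n_perm = n_perm, alpha_level = alpha_level,
                                cap = cap, seed = site_seed),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        if (!skip_errors) stop("stratum (", site, ", ", grp, ") failed: ",
                               conditionMessage(res))
        errors[[paste(site, grp, sep = "|")]] <- conditionMessage(res)
        next
      }
      metrics[[paste(site, grp)]] <- res$metrics
      effects[[paste(site, grp)]] <- res$effects
      classification[[paste(site, grp)]] <- res$classification
    }
  }

  rbind_all <- function(lst) {
    if (length(lst) == 0L) return(NULL)
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  bundle <- list(
    metrics = rbind_all(metrics),
    effects = rbind_all(effects),
    classification = rbind_all(classification),
    filter_reports = rbind_all(filter_reports),
    errors = errors,
    manifest = list(
      package_version = as.character(utils::packageVersion("scalediv")),
      seed = seed, n_perm = n_perm, alpha_level = alpha_level, cap = cap,
      filter = filter, taxon_groups = names(tables),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$effects, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$classification,
                     file.path(out_dir, "classification.csv"), row.names = FALSE)
    if (!is.null(bundle$filter_reports)) {
      utils::write.csv(bundle$filter_reports,
                       file.path(out_dir, "filter_report.csv"), row.names = FALSE)
    }
    manifest <- bundle$manifest
    manifest$timestamp <- NULL  # kept in the return value; excluded on disk so reruns are byte-identical
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

#' Tally scale-dependence categories
#'
#' Counts the classification categories over all site x taxon-group cases and
#' reports the fraction of qualitative reversals (significant, opposite-sign
#' responses at the two scales).
#'
#' @param classification classification table from [run_pipeline()] or
#'   [run_site_taxon_analysis()], or any data.frame with a `category` column.
#' @param metric optional metric name to restrict to (e.g. `"S_n"`).
#' @return List with `counts` (named integer vector over categories),
#'   `n_cases`, and `reversal_fraction` (0 for an empty table).
#' @export
summarize_quadrants <- function(classification, metric = NULL) {
  levels_all <- c("qualitative_reversal", "alpha_only", "gamma_only",
                  "consistent_both", "none", "undetermined")
  if (is.null(classification) || nrow(classification) == 0L) {
    counts <- stats::setNames(integer(length(levels_all)), levels_all)
    return(list(counts = counts, n_cases = 0L, reversal_fraction = 0))
  }
  if (!is.null(metric)) {
    classification <- classification[classification$metric %in% metric, , drop = FALSE]
  }
  cats <- factor(classification$category, levels = levels_all)
  counts <- table(cats)
  n <- nrow(classification)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n_cases = n,
       reversal_fraction = if (n > 0L)
         as.integer(counts[["qualitative_reversal"]]) / n else 0)
}
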