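#' Hierarchical community table
#'
#' A `community_table` bundles a subplot-by-species abundance matrix with the
#' sampling metadata of a nested grassland design: sites contain plots under
#' one of two management types (pasture or meadow), plots contain 1 m^2
#' subplots, and each subplot is one sample (row of the matrix). Abundances
#' are either discrete counts (e.g. OTU reads, or plant cover discretised via
#' [cover_to_counts()]) or raw percent cover.
#'
#' @param abundance numeric matrix, samples x taxa, non-negative. Row names
#'   (if present) must agree with `samples$sample_id`.
#' @param samples data.frame with columns `sample_id`, `site`, `plot`,
#'   `subplot`, `management` (`"pasture"` or `"meadow"`) and optionally
#'   `lui_category` (`"low"`, `"intermediate"`, `"high"` or `"none"`).
#' @param taxa character vector of taxon identifiers; defaults to the matrix
#'   column names.
#' @param abundance_kind `"counts"` or `"percent_cover"`. Counts matrices must
#'   contain integers only.
#'
#' @return An object of class `community_table`: a list with elements
#'   `abundance`, `samples`, `taxa`, `abundance_kind`.
#' @seealso [read_community_table()], [filter_rare_otus()], [pool_group()]
#' @export
community_table <- function(abundance, samples,
                            taxa = colnames(abundance),
                            abundance_kind = c("counts", "percent_cover")) {
  abundance_kind <- match.arg(abundance_kind)
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  required <- c("sample_id", "site", "plot", "subplot", "management")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"lui_category" %in% names(samples)) samples$lui_category <- "none"
  for (col in c(required, "lui_category")) samples[[col]] <- as.character(samples[[col]])

  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(abundance)))
  taxa <- as.character(taxa)

  if (nrow(abundance) != nrow(samples)) {
    stop("abundance has ", nrow(abundance), " rows but metadata describes ",
         nrow(samples), " samples")
  }
  if (ncol(abundance) != length(taxa)) {
    stop("abundance has ", ncol(abundance), " columns but ", length(taxa),
         " taxa were given")
  }
  if (anyNA(abundance)) stop("abundance matrix contains missing values")
  if (any(abundance < 0)) stop("abundance matrix contains negative values")
  if (abundance_kind == "counts" && any(abs(abundance - round(abundance)) > 1e-8)) {
    stop("counts table contains non-integer abundances")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  bad_mgmt <- setdiff(unique(samples$management), c("pasture", "meadow"))
  if (length(bad_mgmt) > 0L) {
    stop("management must be 'pasture' or 'meadow'; found: ",
         paste(bad_mgmt, collapse = ", "))
  }
  # subplot labels must not recur within a plot, nor plot labels within a site
  key <- paste(samples$site, samples$management, samples$plot, samples$subplot)
  if (anyDuplicated(key)) stop("duplicated (site, management, plot, subplot) combination")

  rownames(abundance) <- samples$sample_id
  colnames(abundance) <- taxa

  structure(
    list(abundance = abundance, samples = samples, taxa = taxa,
         abundance_kind = abundance_kind),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table: ", nrow(x$abundance), " samples x ", length(x$taxa),
      " taxa (", x$abundance_kind, ")\n", sep = "")
  cat("  sites: ", paste(unique(x$samples$site), collapse = ", "), "\n", sep = "")
  tab <- table(x$samples$site, x$samples$management)
  cat("  subplots per site x management:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$abundance)

#' Subset a community table by sample
#'
#' Keeps the selected samples (rows) and all taxa; metadata rows stay aligned.
#'
#' @param table a [community_table()].
#' @param keep logical or integer index into the samples.
#' @return A `community_table` with the selected samples.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "community_table"))
  community_table(table$abundance[keep, , drop = FALSE],
                  table$samples[keep, , drop = FALSE],
                  taxa = table$taxa, abundance_kind = table$abundance_kind)
}

#' Read a community table from delimited files
#'
#' Reads an abundance file in long format (columns `sample_id`, `taxon`,
#' `abundance`, one row per observed sample-taxon pair) or wide format (one
#' sample per row, first column `sample_id`, remaining columns taxa), plus a
#' metadata file keyed by `sample_id`. Field separator is sniffed from the
#' file extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' Pairs absent from a long file are zero. Taxa whose column is all zero are
#' retained but reported with a message. Samples without a metadata row are an
#' error; metadata rows without samples are dropped.
#'
#' @param path abundance file.
#' @param format `"long"` or `"wide"`.
#' @param meta_path metadata file with columns `sample_id`, `site`, `plot`,
#'   `subplot`, `management`, and optionally `lui_category`.
#' @param abundance_kind `"counts"` or `"percent_cover"`.
#' @return A [community_table()].
#' @export
read_community_table <- function(path, format = c("long", "wide"), meta_path,
                                 abundance_kind = c("counts", "percent_cover")) {
  format <- match.arg(format)
  abundance_kind <- match.arg(abundance_kind)
  ab <- read_delim_auto(path)
  meta <- read_delim_auto(meta_path)
  if (!"sample_id" %in% names(meta)) stop("metadata file lacks a sample_id column")

  if (format == "long") {
    need <- c("sample_id", "taxon", "abundance")
    missing_cols <- setdiff(need, names(ab))
    if (length(missing_cols) > 0L) {
      stop("long-format file lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    ab$abundance <- as.numeric(ab$abundance)
    if (anyNA(ab$abundance)) stop("non-numeric abundance values in ", path)
    if (any(ab$abundance < 0)) stop("negative abundance values in ", path)
    if (anyDuplicated(paste(ab$sample_id, ab$taxon))) {
      stop("duplicated (sample_id, taxon) pair in long-format file")
    }
    sample_ids <- unique(as.character(ab$sample_id))
    taxa <- sort(unique(as.character(ab$taxon)))
    mat <- matrix(0, nrow = length(sample_ids), ncol = length(taxa),
                  dimnames = list(sample_ids, taxa))
    mat[cbind(match(ab$sample_id, sample_ids), match(ab$taxon, taxa))] <- ab$abundance
  } else {
    if (names(ab)[1L] != "sample_id") stop("wide-format file must start with a sample_id column")
    sample_ids <- as.character(ab$sample_id)
    mat <- as.matrix(ab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    if (anyNA(mat)) stop("non-numeric or missing abundance values in ", path)
    if (any(mat < 0)) stop("negative abundance values in ", path)
    rownames(mat) <- sample_ids
    taxa <- colnames(mat)
  }

  unmatched <- setdiff(sample_ids, as.character(meta$sample_id))
  if (length(unmatched) > 0L) {
    stop("samples without metadata: ", paste(unmatched, collapse = ", "))
  }
  meta <- meta[match(sample_ids, as.character(meta$sample_id)), , drop = FALSE]

  empty <- colnames(mat)[colSums(mat) == 0]
  if (length(empty) > 0L) {
    message("retaining ", length(empty), " all-zero taxon column(s): ",
            paste(utils::head(empty, 5L), collapse = ", "),
            if (length(empty) > 5L) ", ..." else "")
  }
  community_table(mat, meta, taxa = taxa, abundance_kind = abundance_kind)
}

#' Write a community table to delimited files
#'
#' Inverse of [read_community_table()]: writes the abundance matrix in long or
#' wide format plus the sample metadata, so a table round-trips exactly.
#'
#' @param table a [community_table()].
#' @param path abundance file to write.
#' @param meta_path metadata file to write.
#' @param format `"long"` (zero cells omitted) or `"wide"`.
#' @return Invisibly, `table`.
#' @export
write_community_table <- function(table, path, meta_path, format = c("long", "wide")) {
  stopifnot(inherits(table, "community_table"))
  format <- match.arg(format)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  if (format == "long") {
    idx <- which(table$abundance != 0, arr.ind = TRUE)
    long <- data.frame(
      sample_id = rownames(table$abundance)[idx[, 1L]],
      taxon = colnames(table$abundance)[idx[, 2L]],
      abundance = table$abundance[idx],
      stringsAsFactors = FALSE
    )
    long <- long[order(match(long$sample_id, rownames(table$abundance)), long$taxon), ]
    utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    wide <- data.frame(sample_id = rownames(table$abundance), table$abundance,
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(wide, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  meta_sep <- if (grepl("\\.(tsv|txt)$", meta_path)) "\t" else ","
  utils::write.table(table$samples, meta_path, sep = meta_sep, row.names = FALSE, quote = FALSE)
  invisible(table)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Remove rare OTUs by prevalence at a count threshold
#'
#' Keeps a taxon if it occurs more than `min_count` times (strict inequality)
#' in at least a fraction `min_sample_fraction` of the samples; the sample
#' threshold is `ceiling(min_sample_fraction * n_samples)` so it is never
#' zero. The defaults reproduce the common read-count artifact filter for OTU
#' tables: more than 5 reads in at least 1% of samples.
#'
#' @param table a [community_table()] with `abundance_kind = "counts"`.
#' @param min_count integer read threshold (kept occurrences must exceed it).
#' @param min_sample_fraction fraction of samples in (0, 1].
#' @return The filtered `community_table`; the sample set is unchanged. A
#'   data.frame with one row per input taxon (`taxon`, `prevalence`, `kept`)
#'   is attached as attribute `"filter_report"`.
#' @export
filter_rare_otus <- function(table, min_count = 5, min_sample_fraction = 0.01) {
  stopifnot(inherits(table, "community_table"))
  if (table$abundance_kind != "counts") {
    stop("prevalence filtering applies to counts tables; run cover_to_counts() first")
  }
  if (min_count < 0) stop("min_count must be >= 0")
  if (min_sample_fraction <= 0 || min_sample_fraction > 1) {
    stop("min_sample_fraction must be in (0, 1]")
  }
  n_samples <- nrow(table$abundance)
  needed <- ceiling(min_sample_fraction * n_samples)
  prevalence <- colSums(table$abundance > min_count)
  kept <- prevalence >= needed
  report <- data.frame(taxon = table$taxa, prevalence = as.integer(prevalence),
                       kept = as.logical(kept), stringsAsFactors = FALSE)
  out <- community_table(table$abundance[, kept, drop = FALSE], table$samples,
                         taxa = table$taxa[kept], abundance_kind = "counts")
  attr(out, "filter_report") <- report
  out
}

#' Discretise percent cover to pseudo-individual counts
#'
#' Rarefaction and encounter probabilities require discrete individuals, while
#' plant abundance is recorded as percent cover. Each cell is rounded to the
#' nearest integer, except that any positive cover rounding to zero becomes 1
#' so presence is never lost; zero stays zero.
#'
#' @param table a [community_table()] with `abundance_kind = "percent_cover"`.
#' @return A counts `community_table` of the same shape.
#' @export
cover_to_counts <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (table$abundance_kind != "percent_cover") {
    stop("cover_to_counts() expects a percent_cover table")
  }
  counts <- round(table$abundance)
  counts[table$abundance > 0 & counts < 1] <- 1
  community_table(counts, table$samples, taxa = table$taxa, abundance_kind = "counts")
}

#' Pool a site-management group to one abundance vector
#'
#' Sums abundances over every subplot of a (site, management) stratum — the
#' gamma-scale community.
#'
#' @param table a [community_table()].
#' @param site site label.
#' @param management `"pasture"` or `"meadow"`.
#' @return Named numeric vector over taxa.
#' @export
pool_group <- function(table, site, management) {
  stopifnot(inherits(table, "community_table"))
  sel <- table$samples$site == site & table$samples$management == management
  if (!any(sel)) {
    stop("no samples for site '", site, "', management '", management, "'")
  }
  colSums(table$abundance[sel, , drop = FALSE])
}
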