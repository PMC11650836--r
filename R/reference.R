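# Cohort exon-level reference: log2 call thresholds, copy-number translation,
# per-exon frequency and boxplot statistics.

CALL_LEVELS <- c("homozygous_deletion", "heterozygous_deletion", "normal", "duplication")

REFERENCE_COLUMNS <- c(
  "gene", "chromosome", "exon_index", "n_samples",
  "het_del_freq", "hom_del_freq", "dup_freq",
  "mean_log2", "median_log2", "sd_log2", "q1_log2", "q3_log2", "min_log2", "max_log2",
  "mean_depth", "median_depth", "sd_depth", "q1_depth", "q3_depth", "min_depth", "max_depth"
)

#' Log2-ratio call thresholds
#'
#' The log2 coverage-ratio cutoffs that translate a bin's ratio into a call:
#' duplication above 0.3, heterozygous deletion at or below -0.4, homozygous
#' deletion below -1.1. `grid_highlight_log2` (-0.65) is the level below
#' which a bin is flagged for visual highlighting in filtered data grids.
#'
#' @param dup_log2 Duplication cutoff (call is duplication when
#'   `log2 > dup_log2`). Default 0.3.
#' @param het_del_log2 Heterozygous-deletion cutoff. Default -0.4.
#' @param hom_del_log2 Homozygous-deletion cutoff. Default -1.1.
#' @param grid_highlight_log2 Highlight level for data grids. Default -0.65.
#' @return An object of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(dup_log2 = 0.3, het_del_log2 = -0.4,
                           hom_del_log2 = -1.1, grid_highlight_log2 = -0.65) {
  vals <- c(dup_log2, het_del_log2, hom_del_log2, grid_highlight_log2)
  if (!all(is.finite(vals))) stop_value("thresholds must be finite")
  if (!(hom_del_log2 < het_del_log2 && het_del_log2 < dup_log2)) {
    stop_value("thresholds must satisfy hom_del_log2 < het_del_log2 < dup_log2")
  }
  structure(
    list(dup_log2 = dup_log2, het_del_log2 = het_del_log2,
         hom_del_log2 = hom_del_log2, grid_highlight_log2 = grid_highlight_log2),
    class = "cnv_thresholds"
  )
}

#' @export
print.cnv_thresholds <- function(x, ...) {
  cat(sprintf(
    "<cnv_thresholds> dup > %g | het del [%g, %g] | hom del < %g | highlight < %g\n",
    x$dup_log2, x$hom_del_log2, x$het_del_log2, x$hom_del_log2, x$grid_highlight_log2))
  invisible(x)
}

#' Classify a log2 coverage ratio into a copy-number call
#'
#' Partitions the real line into four exclusive, exhaustive call categories:
#' homozygous deletion for `log2 < hom_del_log2`, heterozygous deletion for
#' `hom_del_log2 <= log2 <= het_del_log2`, duplication for
#' `log2 > dup_log2`, normal otherwise. The heterozygous-deletion interval
#' is closed at its upper edge, so a ratio exactly at the deletion cutoff is
#' still called a deletion; the duplication cutoff itself is normal.
#'
#' @param log2 Numeric vector of log2 coverage ratios (finite).
#' @param thresholds A [cnv_thresholds()] object.
#' @return Factor with levels `homozygous_deletion`, `heterozygous_deletion`,
#'   `normal`, `duplication`, in increasing log2 order.
#' @export
classify_log2 <- function(log2, thresholds = cnv_thresholds()) {
  if (length(log2) && any(!is.finite(log2))) {
    stop_value("log2 values must be finite")
  }
  out <- rep("normal", length(log2))
  out[log2 < thresholds$hom_del_log2] <- "homozygous_deletion"
  out[log2 >= thresholds$hom_del_log2 & log2 <= thresholds$het_del_log2] <-
    "heterozygous_deletion"
  out[log2 > thresholds$dup_log2] <- "duplication"
  factor(out, levels = CALL_LEVELS)
}

#' Translate a log2 ratio into an integer copy number
#'
#' The diploid-anchored closed form `round(2 * 2^log2)` with half-up
#' rounding, floored at zero: a ratio of 0 is two copies, -1 is one copy,
#' +0.585 is three copies.
#'
#' @param log2 Numeric vector of finite log2 ratios.
#' @return Non-negative integer vector of copy numbers.
#' @export
log2_to_cn <- function(log2) {
  if (length(log2) && any(!is.finite(log2))) {
    stop_value("log2 values must be finite")
  }
  as.integer(pmax(0, floor(2 * 2^log2 + 0.5)))
}

#' Build the cohort exon-level reference
#'
#' Concatenates exon-indexed cnr tables across a cohort and summarizes every
#' (gene, chromosome, exon) key observed in at least one sample: the
#' fraction of samples whose log2 ratio classifies as heterozygous deletion,
#' homozygous deletion or duplication (exclusive categories over the same
#' denominator), plus the boxplot statistics of log2 and depth — mean,
#' median, standard deviation (n-1 denominator; 0 for a single sample),
#' first and third quartile (linear interpolation between order statistics)
#' and the observed minimum and maximum. The denominator `n_samples` for an
#' exon is the number of cohort samples in which that exon is present.
#'
#' @param cohort Named list of cnr tibbles (one per sample), as returned by
#'   [read_cnr()]; exon indices are assigned internally when absent.
#' @param thresholds A [cnv_thresholds()] object used to classify each
#'   sample's log2 at each exon.
#' @return A tibble with one row per exon and the columns listed for the
#'   reference TSV serialization (see [write_reference()]).
#' @export
build_reference <- function(cohort, thresholds = cnv_thresholds()) {
  if (length(cohort) == 0) stop_content("cohort is empty")
  if (is.null(names(cohort)) || any(!nzchar(names(cohort)))) {
    names(cohort) <- sprintf("sample_%03d", seq_along(cohort))
  }
  indexed <- purrr::map(cohort, function(bins) {
    if (!"exon_index" %in% names(bins)) bins <- assign_exon_indices(bins)
    bins
  })
  all_bins <- dplyr::bind_rows(indexed, .id = "sample_id")
  if (nrow(all_bins) == 0) stop_content("cohort contains no usable bins")
  all_bins$call <- classify_log2(all_bins$log2, thresholds)

  q <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
  stats_tbl <- all_bins |>
    dplyr::group_by(.data$gene, .data$chromosome, .data$exon_index) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      het_del_freq = mean(.data$call == "heterozygous_deletion"),
      hom_del_freq = mean(.data$call == "homozygous_deletion"),
      dup_freq = mean(.data$call == "duplication"),
      mean_log2 = mean(.data$log2),
      median_log2 = stats::median(.data$log2),
      sd_log2 = if (dplyr::n() > 1) stats::sd(.data$log2) else 0,
      q1_log2 = q(.data$log2, 0.25),
      q3_log2 = q(.data$log2, 0.75),
      min_log2 = min(.data$log2),
      max_log2 = max(.data$log2),
      mean_depth = mean(.data$depth),
      median_depth = stats::median(.data$depth),
      sd_depth = if (dplyr::n() > 1) stats::sd(.data$depth) else 0,
      q1_depth = q(.data$depth, 0.25),
      q3_depth = q(.data$depth, 0.75),
      min_depth = min(.data$depth),
      max_depth = max(.data$depth),
      .groups = "drop"
    )
  key <- chromosome_sort_key(stats_tbl$chromosome)
  stats_tbl <- stats_tbl[order(key$rank, key$label, stats_tbl$gene, stats_tbl$exon_index), ]
  stats_tbl[, REFERENCE_COLUMNS]
}

#' Look up one exon in the reference
#'
#' Exact-key lookup on (gene, chromosome, exon index). Gene matching is
#' case-insensitive; chromosome matching ignores a "chr" prefix.
#'
#' @param reference Reference tibble from [build_reference()] or
#'   [read_reference()].
#' @param gene Gene symbol.
#' @param chromosome Chromosome label.
#' @param exon_index 1-based exon ordinal.
#' @return The one-row reference tibble for that exon, or `NULL` when absent.
#' @export
lookup_exon <- function(reference, gene, chromosome, exon_index) {
  hit <- toupper(reference$gene) == toupper(gene) &
    same_chromosome(reference$chromosome, chromosome) &
    reference$exon_index == exon_index
  if (!any(hit)) return(NULL)
  reference[which(hit)[1], , drop = FALSE]
}

#' Write a reference TSV
#'
#' One row per exon, fixed column order: `gene`, `chromosome`,
#' `exon_index`, `n_samples`, the three frequencies, then the seven log2
#' statistics and the seven depth statistics. Floats at 6 decimal places.
#'
#' @param reference Reference tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference <- function(reference, path) {
  header <- paste(REFERENCE_COLUMNS, collapse = "\t")
  if (nrow(reference) == 0) return(write_lines_atomic(header, path))
  fields <- list(
    reference$gene,
    reference$chromosome,
    format_tsv_integer(reference$exon_index),
    format_tsv_integer(reference$n_samples)
  )
  for (col in REFERENCE_COLUMNS[-(1:4)]) {
    fields <- c(fields, list(format_tsv_number(reference[[col]])))
  }
  rows <- do.call(paste, c(fields, sep = "\t"))
  write_lines_atomic(c(header, rows), path)
}

#' Read a reference TSV written by [write_reference()]
#'
#' @param path Path to the reference TSV.
#' @return Reference tibble.
#' @export
read_reference <- function(path) {
  raw <- read_tsv_character(path)
  missing <- setdiff(REFERENCE_COLUMNS, names(raw))
  if (length(missing)) {
    stop_schema("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(
    gene = as.character(raw$gene),
    chromosome = as.character(raw$chromosome),
    exon_index = as.integer(parse_numeric_column(raw$exon_index, "exon_index")),
    n_samples = as.integer(parse_numeric_column(raw$n_samples, "n_samples"))
  )
  for (col in REFERENCE_COLUMNS[-(1:4)]) {
    out[[col]] <- parse_numeric_column(raw[[col]], col)
  }
  out
}
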