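# Preset and custom CNV filtering of annotated bins: in-house frequency
# annotation, consecutive-exon run detection, and the bin-wise z-test with
# Benjamini-Hochberg correction.

PRESETS <- c("total", "bintest", "homozygous_deletion", "total_candidate",
             "bintest_candidate", "consecutive_del", "consecutive_amp")

#' Filter configuration
#'
#' Bundles one preset plus the optional custom filters applied after it.
#' All custom filters are conjunctive; unset filters are no-ops.
#'
#' @param preset One of `"total"` (unfiltered cnr grid), `"bintest"`
#'   (unfiltered bintest grid), `"homozygous_deletion"`,
#'   `"total_candidate"` / `"bintest_candidate"` (panel-restricted),
#'   `"consecutive_del"` / `"consecutive_amp"` (consecutive-exon runs).
#' @param region Optional region string, a chromosome label or
#'   `"chrom:start-end"` in 1-based inclusive coordinates.
#' @param genes Optional character vector of gene symbols
#'   (case-insensitive membership).
#' @param min_depth Optional minimal raw read depth.
#' @param copy_numbers Optional set of integer copy numbers to keep.
#' @param min_abs_log2 Optional minimal absolute log2 ratio.
#' @param max_inhouse_freq Optional maximal in-house frequency in \[0, 1\];
#'   a bin passes when the largest of its non-missing cohort frequencies is
#'   at or below this value (bins with no reference entry always pass).
#' @param consecutive_cutoff Minimal run length for the consecutive presets
#'   (default 2).
#' @return An object of class `cnv_filter_config`.
#' @export
filter_config <- function(preset = "total", region = NULL, genes = NULL,
                          min_depth = NULL, copy_numbers = NULL,
                          min_abs_log2 = NULL, max_inhouse_freq = NULL,
                          consecutive_cutoff = 2L) {
  preset <- match.arg(preset, PRESETS)
  if (!is.null(region)) parse_region(region)
  if (!is.null(max_inhouse_freq) &&
      (max_inhouse_freq < 0 || max_inhouse_freq > 1)) {
    stop_config("max_inhouse_freq must be in [0, 1]")
  }
  consecutive_cutoff <- as.integer(consecutive_cutoff)
  if (is.na(consecutive_cutoff) || consecutive_cutoff < 1) {
    stop_config("consecutive_cutoff must be a positive integer")
  }
  structure(
    list(preset = preset, region = region, genes = genes,
         min_depth = min_depth, copy_numbers = copy_numbers,
         min_abs_log2 = min_abs_log2, max_inhouse_freq = max_inhouse_freq,
         consecutive_cutoff = consecutive_cutoff),
    class = "cnv_filter_config"
  )
}

#' Annotate exon-indexed bins with calls and cohort frequencies
#'
#' Every data grid in the toolkit carries, per bin: the call category from
#' [classify_log2()], the integer copy number from [log2_to_cn()], the
#' cohort in-house frequencies from the exon reference (`NA` when the exon
#' is absent from the reference) and a `highlight` flag for log2 ratios
#' below the grid highlight level.
#'
#' @param bins Exon-indexed bins from [assign_exon_indices()] (exon indices
#'   are assigned internally when absent).
#' @param reference Optional reference tibble; without it the frequency
#'   columns are all `NA`.
#' @param thresholds A [cnv_thresholds()] object.
#' @return The bins with added columns `call`, `cn`, `het_del_freq`,
#'   `hom_del_freq`, `dup_freq`, `highlight`.
#' @export
annotate_bins <- function(bins, reference = NULL, thresholds = cnv_thresholds()) {
  if (!"exon_index" %in% names(bins)) bins <- assign_exon_indices(bins)
  bins$call <- classify_log2(bins$log2, thresholds)
  bins$cn <- log2_to_cn(bins$log2)
  if (is.null(reference) || nrow(reference) == 0) {
    bins$het_del_freq <- NA_real_
    bins$hom_del_freq <- NA_real_
    bins$dup_freq <- NA_real_
  } else {
    freqs <- reference[, c("gene", "chromosome", "exon_index",
                           "het_del_freq", "hom_del_freq", "dup_freq")]
    bins <- dplyr::left_join(bins, freqs,
                             by = c("gene", "chromosome", "exon_index"))
  }
  bins$highlight <- bins$log2 < thresholds$grid_highlight_log2
  bins
}

#' Apply the custom filter panel to annotated bins
#'
#' Conjunction of every set filter in `config`: region overlap (half-open
#' interval intersection after converting the 1-based inclusive region
#' string), case-insensitive gene membership, minimal depth, copy-number
#' membership, minimal absolute log2, and the in-house frequency ceiling
#' (maximum over the non-missing cohort frequencies; bins without any
#' reference frequency pass). Row order is preserved.
#'
#' @param bins Annotated bins from [annotate_bins()].
#' @param config A [filter_config()] object.
#' @return The surviving bins, in input order.
#' @export
apply_custom_filters <- function(bins, config) {
  stopifnot(inherits(config, "cnv_filter_config"))
  keep <- rep(TRUE, nrow(bins))
  if (!is.null(config$region)) {
    reg <- parse_region(config$region)
    on_chrom <- same_chromosome(bins$chromosome, reg$chromosome)
    if (is.na(reg$start)) {
      keep <- keep & on_chrom
    } else {
      # 1-based inclusive display region -> 0-based half-open [start-1, end)
      r0 <- reg$start - 1L
      r1 <- reg$end
      keep <- keep & on_chrom & bins$start < r1 & bins$end > r0
    }
  }
  if (!is.null(config$genes)) {
    keep <- keep & toupper(bins$gene) %in% toupper(config$genes)
  }
  if (!is.null(config$min_depth)) {
    keep <- keep & bins$depth >= config$min_depth
  }
  if (!is.null(config$copy_numbers)) {
    keep <- keep & bins$cn %in% as.integer(config$copy_numbers)
  }
  if (!is.null(config$min_abs_log2)) {
    keep <- keep & abs(bins$log2) >= config$min_abs_log2
  }
  if (!is.null(config$max_inhouse_freq)) {
    fmax <- pmax(bins$het_del_freq, bins$hom_del_freq, bins$dup_freq, na.rm = TRUE)
    all_missing <- is.na(bins$het_del_freq) & is.na(bins$hom_del_freq) &
      is.na(bins$dup_freq)
    keep <- keep & (all_missing | fmax <= config$max_inhouse_freq)
  }
  bins[keep, , drop = FALSE]
}

#' Find runs of consecutively deleted or amplified exons
#'
#' Within each (gene, chromosome) group, finds maximal runs of bins with
#' strictly consecutive exon indices that all satisfy the direction
#' predicate — deletion: `log2 <= het_del_log2`, matching the
#' heterozygous-deletion call boundary of [classify_log2()]; amplification:
#' `log2 > dup_log2` — and discards runs shorter than `min_run`. Runs never
#' span genes or chromosomes.
#'
#' @param bins Exon-indexed bins (annotated or plain).
#' @param direction `"deletion"` or `"amplification"`.
#' @param min_run Minimal run length (default 2).
#' @param thresholds A [cnv_thresholds()] object.
#' @return Tibble of the bins belonging to qualifying runs, with added
#'   columns `run_id` and `run_length`.
#' @export
find_consecutive_runs <- function(bins, direction = c("deletion", "amplification"),
                                  min_run = 2L, thresholds = cnv_thresholds()) {
  direction <- match.arg(direction)
  min_run <- as.integer(min_run)
  if (is.na(min_run) || min_run < 1) stop_config("min_run must be >= 1")
  if (!"exon_index" %in% names(bins)) bins <- assign_exon_indices(bins)

  qualifies <- if (direction == "deletion") {
    bins$log2 <= thresholds$het_del_log2
  } else {
    bins$log2 > thresholds$dup_log2
  }
  cand <- bins[qualifies, , drop = FALSE]
  empty <- bins[0, , drop = FALSE]
  empty$run_id <- character()
  empty$run_length <- integer()
  if (nrow(cand) == 0) return(empty)

  cand <- cand[order(cand$gene, cand$chromosome, cand$exon_index), , drop = FALSE]
  new_group <- c(TRUE, cand$gene[-1] != cand$gene[-nrow(cand)] |
                   cand$chromosome[-1] != cand$chromosome[-nrow(cand)] |
                   diff(cand$exon_index) != 1L)
  run_idx <- cumsum(new_group)
  run_len <- as.integer(stats::ave(run_idx, run_idx, FUN = length))
  keep <- run_len >= min_run
  out <- cand[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  ridx <- run_idx[keep]
  out$run_id <- sprintf("%s:%s:run%d", out$gene, out$chromosome,
                        match(ridx, unique(ridx)))
  out$run_length <- run_len[keep]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The standard step-up false-discovery-rate procedure: p-values are sorted
#' ascending, the i-th smallest is scaled by m/i, monotonicity is enforced
#' from the largest rank downward by a running minimum, values are capped
#' at 1, and the result is returned in the original input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_value("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- q
  adjusted
}

#' Recompute the bin-wise z-test against the cohort reference
#'
#' Re-derivation of the single-bin CNV test: for each bin with a reference
#' entry whose log2 standard deviation is positive, the z-score
#' `(log2 - mean_log2_ref) / sd_log2_ref` is converted to a two-sided
#' normal p-value, the p-values are Benjamini-Hochberg adjusted across all
#' tested bins, and a bin is significant when its adjusted p-value is at or
#' below `alpha`. Bins that cannot be tested (no reference entry, or zero
#' reference spread) are dropped with their count recorded in attribute
#' `n_skipped`.
#'
#' @param bins Annotated, exon-indexed bins.
#' @param reference Reference tibble from [build_reference()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return The testable bins with added columns `z`, `p_value`,
#'   `p_adjusted`, `significant`; attribute `n_skipped` counts untestable
#'   bins.
#' @export
recompute_bintest <- function(bins, reference, alpha = 0.05) {
  if (!"exon_index" %in% names(bins)) bins <- assign_exon_indices(bins)
  ref <- reference[, c("gene", "chromosome", "exon_index", "mean_log2", "sd_log2")]
  names(ref)[4:5] <- c(".ref_mean_log2", ".ref_sd_log2")
  joined <- dplyr::left_join(bins, ref, by = c("gene", "chromosome", "exon_index"))
  testable <- !is.na(joined$.ref_mean_log2) & !is.na(joined$.ref_sd_log2) &
    joined$.ref_sd_log2 > 0
  n_skipped <- sum(!testable)
  out <- joined[testable, , drop = FALSE]
  if (nrow(out) == 0) stop_content("no bins are testable against this reference")
  out$z <- (out$log2 - out$.ref_mean_log2) / out$.ref_sd_log2
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- out$p_adjusted <= alpha
  out$.ref_mean_log2 <- NULL
  out$.ref_sd_log2 <- NULL
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Apply a filter preset, then the custom filter panel
#'
#' Dispatches on `config$preset`: `total` and `bintest` are identities on
#' the cnr and bintest grids respectively; `homozygous_deletion` keeps cnr
#' bins called as homozygous deletion; the `*_candidate` presets restrict
#' the respective grid to the genes of a panel; `consecutive_del` /
#' `consecutive_amp` return consecutive-exon runs from the cnr grid with
#' minimal length `config$consecutive_cutoff`. The custom filters of
#' `config` are applied to the preset's output.
#'
#' @param bins_cnr Annotated cnr bins.
#' @param bins_bintest Annotated bintest bins (required for the bintest
#'   presets).
#' @param config A [filter_config()] object.
#' @param panel A `cnv_panel` (required for the candidate presets).
#' @param thresholds A [cnv_thresholds()] object.
#' @return The filtered grid (with `run_id`/`run_length` columns for the
#'   consecutive presets).
#' @export
apply_preset <- function(bins_cnr, bins_bintest = NULL, config = filter_config(),
                         panel = NULL, thresholds = cnv_thresholds()) {
  stopifnot(inherits(config, "cnv_filter_config"))
  preset <- config$preset
  needs_panel <- preset %in% c("total_candidate", "bintest_candidate")
  if (needs_panel && is.null(panel)) {
    stop_config("preset '%s' requires a gene panel", preset)
  }
  needs_bintest <- preset %in% c("bintest", "bintest_candidate")
  if (needs_bintest && is.null(bins_bintest)) {
    stop_config("preset '%s' requires a bintest table", preset)
  }
  out <- switch(
    preset,
    total = bins_cnr,
    bintest = bins_bintest,
    homozygous_deletion = bins_cnr[bins_cnr$call == "homozygous_deletion", , drop = FALSE],
    total_candidate = bins_cnr[toupper(bins_cnr$gene) %in% panel$genes, , drop = FALSE],
    bintest_candidate = bins_bintest[toupper(bins_bintest$gene) %in% panel$genes, , drop = FALSE],
    consecutive_del = find_consecutive_runs(bins_cnr, "deletion",
                                            config$consecutive_cutoff, thresholds),
    consecutive_amp = find_consecutive_runs(bins_cnr, "amplification",
                                            config$consecutive_cutoff, thresholds)
  )
  apply_custom_filters(out, config)
}

#' Write a filtered data grid as TSV
#'
#' Emits the annotated-bin columns (plus `run_id`/`run_length` when
#' present) with floats at 6 decimal places and missing cells empty.
#'
#' @param grid Filtered bins from [apply_preset()] or friends.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_grid <- function(grid, path) {
  cols <- names(grid)
  header <- paste(cols, collapse = "\t")
  if (nrow(grid) == 0) return(write_lines_atomic(header, path))
  fields <- lapply(cols, function(col) {
    x <- grid[[col]]
    if (is.factor(x)) as.character(x)
    else if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    else if (is.integer(x)) format_tsv_integer(x)
    else if (is.numeric(x)) format_tsv_number(x)
    else ifelse(is.na(x), "", as.character(x))
  })
  rows <- do.call(paste, c(fields, sep = "\t"))
  write_lines_atomic(c(header, rows), path)
}
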