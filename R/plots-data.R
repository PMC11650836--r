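# Plot-ready series: MLPA-like per-exon boxplots, genome/chromosome log2
# scatter with segment overlay, B-allele-frequency series, a windowed LOH
# flag, and IGV locus links.

#' Per-exon boxplot series for one gene
#'
#' The MLPA-like view: for every reference exon of a gene, the cohort box
#' (first quartile, median, third quartile, mean) with whiskers at the
#' observed minimum and maximum, for both the log2 ratio and the raw depth,
#' overlaid with the analyzed sample's own values and their call. Sample
#' values are `NA` where the sample lacks the exon.
#'
#' @param gene Gene symbol (case-insensitive).
#' @param reference Reference tibble from [build_reference()].
#' @param sample_bins Exon-indexed bins of the analyzed sample.
#' @param thresholds A [cnv_thresholds()] object; its three call cutoffs
#'   are attached for threshold lines.
#' @return Tibble with one row per reference exon in exon order: the box
#'   statistics per metric, `sample_log2`, `sample_depth`, `sample_call`;
#'   attributes `gene` and `thresholds`.
#' @export
boxplot_series <- function(gene, reference, sample_bins,
                           thresholds = cnv_thresholds()) {
  hit <- toupper(reference$gene) == toupper(gene)
  if (!any(hit)) {
    near <- unique(reference$gene[startsWith(toupper(reference$gene), toupper(gene))])
    stop_lookup("gene '%s' not in reference%s", gene,
                if (length(near)) paste0("; near matches: ", paste(near, collapse = ", "))
                else "")
  }
  ref <- reference[hit, , drop = FALSE]
  ref <- ref[order(ref$exon_index), , drop = FALSE]
  if (!"exon_index" %in% names(sample_bins)) {
    sample_bins <- assign_exon_indices(sample_bins)
  }
  smp <- sample_bins[toupper(sample_bins$gene) == toupper(gene) &
                       same_chromosome(sample_bins$chromosome, ref$chromosome[1]), ,
                     drop = FALSE]
  idx <- match(ref$exon_index, smp$exon_index)
  out <- tibble::tibble(
    exon_index = ref$exon_index,
    log2_q1 = ref$q1_log2, log2_median = ref$median_log2, log2_q3 = ref$q3_log2,
    log2_mean = ref$mean_log2,
    log2_whisker_low = ref$min_log2, log2_whisker_high = ref$max_log2,
    depth_q1 = ref$q1_depth, depth_median = ref$median_depth, depth_q3 = ref$q3_depth,
    depth_mean = ref$mean_depth,
    depth_whisker_low = ref$min_depth, depth_whisker_high = ref$max_depth,
    sample_log2 = smp$log2[idx],
    sample_depth = smp$depth[idx]
  )
  out$sample_call <- factor(rep(NA_character_, nrow(out)), levels = CALL_LEVELS)
  ok <- is.finite(out$sample_log2)
  if (any(ok)) out$sample_call[ok] <- classify_log2(out$sample_log2[ok], thresholds)
  attr(out, "gene") <- ref$gene[1]
  attr(out, "thresholds") <- thresholds
  out
}

#' Genome- or chromosome-wide log2 scatter series
#'
#' Turns every cnr bin in the requested region into a scatter point at the
#' bin midpoint, flagged when the midpoint lies inside a called segment
#' with a non-normal copy-number call (classification of the segment log2).
#' The genome view concatenates chromosomes in natural order with
#' cumulative coordinate offsets in `position_genome`.
#'
#' @param cnr_bins Bins from [read_cnr()] (antitarget bins are kept).
#' @param cns_segments Optional segments from [read_cns()].
#' @param region `"genome"` or a chromosome label present in the bins.
#' @param thresholds A [cnv_thresholds()] object for the segment call.
#' @return List with `points` (tibble: `chromosome`, `position_mid`,
#'   `position_genome`, `log2`, `in_called_segment`) and `segments`
#'   (tibble with `aberrant` flag and genome offsets; empty when no
#'   segments given).
#' @export
scatter_series <- function(cnr_bins, cns_segments = NULL, region = "genome",
                           thresholds = cnv_thresholds()) {
  bins <- cnr_bins
  segs <- cns_segments
  if (!identical(region, "genome")) {
    on_chrom <- same_chromosome(bins$chromosome, region)
    if (!any(on_chrom)) stop_lookup("chromosome '%s' not present in the bins", region)
    bins <- bins[on_chrom, , drop = FALSE]
    if (!is.null(segs)) {
      segs <- segs[same_chromosome(segs$chromosome, region), , drop = FALSE]
    }
  }
  key <- chromosome_sort_key(bins$chromosome)
  bins <- bins[order(key$rank, key$label, bins$start), , drop = FALSE]
  # cumulative offsets per chromosome (genome view); a single chromosome
  # gets offset 0
  chroms <- unique(bins$chromosome)
  spans <- vapply(chroms, function(ch) max(bins$end[bins$chromosome == ch]),
                  numeric(1))
  offsets <- stats::setNames(c(0, cumsum(as.numeric(spans))[-length(spans)]), chroms)
  mid <- floor((bins$start + bins$end) / 2)
  points <- tibble::tibble(
    chromosome = bins$chromosome,
    position_mid = as.integer(mid),
    position_genome = as.numeric(mid) + offsets[bins$chromosome],
    log2 = bins$log2
  )
  if (is.null(segs) || nrow(segs) == 0) {
    points$in_called_segment <- FALSE
    seg_out <- tibble::tibble(chromosome = character(), start = integer(),
                              end = integer(), log2 = numeric(),
                              aberrant = logical())
  } else {
    seg_call <- classify_log2(segs$log2, thresholds)
    seg_out <- tibble::tibble(
      chromosome = segs$chromosome, start = segs$start, end = segs$end,
      log2 = segs$log2, aberrant = seg_call != "normal"
    )
    ab <- seg_out[seg_out$aberrant, , drop = FALSE]
    flagged <- rep(FALSE, nrow(points))
    if (nrow(ab) > 0) {
      for (i in seq_len(nrow(ab))) {
        hit <- same_chromosome(points$chromosome, ab$chromosome[i]) &
          points$position_mid >= ab$start[i] & points$position_mid < ab$end[i]
        flagged <- flagged | hit
      }
    }
    points$in_called_segment <- flagged
  }
  list(points = points, segments = seg_out)
}

#' B-allele-frequency series from SNV observations
#'
#' The allelic balance of each SNV: `alt_depth / (ref_depth + alt_depth)`,
#' which is 0 for homozygous reference, about 0.5 for heterozygous, and 1
#' for homozygous alternative sites. Observations with zero total depth are
#' skipped and counted in attribute `n_skipped`.
#'
#' @param snvs Observations from [read_snvs()].
#' @param region Optional chromosome label or `"chrom:start-end"`
#'   (1-based inclusive).
#' @return Tibble with `chromosome`, `position`, `frequency`, sorted by
#'   chromosome (natural order) and position.
#' @export
baf_series <- function(snvs, region = NULL) {
  obs <- snvs
  if (!is.null(region)) {
    reg <- parse_region(region)
    sel <- same_chromosome(obs$chromosome, reg$chromosome)
    if (!is.na(reg$start)) {
      sel <- sel & obs$position >= reg$start & obs$position <= reg$end
    }
    obs <- obs[sel, , drop = FALSE]
  }
  total <- obs$ref_depth + obs$alt_depth
  n_skipped <- sum(total <= 0)
  obs <- obs[total > 0, , drop = FALSE]
  out <- tibble::tibble(
    chromosome = obs$chromosome,
    position = obs$position,
    frequency = obs$alt_depth / (obs$ref_depth + obs$alt_depth)
  )
  key <- chromosome_sort_key(out$chromosome)
  out <- out[order(key$rank, key$label, out$position), , drop = FALSE]
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Detect loss-of-heterozygosity intervals from a BAF series
#'
#' A windowed operationalization of the visual LOH signature (consecutive
#' regions whose SNVs are all homozygous, balance 0 or 1): a sliding window
#' of `window_snvs` consecutive points on a chromosome is flagged when the
#' fraction of points strictly inside the heterozygous band is at most
#' `max_het_fraction`; overlapping flagged windows are merged into maximal
#' intervals.
#'
#' @param points BAF series from [baf_series()] (sorted by chromosome and
#'   position).
#' @param window_snvs Window size in SNVs (default 25; must be >= 2).
#' @param het_band Numeric length-2: the open heterozygous balance band
#'   (default `c(0.3, 0.7)`).
#' @param max_het_fraction Maximal tolerated heterozygous fraction inside a
#'   flagged window (default 0.1).
#' @return Tibble of intervals: `chromosome`, `start`, `end` (positions of
#'   the first and last SNV covered), `n_snvs`.
#' @export
detect_loh <- function(points, window_snvs = 25L, het_band = c(0.3, 0.7),
                       max_het_fraction = 0.1) {
  window_snvs <- as.integer(window_snvs)
  if (is.na(window_snvs) || window_snvs < 2) {
    stop_config("window_snvs must be >= 2")
  }
  out <- list()
  for (ch in unique(points$chromosome)) {
    p <- points[points$chromosome == ch, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    n <- nrow(p)
    if (n < window_snvs) next
    het <- p$frequency > het_band[1] & p$frequency < het_band[2]
    # window het counts via cumulative sums
    cs <- cumsum(c(0, het))
    starts <- seq_len(n - window_snvs + 1)
    counts <- cs[starts + window_snvs] - cs[starts]
    flagged <- counts / window_snvs <= max_het_fraction
    if (!any(flagged)) next
    covered <- rep(FALSE, n)
    for (s in starts[flagged]) covered[s:(s + window_snvs - 1)] <- TRUE
    r <- rle(covered)
    stop_idx <- cumsum(r$lengths)
    start_idx <- stop_idx - r$lengths + 1
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chromosome = ch,
        start = p$position[start_idx[k]],
        end = p$position[stop_idx[k]],
        n_snvs = stop_idx[k] - start_idx[k] + 1L
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chromosome = character(), start = integer(),
                          end = integer(), n_snvs = integer()))
  }
  dplyr::bind_rows(out)
}

#' Build an IGV locus outlink
#'
#' Substitutes the `{locus}` placeholder of the configured IGV URL template
#' with 1-based inclusive display coordinates for an internal 0-based
#' half-open interval.
#'
#' @param env Named vector from [read_env_file()]; must contain an
#'   `IGV_LINK` template with the literal placeholder `{locus}`.
#' @param chromosome Chromosome label.
#' @param start,end Internal 0-based half-open interval.
#' @return The URL string.
#' @export
igv_locus_link <- function(env, chromosome, start, end) {
  if (!"IGV_LINK" %in% names(env)) stop_config("env config has no IGV_LINK key")
  template <- env[["IGV_LINK"]]
  if (!grepl("{locus}", template, fixed = TRUE)) {
    stop_config("IGV_LINK template lacks the {locus} placeholder")
  }
  locus <- sprintf("%s:%d-%d", chromosome, as.integer(start) + 1L, as.integer(end))
  sub("{locus}", locus, template, fixed = TRUE)
}

#' Export a plot series as JSON
#'
#' Serializes a boxplot, scatter or BAF series (plus thresholds when
#' attached) into a JSON document for downstream plotting.
#'
#' @param series A series object from [boxplot_series()],
#'   [scatter_series()] or [baf_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_series_json <- function(series, path) {
  payload <- if (is.data.frame(series)) {
    doc <- list(points = series)
    g <- attr(series, "gene")
    th <- attr(series, "thresholds")
    if (!is.null(g)) doc$gene <- g
    if (!is.null(th)) doc$thresholds <- unclass(th)
    doc
  } else {
    series
  }
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  write_lines_atomic(json, path)
}
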