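# Seeded synthetic-data generator: cnr cohorts with injected single- and
# multi-exon deletions/duplications, matching cns segments, trio sets, and
# SNV VCFs with an optional LOH region.

EVENT_KINDS <- c(het_del = -1.0, hom_del = -3.3, dup = 0.58)

#' Specification for a synthetic cnr cohort
#'
#' Describes the cohort the generator emits: a gene model (where each gene's
#' exons sit), the number of samples, the baseline noise, and the CNV events
#' to inject. Defaults model a quiet diploid exome slice: per-bin log2 noise
#' with standard deviation 0.15 around 0, mean raw depth 200, and event
#' shifts that move a bin's log2 by -1.0 (heterozygous deletion), -3.3
#' (homozygous deletion) or +0.58 (duplication) — deep enough that the
#' intended call is assigned with near certainty at the default noise.
#'
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @param genes Tibble with columns `gene`, `chromosome`, `n_exons`,
#'   `start`, `exon_spacing` (distance between consecutive exon starts).
#' @param n_samples Number of cohort samples.
#' @param baseline_log2_sd Standard deviation of the per-bin log2 noise.
#' @param baseline_depth_mean Mean raw depth at log2 = 0.
#' @param events Optional tibble with columns `sample` (1-based index),
#'   `gene`, `exon_from`, `exon_to`, `kind` (`"het_del"`, `"hom_del"`,
#'   `"dup"`) and optional `log2_shift` (kind default used when `NA`).
#' @param bin_width Width of each exon bin in bp.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed, genes, n_samples,
                       baseline_log2_sd = 0.15, baseline_depth_mean = 200,
                       events = NULL, bin_width = 120L) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene", "chromosome", "n_exons", "start", "exon_spacing")
  missing <- setdiff(required, names(genes))
  if (length(missing)) {
    stop_config("genes table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(genes$exon_spacing <= bin_width)) {
    stop_config("exon_spacing must exceed bin_width")
  }
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    if (!"log2_shift" %in% names(events)) events$log2_shift <- NA_real_
    if (!all(events$kind %in% names(EVENT_KINDS))) {
      stop_config("unknown event kind: %s",
                  paste(setdiff(events$kind, names(EVENT_KINDS)), collapse = ", "))
    }
    for (i in seq_len(nrow(events))) {
      g <- genes[genes$gene == events$gene[i], , drop = FALSE]
      if (nrow(g) == 0) stop_config("event gene '%s' not in gene model", events$gene[i])
      if (events$exon_from[i] < 1 || events$exon_to[i] > g$n_exons[1] ||
          events$exon_from[i] > events$exon_to[i]) {
        stop_config("event exon range %d-%d outside gene '%s' (1-%d)",
                    events$exon_from[i], events$exon_to[i], events$gene[i],
                    g$n_exons[1])
      }
      if (events$sample[i] < 1 || events$sample[i] > n_samples) {
        stop_config("event sample index %d outside cohort (1-%d)",
                    events$sample[i], n_samples)
      }
    }
  }
  structure(
    list(seed = as.integer(seed), genes = genes, n_samples = as.integer(n_samples),
         baseline_log2_sd = baseline_log2_sd,
         baseline_depth_mean = baseline_depth_mean,
         events = events, bin_width = as.integer(bin_width)),
    class = "synth_spec"
  )
}

# One row per (gene, exon) of the gene model, in reference bin order.
synth_bin_layout <- function(spec) {
  layout <- purrr::pmap_dfr(spec$genes, function(gene, chromosome, n_exons,
                                                 start, exon_spacing, ...) {
    starts <- as.integer(start + (seq_len(n_exons) - 1) * exon_spacing)
    tibble::tibble(
      chromosome = chromosome, start = starts,
      end = starts + spec$bin_width, gene = gene,
      exon_index = seq_len(n_exons)
    )
  })
  key <- chromosome_sort_key(layout$chromosome)
  layout[order(key$rank, key$label, layout$gene, layout$start), , drop = FALSE]
}

#' Generate a synthetic cnr cohort
#'
#' Draws, per sample and bin, `log2 ~ Normal(0, baseline_log2_sd)` plus the
#' injected event shift where applicable, and couples the raw depth to it
#' multiplicatively (`depth = round(baseline_depth_mean * 2^log2)`) so
#' depth- and log2-based views agree. Deterministic per seed.
#'
#' @param spec A [synth_spec()] object.
#' @return Named list of cnr tibbles, one per sample
#'   (`sample_001`, ...), each in [read_cnr()] shape.
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  layout <- synth_bin_layout(spec)
  n_bins <- nrow(layout)
  set.seed(spec$seed)
  cohort <- vector("list", spec$n_samples)
  names(cohort) <- sprintf("sample_%03d", seq_len(spec$n_samples))
  for (s in seq_len(spec$n_samples)) {
    log2 <- stats::rnorm(n_bins, 0, spec$baseline_log2_sd)
    if (!is.null(spec$events)) {
      ev <- spec$events[spec$events$sample == s, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        shift <- ev$log2_shift[i]
        if (is.na(shift)) shift <- EVENT_KINDS[[ev$kind[i]]]
        hit <- layout$gene == ev$gene[i] &
          layout$exon_index >= ev$exon_from[i] &
          layout$exon_index <= ev$exon_to[i]
        log2[hit] <- log2[hit] + shift
      }
    }
    depth <- round(spec$baseline_depth_mean * 2^log2)
    weight <- round(stats::runif(n_bins, 0.6, 1), 6)
    cohort[[s]] <- tibble::tibble(
      chromosome = layout$chromosome,
      start = layout$start,
      end = layout$end,
      gene = layout$gene,
      depth = depth,
      log2 = round(log2, 6),
      weight = weight
    )
  }
  cohort
}

#' Aggregate one sample's bins into synthetic cns segments
#'
#' Maximal runs of positionally consecutive bins on the same chromosome with
#' the same call become one segment, with log2 and depth averaged, `probes`
#' the run length and `weight` the summed bin weights.
#'
#' @param bins One sample's cnr tibble.
#' @param thresholds A [cnv_thresholds()] object.
#' @return Segments tibble in [read_cns()] shape.
#' @export
synth_cns <- function(bins, thresholds = cnv_thresholds()) {
  key <- chromosome_sort_key(bins$chromosome)
  bins <- bins[order(key$rank, key$label, bins$start), , drop = FALSE]
  call <- as.character(classify_log2(bins$log2, thresholds))
  n <- nrow(bins)
  new_seg <- c(TRUE, bins$chromosome[-1] != bins$chromosome[-n] |
                 call[-1] != call[-n])
  seg_id <- cumsum(new_seg)
  bins |>
    dplyr::mutate(.seg = seg_id) |>
    dplyr::group_by(.data$.seg) |>
    dplyr::summarise(
      chromosome = dplyr::first(.data$chromosome),
      start = min(.data$start),
      end = max(.data$end),
      genes = list(unique(.data$gene)),
      log2 = mean(.data$log2),
      depth = mean(.data$depth),
      probes = dplyr::n(),
      weight = sum(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::select(-".seg") |>
    dplyr::mutate(cn = log2_to_cn(.data$log2))
}

#' Generate synthetic SNV observations with an optional LOH region
#'
#' Outside the LOH interval, genotypes are drawn heterozygous / homozygous
#' reference / homozygous alternative with probabilities 0.5 / 0.25 / 0.25
#' and allelic depths (d, d) / (2d, 0) / (0, 2d); inside the LOH interval no
#' heterozygous genotypes occur (homozygous reference and alternative each
#' 0.5). Positions are drawn uniformly without replacement and sorted.
#' Deterministic per seed.
#'
#' @param chromosome Chromosome label.
#' @param n_snvs Number of SNVs (>= 1).
#' @param loh_interval Optional numeric length-2 `(start, end)` in 1-based
#'   inclusive coordinates.
#' @param seed Integer seed.
#' @param chrom_length Model chromosome length in bp.
#' @param allele_depth Per-allele read depth `d` (default 15).
#' @return Tibble in [read_snvs()] shape (`chromosome`, `position`,
#'   `ref_depth`, `alt_depth`, `genotype`).
#' @export
synth_snvs <- function(chromosome, n_snvs, loh_interval = NULL, seed = 1L,
                       chrom_length = 2e8, allele_depth = 15L) {
  if (n_snvs < 1) stop_config("n_snvs must be >= 1")
  if (!is.null(loh_interval)) {
    if (length(loh_interval) != 2 || loh_interval[1] > loh_interval[2] ||
        loh_interval[1] < 1 || loh_interval[2] > chrom_length) {
      stop_config("loh_interval must lie within 1..chrom_length")
    }
  }
  set.seed(as.integer(seed))
  position <- sort(sample.int(as.integer(chrom_length), n_snvs))
  in_loh <- if (is.null(loh_interval)) rep(FALSE, n_snvs) else {
    position >= loh_interval[1] & position <= loh_interval[2]
  }
  u <- stats::runif(n_snvs)
  genotype <- ifelse(in_loh,
                     ifelse(u < 0.5, "0/0", "1/1"),
                     ifelse(u < 0.5, "0/1", ifelse(u < 0.75, "0/0", "1/1")))
  d <- as.integer(allele_depth)
  ref_depth <- ifelse(genotype == "0/1", d, ifelse(genotype == "0/0", 2L * d, 0L))
  alt_depth <- ifelse(genotype == "0/1", d, ifelse(genotype == "1/1", 2L * d, 0L))
  tibble::tibble(
    chromosome = chromosome,
    position = position,
    ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(alt_depth),
    genotype = genotype
  )
}

#' Write synthetic SNV observations as a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 with GT and AD per record, readable
#' by [read_snvs()]. Synthetic REF/ALT alleles are fixed (A, G).
#'
#' @param snvs Tibble from [synth_snvs()].
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return The path, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, sample_name = "SYNTH") {
  contigs <- unique(snvs$chromosome)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exoncnv_synth",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- character(0)
  if (nrow(snvs) > 0) {
    rows <- paste(
      snvs$chromosome, snvs$position, ".", "A", "G", ".", "PASS", ".",
      "GT:AD",
      sprintf("%s:%d,%d", snvs$genotype, snvs$ref_depth, snvs$alt_depth),
      sep = "\t"
    )
  }
  write_lines_atomic(c(header, rows), path)
}

#' Generate a synthetic trio
#'
#' Builds index, father and mother cnr tables over the same gene model:
#' `denovo_events` are injected into the index only, `inherited_events`
#' into the index and the named parent.
#'
#' @param spec A [synth_spec()] for a 1-sample cohort (the shared layout and
#'   noise model; its `events` field is ignored).
#' @param denovo_events Event tibble as in [synth_spec()] (sample column
#'   ignored), injected into the index only.
#' @param inherited_events Event tibble with an extra `parent` column
#'   (`"father"` or `"mother"`), injected into the index and that parent.
#' @return Named list of three cnr tibbles: `index`, `father`, `mother`.
#' @export
synth_trio <- function(spec, denovo_events = NULL, inherited_events = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  fix_sample <- function(ev) {
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    ev <- tibble::as_tibble(ev)
    ev$sample <- 1L
    ev
  }
  member_spec <- function(seed_offset, events) {
    synth_spec(seed = spec$seed + seed_offset, genes = spec$genes, n_samples = 1L,
               baseline_log2_sd = spec$baseline_log2_sd,
               baseline_depth_mean = spec$baseline_depth_mean,
               events = events, bin_width = spec$bin_width)
  }
  de <- fix_sample(denovo_events)
  inh <- fix_sample(inherited_events)
  index_events <- dplyr::bind_rows(
    if (!is.null(de)) de[, c("sample", "gene", "exon_from", "exon_to", "kind")],
    if (!is.null(inh)) inh[, c("sample", "gene", "exon_from", "exon_to", "kind")]
  )
  if (!is.null(index_events) && nrow(index_events) == 0) index_events <- NULL
  father_events <- if (!is.null(inh)) {
    fe <- inh[inh$parent == "father", c("sample", "gene", "exon_from", "exon_to", "kind")]
    if (nrow(fe)) fe else NULL
  }
  mother_events <- if (!is.null(inh)) {
    me <- inh[inh$parent == "mother", c("sample", "gene", "exon_from", "exon_to", "kind")]
    if (nrow(me)) me else NULL
  }
  list(
    index = synth_cohort(member_spec(0L, index_events))[[1]],
    father = synth_cohort(member_spec(1L, father_events))[[1]],
    mother = synth_cohort(member_spec(2L, mother_events))[[1]]
  )
}
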