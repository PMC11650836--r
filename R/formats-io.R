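# Readers and writers for the external table formats: CNVkit-style cnr /
# bintest / cns TSVs, SNV VCFs, AnnotSV annotation tables, gene panels and
# key=value configuration files.

CNR_COLUMNS <- c("chromosome", "start", "end", "gene", "depth", "log2", "weight")
PVALUE_COLUMN <- "p_bintest"
ANTITARGET_LABELS <- c("Antitarget", "-")

validate_cnr <- function(bins) {
  bad <- which(!(bins$start < bins$end))
  if (length(bad)) stop_content("start >= end at data row %d", bad[1])
  bad <- which(bins$depth < 0)
  if (length(bad)) stop_content("negative depth at data row %d", bad[1])
  bad <- which(bins$weight < 0)
  if (length(bad)) stop_content("negative weight at data row %d", bad[1])
  if (PVALUE_COLUMN %in% names(bins)) {
    p <- bins[[PVALUE_COLUMN]]
    bad <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad)) stop_content("p-value outside [0, 1] at data row %d", bad[1])
  }
  invisible(bins)
}

#' Read a cnr or bintest coverage-bin table
#'
#' Parses a tab-separated per-bin copy-number table in the CNVkit dialect:
#' one row per target/antitarget bin with the bias-corrected log2 coverage
#' ratio against a pooled reference (`log2`), the raw mean coverage (`depth`)
#' and the bin weight. A bintest table is the same shape plus a per-bin
#' p-value column (`p_bintest`) from the bin-wise z-test.
#'
#' Coordinates are 0-based half-open (BED convention). Row order is
#' preserved. Cells that are empty or "." are treated as missing; missing
#' values in mandatory numeric columns are an error, a missing p-value is
#' kept as `NA`.
#'
#' @param path Path to the tab-separated file (header row required).
#' @param expect_pvalue If `TRUE`, require the `p_bintest` column (bintest
#'   files); otherwise the column is read when present.
#' @return A tibble with columns `chromosome`, `start`, `end`, `gene`,
#'   `depth`, `log2`, `weight` and, when present, `p_bintest`.
#' @export
read_cnr <- function(path, expect_pvalue = FALSE) {
  raw <- read_tsv_character(path)
  required <- CNR_COLUMNS
  if (expect_pvalue) required <- c(required, PVALUE_COLUMN)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_schema("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  bins <- tibble::tibble(
    chromosome = as.character(raw$chromosome),
    start = as.integer(parse_numeric_column(raw$start, "start")),
    end = as.integer(parse_numeric_column(raw$end, "end")),
    gene = as.character(raw$gene),
    depth = parse_numeric_column(raw$depth, "depth"),
    log2 = parse_numeric_column(raw$log2, "log2"),
    weight = parse_numeric_column(raw$weight, "weight")
  )
  if (PVALUE_COLUMN %in% names(raw)) {
    bins[[PVALUE_COLUMN]] <- parse_numeric_column(raw[[PVALUE_COLUMN]],
                                                  PVALUE_COLUMN, allow_na = TRUE)
  }
  validate_cnr(bins)
  bins
}

#' Write a cnr or bintest table
#'
#' Inverse of [read_cnr()]: floats are written at 6 decimal places, so a
#' write/read round trip reproduces every field at that precision. The
#' p-value column is emitted only when at least one row carries a p-value.
#' Output is written atomically (temporary file, then rename).
#'
#' @param bins Tibble as returned by [read_cnr()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cnr <- function(bins, path) {
  emit_p <- PVALUE_COLUMN %in% names(bins) && any(!is.na(bins[[PVALUE_COLUMN]]))
  cols <- CNR_COLUMNS
  if (emit_p) cols <- c(cols, PVALUE_COLUMN)
  header <- paste(cols, collapse = "\t")
  if (nrow(bins) == 0) {
    return(write_lines_atomic(header, path))
  }
  fields <- list(
    bins$chromosome,
    format_tsv_integer(bins$start),
    format_tsv_integer(bins$end),
    bins$gene,
    format_tsv_number(bins$depth),
    format_tsv_number(bins$log2),
    format_tsv_number(bins$weight)
  )
  if (emit_p) fields <- c(fields, list(format_tsv_number(bins[[PVALUE_COLUMN]])))
  rows <- do.call(paste, c(fields, sep = "\t"))
  write_lines_atomic(c(header, rows), path)
}

#' Read a cns segment table
#'
#' Parses the per-segment aggregation of bins produced after segmentation:
#' each row spans `probes` bins and carries the aggregated log2 ratio and
#' depth. The gene cell may hold several comma-joined gene labels; it is
#' split into the list-column `genes`.
#'
#' @param path Path to the tab-separated cns file.
#' @return A tibble with columns `chromosome`, `start`, `end`, `genes`
#'   (list of character), `log2`, `depth`, `probes`, `weight` and, when
#'   present in the file, the integer copy-number call `cn`.
#' @export
read_cns <- function(path) {
  raw <- read_tsv_character(path)
  required <- c("chromosome", "start", "end", "gene", "log2", "depth", "probes", "weight")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_schema("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  segments <- tibble::tibble(
    chromosome = as.character(raw$chromosome),
    start = as.integer(parse_numeric_column(raw$start, "start")),
    end = as.integer(parse_numeric_column(raw$end, "end")),
    genes = strsplit(as.character(raw$gene), ",", fixed = TRUE),
    log2 = parse_numeric_column(raw$log2, "log2"),
    depth = parse_numeric_column(raw$depth, "depth"),
    probes = as.integer(parse_numeric_column(raw$probes, "probes")),
    weight = parse_numeric_column(raw$weight, "weight")
  )
  if ("cn" %in% names(raw)) {
    segments$cn <- as.integer(parse_numeric_column(raw$cn, "cn", allow_na = TRUE))
  }
  bad <- which(!(segments$start < segments$end))
  if (length(bad)) stop_content("start >= end at data row %d", bad[1])
  bad <- which(segments$probes < 1)
  if (length(bad)) stop_content("probes < 1 at data row %d", bad[1])
  bad <- which(segments$depth < 0)
  if (length(bad)) stop_content("negative depth at data row %d", bad[1])
  segments
}

#' Write a cns segment table
#'
#' @param segments Tibble as returned by [read_cns()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cns <- function(segments, path) {
  cols <- c("chromosome", "start", "end", "gene", "log2", "depth", "probes", "weight")
  emit_cn <- "cn" %in% names(segments) && any(!is.na(segments$cn))
  if (emit_cn) cols <- c(cols, "cn")
  header <- paste(cols, collapse = "\t")
  if (nrow(segments) == 0) {
    return(write_lines_atomic(header, path))
  }
  fields <- list(
    segments$chromosome,
    format_tsv_integer(segments$start),
    format_tsv_integer(segments$end),
    vapply(segments$genes, paste, character(1), collapse = ","),
    format_tsv_number(segments$log2),
    format_tsv_number(segments$depth),
    format_tsv_integer(segments$probes),
    format_tsv_number(segments$weight)
  )
  if (emit_cn) fields <- c(fields, list(format_tsv_integer(segments$cn)))
  rows <- do.call(paste, c(fields, sep = "\t"))
  write_lines_atomic(c(header, rows), path)
}

#' Read biallelic SNV observations from a VCF
#'
#' Extracts per-site reference and alternative read depths for biallelic
#' SNVs, the input for B-allele-frequency analysis. Depths come from the
#' per-sample allelic depth (AD) field of the first sample; records without
#' AD but with a genotype fall back to the genotype convention
#' heterozygous = (1, 1), homozygous reference = (1, 0), homozygous
#' alternative = (0, 1), so that the downstream allelic balance is exactly
#' 0, 0.5 or 1. Multiallelic records and non-SNV records are skipped; the
#' skip count is attached as attribute `n_skipped`.
#'
#' @param path Path to a VCF file (plain or bgzip-compressed).
#' @param region Optional region restriction, either a chromosome label or
#'   `"chrom:start-end"` in 1-based inclusive coordinates. A region absent
#'   from the file yields an empty result, not an error.
#' @return A tibble with columns `chromosome`, `position` (1-based),
#'   `ref_depth`, `alt_depth`, `genotype`.
#' @export
read_snvs <- function(path, region = NULL) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_io("cannot read VCF %s: %s", path, conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  empty <- tibble::tibble(chromosome = character(), position = integer(),
                          ref_depth = integer(), alt_depth = integer(),
                          genotype = character())
  if (n == 0) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & nchar(ref) == 1 & nchar(alt) == 1 & !is.na(alt)
  n_skipped <- sum(!snv)

  gt <- NULL
  ad <- NULL
  if (ncol(vcf@gt) >= 2) {
    gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
    ad <- suppressWarnings(vcfR::extract.gt(vcf, element = "AD")[, 1])
  }

  keep <- which(snv)
  ref_depth <- integer(length(keep))
  alt_depth <- integer(length(keep))
  genotype <- rep(NA_character_, length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    g <- if (!is.null(gt)) gt[i] else NA_character_
    genotype[j] <- g
    a <- if (!is.null(ad)) ad[i] else NA_character_
    if (!is.na(a) && nzchar(a)) {
      parts <- suppressWarnings(as.integer(strsplit(a, ",", fixed = TRUE)[[1]]))
      ref_depth[j] <- parts[1]
      alt_depth[j] <- if (length(parts) >= 2) parts[2] else 0L
    } else if (!is.na(g)) {
      alleles <- strsplit(g, "[/|]")[[1]]
      n_alt <- sum(alleles == "1")
      n_ref <- sum(alleles == "0")
      if (n_alt > 0 && n_ref > 0) {
        ref_depth[j] <- 1L; alt_depth[j] <- 1L
      } else if (n_alt > 0) {
        ref_depth[j] <- 0L; alt_depth[j] <- 1L
      } else {
        ref_depth[j] <- 1L; alt_depth[j] <- 0L
      }
    } else {
      ref_depth[j] <- 0L
      alt_depth[j] <- 0L
    }
  }
  out <- tibble::tibble(
    chromosome = unname(fix[keep, "CHROM"]),
    position = as.integer(fix[keep, "POS"]),
    ref_depth = ref_depth,
    alt_depth = alt_depth,
    genotype = genotype
  )
  if (!is.null(region)) {
    reg <- parse_region(region)
    sel <- same_chromosome(out$chromosome, reg$chromosome)
    if (!is.na(reg$start)) {
      sel <- sel & out$position >= reg$start & out$position <= reg$end
    }
    out <- out[sel, , drop = FALSE]
  }
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

# Parse "chrom" or "chrom:start-end" (1-based inclusive display coordinates).
parse_region <- function(region) {
  if (!is.character(region) || length(region) != 1 || !nzchar(region)) {
    stop_config("malformed region '%s'", paste(region, collapse = ","))
  }
  if (!grepl(":", region, fixed = TRUE)) {
    return(list(chromosome = region, start = NA_integer_, end = NA_integer_))
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4) stop_config("malformed region '%s'", region)
  start <- as.integer(gsub(",", "", m[3], fixed = TRUE))
  end <- as.integer(gsub(",", "", m[4], fixed = TRUE))
  if (is.na(start) || is.na(end) || start > end) {
    stop_config("malformed region '%s'", region)
  }
  list(chromosome = m[2], start = start, end = end)
}

#' Read and reduce an AnnotSV annotation table
#'
#' AnnotSV full-annotation TSVs carry on the order of a hundred columns; a
#' column configuration selects the subset to expose, in the configured
#' order. Empty cells and "." become `NA`.
#'
#' @param path Path to the AnnotSV tab-separated output.
#' @param columns Character vector of column names to keep, in display order.
#' @return A tibble with exactly the configured columns.
#' @export
read_annotsv <- function(path, columns) {
  if (length(columns) == 0) stop_config("empty column configuration")
  raw <- read_tsv_character(path)
  missing <- setdiff(columns, names(raw))
  if (length(missing)) {
    stop_schema("column(s) absent from AnnotSV table: %s",
                paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(raw[, columns, drop = FALSE])
  out[] <- lapply(out, function(x) {
    x[x == "" | x == "."] <- NA_character_
    x
  })
  out
}

#' Read a column-selection configuration
#'
#' Accepts either one column name per line or a single tab-delimited line;
#' lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the configuration file.
#' @return Character vector of column names.
#' @export
read_column_config <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- unlist(strsplit(lines, "\t", fixed = TRUE), use.names = FALSE)
  cols <- trimws(cols)
  cols <- cols[nzchar(cols)]
  if (length(cols) == 0) stop_config("column configuration is empty")
  cols
}

#' Read an env-style key=value configuration file
#'
#' Recognized keys include `IGV_LINK` (an IGV locus URL template containing
#' the literal placeholder `{locus}`), `REFERENCE_PATH` and `PANEL_DIR`.
#' Unknown keys are kept. Duplicate keys are an error.
#'
#' @param path Path to the env file (`KEY=VALUE` lines, `#` comments allowed).
#' @return Named character vector.
#' @export
read_env_file <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  has_eq <- grepl("=", lines, fixed = TRUE)
  if (any(!has_eq)) stop_config("env line without '=': %s", lines[!has_eq][1])
  keys <- trimws(sub("=.*$", "", lines))
  values <- sub("^[^=]*=", "", lines)
  if (anyDuplicated(keys)) {
    stop_config("duplicate env key: %s", keys[duplicated(keys)][1])
  }
  stats::setNames(values, keys)
}

#' Load a gene panel
#'
#' Panels restrict the analysis to candidate genes. Two dialects are
#' supported: plain text (one gene symbol per line, `#` comments allowed)
#' and PanelApp-style TSV, from which the gene-symbol column (first header
#' containing "symbol", case-insensitive) is extracted, optionally
#' restricted to rows whose confidence/status cell equals `confidence`.
#' Symbols are upper-cased, whitespace-stripped and deduplicated.
#'
#' @param path Path to the panel file.
#' @param kind `"txt"` or `"panelapp_tsv"`.
#' @param confidence Optional exact confidence-level value to keep
#'   (PanelApp TSV only).
#' @return An object of class `cnv_panel`: a list with `name` (file stem)
#'   and `genes` (character vector of unique upper-case symbols).
#' @export
load_panel <- function(path, kind = c("txt", "panelapp_tsv"), confidence = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (kind == "txt") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  } else {
    raw <- read_tsv_character(path)
    sym_col <- grep("symbol", names(raw), ignore.case = TRUE, value = TRUE)
    if (length(sym_col) == 0) {
      stop_schema("no gene-symbol column found in PanelApp TSV %s", path)
    }
    rows <- raw
    if (!is.null(confidence)) {
      conf_col <- grep("confidence", names(raw), ignore.case = TRUE, value = TRUE)
      if (length(conf_col) == 0) {
        conf_col <- grep("status", names(raw), ignore.case = TRUE, value = TRUE)
      }
      if (length(conf_col) == 0) {
        stop_schema("no confidence/status column found in PanelApp TSV %s", path)
      }
      rows <- raw[raw[[conf_col[1]]] == confidence, , drop = FALSE]
    }
    genes <- rows[[sym_col[1]]]
  }
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop_content("panel %s contains no genes", path)
  structure(
    list(name = tools::file_path_sans_ext(basename(path)), genes = genes),
    class = "cnv_panel"
  )
}

#' @export
print.cnv_panel <- function(x, ...) {
  cat(sprintf("<cnv_panel> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Write a plain-text gene panel
#'
#' @param panel A `cnv_panel` object from [load_panel()].
#' @param path Output path (one symbol per line).
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cnv_panel"))
  write_lines_atomic(panel$genes, path)
}

# Strip a trailing all-numeric "_<n>" target suffix from a gene label; any
# other label (including multi-underscore or non-numeric suffixes) is used
# verbatim.
normalize_gene_label <- function(gene) {
  sub("_[0-9]+$", "", gene)
}

#' Assign exon indices to coverage bins
#'
#' Exon identity in the cohort reference is positional: within each
#' (gene, chromosome) group, bins are sorted by start coordinate and
#' numbered 1..n. Gene labels with a trailing all-numeric `_<n>` target
#' suffix are collapsed to the bare gene symbol first. Background and
#' antitarget bins (gene label `"Antitarget"` or `"-"`) are excluded.
#' The numbering is invariant under permutation of the input rows.
#'
#' @param bins Tibble of coverage bins from [read_cnr()].
#' @return The exon-indexed bins: antitarget rows removed, `gene` replaced
#'   by the normalized label, new integer column `exon_index`, sorted by
#'   chromosome (natural order), gene and start.
#' @export
assign_exon_indices <- function(bins) {
  if (nrow(bins) == 0) {
    bins$exon_index <- integer()
    return(bins)
  }
  bins <- bins[!(bins$gene %in% ANTITARGET_LABELS), , drop = FALSE]
  bins$gene <- normalize_gene_label(bins$gene)
  key <- chromosome_sort_key(bins$chromosome)
  ord <- order(key$rank, key$label, bins$gene, bins$start, bins$end)
  bins <- bins[ord, , drop = FALSE]
  bins <- dplyr::group_by(bins, .data$gene, .data$chromosome)
  bins <- dplyr::mutate(bins, exon_index = dplyr::row_number())
  dplyr::ungroup(bins)
}
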