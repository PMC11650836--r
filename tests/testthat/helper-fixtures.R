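# Shared fixture builders. Everything is generated in code at test time.

# A small hand-written cnr tibble (valid, exon-indexable).
fixture_cnr <- function() {
  tibble::tibble(
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 500L, 900L, 5000L, 300L),
    end = c(220L, 620L, 1020L, 5120L, 420L),
    gene = c("UBR4_1", "UBR4_2", "UBR4_3", "FNTA_1", "ACTB_1"),
    depth = c(210, 180, 0, 240, 199.5),
    log2 = c(0.01, -0.52, -1.5, 0.35, 0.0),
    weight = c(0.9, 0.8, 0.7, 1.0, 0.95)
  )
}

write_fixture_cnr <- function(bins = fixture_cnr(), path = tempfile(fileext = ".cnr")) {
  exoncnv::write_cnr(bins, path)
  path
}

# Minimal single-sample VCF text with AD genotypes; returns the path.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf"),
                              records = NULL) {
  if (is.null(records)) {
    records <- c(
      "chr1\t1000\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:10,10",
      "chr1\t2000\t.\tC\tT\t.\tPASS\t.\tGT:AD\t1/1:0,20",
      "chr1\t3000\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/0:20,0",
      "chr1\t4000\t.\tT\tC,G\t.\tPASS\t.\tGT:AD\t1/2:0,10,10",
      "chr2\t1500\t.\tA\tC\t.\tPASS\t.\tGT:AD\t0/1:12,14"
    )
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  writeLines(c(header, records), path)
  path
}

# Cohort of n constant-log2 samples over one 5-exon gene, with optional
# per-sample overrides: a named list sample_index -> c(exon = log2).
constant_cohort <- function(n, overrides = list(), depth = 200) {
  base <- tibble::tibble(
    chromosome = "chr1",
    start = seq(100L, by = 1000L, length.out = 5L),
    end = seq(100L, by = 1000L, length.out = 5L) + 120L,
    gene = "G1",
    depth = depth,
    log2 = 0,
    weight = 1
  )
  cohort <- lapply(seq_len(n), function(i) {
    b <- base
    ov <- overrides[[as.character(i)]]
    if (!is.null(ov)) {
      for (ex in names(ov)) b$log2[as.integer(ex)] <- ov[[ex]]
    }
    b
  })
  names(cohort) <- sprintf("s%02d", seq_len(n))
  cohort
}

# Random exon-indexed bins over a handful of genes, for property tests.
random_indexed_bins <- function(n_genes = 3, max_exons = 8) {
  genes <- paste0("G", seq_len(n_genes))
  rows <- lapply(seq_along(genes), function(i) {
    n <- sample(2:max_exons, 1)
    starts <- sort(sample.int(1e6, n)) + (i - 1L) * 2e6
    tibble::tibble(
      chromosome = "chr1", start = starts, end = starts + 100L,
      gene = genes[i], depth = runif(n, 50, 400),
      log2 = rnorm(n, 0, 0.8), weight = runif(n)
    )
  })
  exoncnv::assign_exon_indices(dplyr::bind_rows(rows))
}

# Independent brute-force BH step-up oracle (direct definition:
# q_i = min over j with p_j >= p_i of min(1, p_j * m / rank_j)).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- numeric(m)
  r[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i] - 1e-15)
    min(1, min(p[js] * m / r[js]))
  }, numeric(1))
}

# Brute-force run finder: enumerate every contiguous exon window of each
# (gene, chromosome) group and keep maximal qualifying windows.
runs_oracle <- function(bins, direction, min_run, thresholds = exoncnv::cnv_thresholds()) {
  pred <- if (direction == "deletion") {
    bins$log2 <= thresholds$het_del_log2
  } else {
    bins$log2 > thresholds$dup_log2
  }
  out <- list()
  groups <- unique(bins[, c("gene", "chromosome")])
  for (g in seq_len(nrow(groups))) {
    sel <- bins$gene == groups$gene[g] & bins$chromosome == groups$chromosome[g]
    sub <- bins[sel, , drop = FALSE]
    sub <- sub[order(sub$exon_index), , drop = FALSE]
    p <- pred[sel][order(bins$exon_index[sel])]
    n <- nrow(sub)
    for (i in seq_len(n)) {
      for (j in i:n) {
        idx <- sub$exon_index[i:j]
        window_ok <- all(p[i:j]) && all(diff(idx) == 1)
        left_extendable <- i > 1 && p[i - 1] && sub$exon_index[i - 1] == idx[1] - 1
        right_extendable <- j < n && p[j + 1] && sub$exon_index[j + 1] == idx[length(idx)] + 1
        if (window_ok && !left_extendable && !right_extendable &&
            (j - i + 1) >= min_run) {
          out[[length(out) + 1]] <- sub[i:j, , drop = FALSE]
        }
      }
    }
  }
  if (length(out) == 0) return(bins[0, , drop = FALSE])
  dplyr::bind_rows(out)
}
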