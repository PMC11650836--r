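# Table readers/writers, VCF ingestion, panels, configs, exon indexing.

test_that("cnr parsing preserves rows and order and round-trips at 6 decimals", {
  bins <- fixture_cnr()
  path <- write_fixture_cnr(bins)
  back <- read_cnr(path)
  expect_identical(nrow(back), nrow(bins))
  expect_identical(back$gene, bins$gene)
  expect_equal(back$log2, bins$log2, tolerance = 1e-9)
  expect_equal(back$depth, bins$depth, tolerance = 1e-9)

  # header-only file is an empty collection, not an error
  empty <- bins[0, ]
  p2 <- write_fixture_cnr(empty)
  expect_identical(nrow(read_cnr(p2)), 0L)

  # byte-stable: writing the parsed table again reproduces the file exactly
  p3 <- tempfile(fileext = ".cnr")
  write_cnr(back, p3)
  expect_identical(readLines(p3), readLines(path))
})

test_that("bintest p-value column is required when expected, optional otherwise", {
  bins <- fixture_cnr()
  bins$p_bintest <- c(0.003, NA, 0.5, 1, 0)
  path <- write_fixture_cnr(bins)
  back <- read_cnr(path, expect_pvalue = TRUE)
  expect_equal(back$p_bintest[1], 0.003)
  expect_true(is.na(back$p_bintest[2]))

  plain <- write_fixture_cnr(fixture_cnr())
  expect_error(read_cnr(plain, expect_pvalue = TRUE), class = "exoncnv_schema_error")
  # p column emitted only when some record carries a p-value
  no_p <- fixture_cnr()
  no_p$p_bintest <- NA_real_
  p2 <- tempfile(fileext = ".cnr")
  write_cnr(no_p, p2)
  expect_false(grepl("p_bintest", readLines(p2, n = 1)))
})

test_that("cnr reader rejects bad files with precise errors", {
  expect_error(read_cnr(tempfile()), class = "exoncnv_io_error")

  path <- tempfile(fileext = ".cnr")
  writeLines(c("chromosome\tstart\tend\tgene\tdepth\tlog2",
               "chr1\t1\t2\tG\t5\t0"), path)
  expect_error(read_cnr(path), class = "exoncnv_schema_error", regexp = "weight")

  writeLines(c("chromosome\tstart\tend\tgene\tdepth\tlog2\tweight",
               "chr1\t1\t2\tG\t5\t0\t1",
               "chr1\t3\t4\tG\toops\t0\t1"), path)
  expect_error(read_cnr(path), class = "exoncnv_parse_error", regexp = "row 2")

  writeLines(c("chromosome\tstart\tend\tgene\tdepth\tlog2\tweight",
               "chr1\t1\t2\tG\t.\t0\t1"), path)
  expect_error(read_cnr(path), class = "exoncnv_content_error")
})

test_that("cns parsing splits gene lists and validates probes", {
  path <- tempfile(fileext = ".cns")
  writeLines(c("chromosome\tstart\tend\tgene\tlog2\tdepth\tprobes\tweight",
               "chr1\t100\t9000\tA,B\t-0.9\t120\t12\t9.5",
               "chr2\t100\t400\tC\t0.1\t210\t3\t2.5"), path)
  segs <- read_cns(path)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$genes[[1]], c("A", "B"))
  expect_identical(segs$probes, c(12L, 3L))

  writeLines(c("chromosome\tstart\tend\tgene\tlog2\tdepth\tprobes\tweight",
               "chr1\t100\t9000\tA\t-0.9\t120\t0\t9.5"), path)
  expect_error(read_cns(path), class = "exoncnv_content_error")
})

test_that("VCF ingestion extracts allelic depths, skips multiallelics, honors regions", {
  path <- write_fixture_vcf()
  snvs <- read_snvs(path)
  expect_identical(nrow(snvs), 4L)            # 5 records, one multiallelic
  expect_identical(attr(snvs, "n_skipped"), 1L)
  first <- snvs[snvs$position == 1000, ]
  expect_identical(c(first$ref_depth, first$alt_depth), c(10L, 10L))

  chr1 <- read_snvs(path, region = "chr1")
  expect_identical(sort(chr1$position), c(1000L, 2000L, 3000L))
  # naive oracle: full scan + filter
  expect_identical(nrow(chr1), sum(snvs$chromosome == "chr1"))
  windowed <- read_snvs(path, region = "chr1:1500-2500")
  expect_identical(windowed$position, 2000L)
  expect_identical(nrow(read_snvs(path, region = "chr9")), 0L)
})

test_that("VCF records without AD fall back to the genotype convention", {
  path <- write_fixture_vcf(records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT\t1/1",
    "chr1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t0/0"
  ))
  # rewrite header FORMAT column consistency is irrelevant to the parser
  snvs <- read_snvs(path)
  baf <- baf_series(snvs)
  expect_equal(baf$frequency, c(0.5, 1, 0))
})

test_that("AnnotSV reduction exposes exactly the configured columns in order", {
  path <- tempfile(fileext = ".tsv")
  header <- c("AnnotSV_ID", "SV_chrom", "SV_start", "SV_end", "SV_type",
              "Gene_name", "ACMG_class", "Extra1", "Extra2")
  rows <- vapply(1:10, function(i) {
    paste(c(sprintf("id%d", i), "1", i * 100, i * 100 + 50, "DEL",
            "GENE", "3", ".", ""), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)

  cfg <- c("SV_chrom", "SV_start", "SV_end", "SV_type")
  out <- read_annotsv(path, cfg)
  expect_identical(names(out), cfg)
  expect_identical(nrow(out), 10L)

  full <- read_annotsv(path, header)
  expect_identical(names(full), header)
  expect_true(all(is.na(full$Extra1)))        # "." becomes missing

  expect_error(read_annotsv(path, c("SV_chrom", "NOPE")),
               class = "exoncnv_schema_error", regexp = "NOPE")
  expect_error(read_annotsv(path, character(0)), class = "exoncnv_config_error")

  cfg_file <- tempfile()
  writeLines(c("# comment", "SV_chrom", "SV_start"), cfg_file)
  expect_identical(read_column_config(cfg_file), c("SV_chrom", "SV_start"))
  writeLines("SV_chrom\tSV_start\tSV_end", cfg_file)
  expect_identical(read_column_config(cfg_file), c("SV_chrom", "SV_start", "SV_end"))
})

test_that("panels load from txt and PanelApp TSVs with dedup and case folding", {
  txt <- tempfile(fileext = ".txt")
  writeLines(c("ubr4", "UBR4", "FNTA", "", "# comment"), txt)
  panel <- load_panel(txt, "txt")
  expect_setequal(panel$genes, c("UBR4", "FNTA"))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Entity Name\tGene Symbol\tGEL_Status_Confidence",
    "a\tubr4\tGreen", "b\tUBR4\tGreen", "c\tFNTA\tAmber",
    "d\tfnta\tGreen", "e\tACTB\tRed"
  ), tsv)
  p2 <- load_panel(tsv, "panelapp_tsv")
  expect_setequal(p2$genes, c("UBR4", "FNTA", "ACTB"))
  p3 <- load_panel(tsv, "panelapp_tsv", confidence = "Green")
  expect_setequal(p3$genes, c("UBR4", "FNTA"))

  empty <- tempfile()
  writeLines("# nothing", empty)
  expect_error(load_panel(empty, "txt"), class = "exoncnv_content_error")

  # round trip through the plain-text writer
  out <- tempfile()
  write_panel(p2, out)
  expect_setequal(load_panel(out, "txt")$genes, p2$genes)
})

test_that("env files parse to unique keys", {
  path <- tempfile()
  writeLines(c("# env", "IGV_LINK=http://host/goto?locus={locus}",
               "PANEL_DIR=/panels"), path)
  env <- read_env_file(path)
  expect_identical(unname(env["PANEL_DIR"]), "/panels")
  writeLines(c("A=1", "A=2"), path)
  expect_error(read_env_file(path), class = "exoncnv_config_error")
})

test_that("exon indexing numbers bins by position within gene and chromosome", {
  bins <- fixture_cnr()
  idx <- assign_exon_indices(bins)
  ubr4 <- idx[idx$gene == "UBR4", ]
  expect_identical(ubr4$exon_index[order(ubr4$start)], 1:3)
  expect_true(all(c("FNTA", "ACTB") %in% idx$gene))    # suffix stripped

  # same gene label on two chromosomes: independent numbering
  two <- tibble::tibble(
    chromosome = c("chr1", "chr2", "chr1"),
    start = c(10L, 10L, 500L), end = c(100L, 100L, 600L),
    gene = "G", depth = 100, log2 = 0, weight = 1
  )
  out <- assign_exon_indices(two)
  expect_identical(out$exon_index[out$chromosome == "chr2"], 1L)
  expect_identical(sort(out$exon_index[out$chromosome == "chr1"]), 1:2)

  # antitarget and background labels are excluded
  bg <- bins
  bg$gene[2] <- "Antitarget"
  bg$gene[5] <- "-"
  expect_false(any(assign_exon_indices(bg)$gene %in% c("Antitarget", "-")))
})

test_that("exon indexing is invariant under input permutation", {
  set.seed(42)
  for (rep in 1:5) {
    bins <- random_indexed_bins()
    raw <- bins[, setdiff(names(bins), "exon_index")]
    shuffled <- raw[sample.int(nrow(raw)), ]
    a <- assign_exon_indices(raw)
    b <- assign_exon_indices(shuffled)
    key <- function(x) x[order(x$gene, x$chromosome, x$start), c("gene", "start", "exon_index")]
    expect_identical(key(a), key(b))
    # each bin gets exactly one index and indices are 1..n per group
    counts <- dplyr::count(a, gene, chromosome)
    for (g in seq_len(nrow(counts))) {
      sub <- a[a$gene == counts$gene[g] & a$chromosome == counts$chromosome[g], ]
      expect_identical(sort(sub$exon_index), seq_len(nrow(sub)))
    }
  }
})
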