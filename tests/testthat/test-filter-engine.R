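# Frequency annotation, custom filters, runs, BH adjustment, bin z-test,
# presets.

make_annotated <- function() {
  cohort <- constant_cohort(10, overrides = list(
    "1" = c("2" = -1.5), "2" = c("2" = -1.5)
  ))
  ref <- build_reference(cohort)
  sample_bins <- constant_cohort(1, overrides = list("1" = c("2" = -1.5, "4" = -0.7)))[[1]]
  list(ref = ref, bins = annotate_bins(sample_bins, ref))
}

test_that("annotation attaches calls, copy numbers, frequencies and highlights", {
  x <- make_annotated()
  bins <- x$bins
  expect_equal(bins$hom_del_freq[bins$exon_index == 2], 0.2)
  expect_identical(as.character(bins$call[bins$exon_index == 2]), "homozygous_deletion")
  expect_identical(bins$cn[bins$exon_index == 2], 1L)  # 2*2^-1.5 = 0.707 -> 1
  # highlight boundary: below -0.65 only
  expect_true(bins$highlight[bins$exon_index == 2])
  expect_true(bins$highlight[bins$exon_index == 4])    # -0.7 < -0.65
  expect_false(any(bins$highlight[bins$exon_index %in% c(1, 3, 5)]))
  b2 <- annotate_bins(constant_cohort(1)[[1]],
                      thresholds = cnv_thresholds(grid_highlight_log2 = -0.65))
  expect_false(any(b2$highlight))

  # bin without a reference exon keeps missing frequencies but is retained
  extra <- constant_cohort(1)[[1]]
  extra$gene <- "G_NOT_IN_REF"
  ann <- annotate_bins(extra, x$ref)
  expect_identical(nrow(ann), 5L)
  expect_true(all(is.na(ann$hom_del_freq)))
})

test_that("custom filters are conjunctive, order-preserving and order-independent", {
  x <- make_annotated()
  bins <- x$bins

  expect_identical(apply_custom_filters(bins, filter_config()), bins)  # identity

  cfg <- filter_config(min_depth = 150)
  deep <- apply_custom_filters(bins, cfg)
  expect_true(all(deep$depth >= 150))

  # frequency ceiling: missing frequencies pass
  mixed <- bins
  mixed$hom_del_freq <- c(0.2, 0, NA, 0, 0)
  mixed$het_del_freq <- NA_real_
  mixed$dup_freq <- NA_real_
  kept <- apply_custom_filters(mixed, filter_config(max_inhouse_freq = 0.05))
  expect_identical(kept$exon_index, c(2L, 3L, 4L, 5L))

  # region (1-based inclusive string) against half-open bins
  reg <- apply_custom_filters(bins, filter_config(region = "chr1:101-220"))
  expect_identical(reg$exon_index, 1L)
  expect_error(filter_config(region = "chr1:x-y"), class = "exoncnv_config_error")

  # conjunction is order-independent: one pass equals sequential passes
  cfg_all <- filter_config(genes = "g1", min_depth = 10, min_abs_log2 = 0.5)
  seq1 <- apply_custom_filters(
    apply_custom_filters(bins, filter_config(min_abs_log2 = 0.5)),
    filter_config(genes = "g1", min_depth = 10))
  expect_identical(apply_custom_filters(bins, cfg_all), seq1)

  # copy-number set
  cn1 <- apply_custom_filters(bins, filter_config(copy_numbers = 1L))
  expect_true(all(cn1$cn == 1L))
})

test_that("consecutive-run detection equals exhaustive window enumeration", {
  th <- cnv_thresholds()
  # hand-built case: exons 3,4,5 deleted, plus isolated exons 7 and 9
  b <- constant_cohort(1)[[1]]
  b <- dplyr::bind_rows(b, b, b)[1:9, ]
  b$start <- seq(100L, by = 1000L, length.out = 9L)
  b$end <- b$start + 120L
  b$log2 <- c(0, 0, -0.8, -0.9, -0.6, 0, -0.8, 0, -0.9)
  b <- assign_exon_indices(b)
  runs <- find_consecutive_runs(b, "deletion", min_run = 2, thresholds = th)
  expect_identical(runs$exon_index, 3:5)
  expect_identical(unique(runs$run_length), 3L)
  # exons 7 and 9 qualify individually but are not consecutive
  expect_identical(nrow(find_consecutive_runs(b[b$exon_index %in% c(7, 9), ],
                                              "deletion", min_run = 2)), 0L)

  # min_run = 1 equals the plain per-bin filter
  r1 <- find_consecutive_runs(b, "deletion", min_run = 1, thresholds = th)
  expect_identical(sort(r1$exon_index),
                   sort(b$exon_index[b$log2 <= th$het_del_log2]))

  expect_error(find_consecutive_runs(b, "deletion", min_run = 0),
               class = "exoncnv_config_error")
})

test_that("run detection agrees with the brute-force oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    bins <- random_indexed_bins(n_genes = sample(1:4, 1))
    bins <- bins[seq_len(min(nrow(bins), 50)), ]
    min_run <- sample(1:3, 1)
    for (dir in c("deletion", "amplification")) {
      got <- find_consecutive_runs(bins, dir, min_run)
      want <- runs_oracle(bins, dir, min_run)
      key <- function(x) {
        x <- tibble::as_tibble(x)[, c("gene", "chromosome", "exon_index")]
        x[order(x$gene, x$chromosome, x$exon_index), ]
      }
      expect_identical(key(got), key(want))
    }
  }
})

test_that("BH step-up matches hand-executed examples and the oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "exoncnv_value_error")

  set.seed(123)
  for (rep in 1:200) {
    p <- runif(sample(1:50, 1))
    got <- bh_adjust(p)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    expect_equal(got, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), got[perm], tolerance = 1e-15)
  }
})

test_that("the recomputed bin z-test matches normal-tail examples", {
  cohort <- constant_cohort(20)
  set.seed(5)
  for (i in seq_along(cohort)) cohort[[i]]$log2 <- rnorm(5, 0, 0.25)
  ref <- build_reference(cohort)
  ref$mean_log2 <- 0
  ref$sd_log2 <- 0.25

  sample_bins <- constant_cohort(1)[[1]]
  sample_bins$log2 <- c(0, -1, 0, 0, 0)
  tested <- recompute_bintest(annotate_bins(sample_bins, ref), ref)
  expect_equal(tested$z[2], -4)
  expect_equal(tested$p_value[2], 2 * stats::pnorm(-4), tolerance = 1e-12)
  expect_equal(tested$p_value[2], 6.33e-5, tolerance = 1e-2)
  expect_equal(tested$p_value[1], 1)   # at the reference mean

  # all bins at the mean: nothing significant at any alpha < 1
  flat <- constant_cohort(1)[[1]]
  flat$log2 <- 0
  t2 <- recompute_bintest(annotate_bins(flat, ref), ref, alpha = 0.9)
  expect_false(any(t2$significant))

  # zero-sd exons are skipped with a count; empty testable set errors
  ref0 <- ref
  ref0$sd_log2 <- 0
  expect_error(recompute_bintest(annotate_bins(flat, ref0), ref0),
               class = "exoncnv_content_error")
  ref_half <- ref
  ref_half$sd_log2[1:2] <- 0
  t3 <- recompute_bintest(annotate_bins(flat, ref_half), ref_half)
  expect_identical(attr(t3, "n_skipped"), 2L)
  expect_identical(nrow(t3), 3L)
})

test_that("presets follow their definitions and compose with custom filters", {
  cohort <- constant_cohort(10)
  ref <- build_reference(cohort)
  cnr <- constant_cohort(1, overrides = list("1" = c("3" = -1.5, "4" = -0.6)))[[1]]
  bins_cnr <- annotate_bins(cnr, ref)
  bt <- cnr
  bt$gene <- c("UBR4", "UBR4", "FNTA", "FNTA", "FNTA")
  bins_bt <- annotate_bins(bt)

  expect_identical(apply_preset(bins_cnr, config = filter_config("total")), bins_cnr)
  expect_identical(apply_preset(bins_cnr, bins_bt, filter_config("bintest")), bins_bt)

  hom <- apply_preset(bins_cnr, config = filter_config("homozygous_deletion"))
  expect_identical(nrow(hom), 1L)
  expect_identical(hom$exon_index, 3L)

  panel <- structure(list(name = "p", genes = "UBR4"), class = "cnv_panel")
  cand <- apply_preset(bins_cnr, bins_bt, filter_config("bintest_candidate"), panel)
  expect_identical(unique(cand$gene), "UBR4")
  expect_identical(nrow(cand), 2L)
  expect_error(apply_preset(bins_cnr, bins_bt, filter_config("bintest_candidate")),
               class = "exoncnv_config_error")

  runs <- apply_preset(bins_cnr, config = filter_config("consecutive_del",
                                                        consecutive_cutoff = 2))
  expect_identical(runs$exon_index, 3:4)

  # custom filters apply after the preset
  hom_deep <- apply_preset(bins_cnr,
                           config = filter_config("homozygous_deletion", min_depth = 1e6))
  expect_identical(nrow(hom_deep), 0L)

  # every preset output is a subset of its input
  for (p in c("total", "homozygous_deletion", "consecutive_del", "consecutive_amp")) {
    out <- apply_preset(bins_cnr, config = filter_config(p))
    expect_true(all(out$start %in% bins_cnr$start))
  }
})
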