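# Trio mode: left join of an index sample's bins with both parents' cnr
# tables, and the de novo candidate filter.

#' Left-join index bins with parental cnr tables
#'
#' Joins on the exact bin key (chromosome, start, end, gene): exactly one
#' output row per index bin. Parental log2/depth are `NA` where a parent
#' lacks the key; duplicate keys within a parent use the first occurrence
#' and are counted in attributes `n_duplicate_father` /
#' `n_duplicate_mother`. Parental calls are classified from the parental
#' log2 with the same thresholds as the index.
#'
#' @param index_bins Annotated bins of the index sample (annotated
#'   internally when plain).
#' @param father_bins,mother_bins Parental cnr tibbles from [read_cnr()].
#' @param thresholds A [cnv_thresholds()] object.
#' @return Tibble with all index columns plus `father_log2`, `father_depth`,
#'   `father_call`, `mother_log2`, `mother_depth`, `mother_call`.
#' @export
trio_join <- function(index_bins, father_bins, mother_bins,
                      thresholds = cnv_thresholds()) {
  if (!"call" %in% names(index_bins)) {
    index_bins <- annotate_bins(index_bins, thresholds = thresholds)
  }
  join_parent <- function(joined, parent, prefix) {
    keys <- c("chromosome", "start", "end", "gene")
    parent <- parent[, c(keys, "log2", "depth"), drop = FALSE]
    dup <- duplicated(parent[, keys, drop = FALSE])
    n_dup <- sum(dup)
    parent <- parent[!dup, , drop = FALSE]
    names(parent)[names(parent) == "log2"] <- paste0(prefix, "_log2")
    names(parent)[names(parent) == "depth"] <- paste0(prefix, "_depth")
    out <- dplyr::left_join(joined, parent, by = keys)
    list(out = out, n_dup = n_dup)
  }
  # The index gene labels were normalized during exon indexing; normalize
  # the parents' labels the same way so the key matches.
  prep <- function(parent) {
    parent$gene <- normalize_gene_label(parent$gene)
    parent
  }
  f <- join_parent(index_bins, prep(father_bins), "father")
  m <- join_parent(f$out, prep(mother_bins), "mother")
  out <- m$out
  classify_or_na <- function(x) {
    call <- factor(rep(NA_character_, length(x)), levels = CALL_LEVELS)
    ok <- is.finite(x)
    if (any(ok)) call[ok] <- classify_log2(x[ok], thresholds)
    call
  }
  out$father_call <- classify_or_na(out$father_log2)
  out$mother_call <- classify_or_na(out$mother_log2)
  attr(out, "n_duplicate_father") <- as.integer(f$n_dup)
  attr(out, "n_duplicate_mother") <- as.integer(m$n_dup)
  out
}

#' Filter trio records for de novo CNV candidates
#'
#' Keeps records where the index call is aberrant (not normal) and both
#' parental calls are normal. Records with missing parental data cannot be
#' assessed: they are excluded and counted in attribute `n_incomplete`.
#'
#' @param records Trio records from [trio_join()].
#' @return The de novo candidate records; attribute `n_incomplete` counts
#'   index bins dropped for missing parental data.
#' @export
filter_denovo <- function(records) {
  complete <- !is.na(records$father_call) & !is.na(records$mother_call)
  aberrant <- records$call != "normal"
  n_incomplete <- sum(!complete & aberrant)
  keep <- complete & aberrant &
    records$father_call == "normal" & records$mother_call == "normal"
  out <- records[keep, , drop = FALSE]
  attr(out, "n_incomplete") <- as.integer(n_incomplete)
  out
}
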