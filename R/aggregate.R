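#' Collapse per-mammogram features to one record per woman
#'
#' Each feature is aggregated independently as the median over a woman's
#' mammograms (for an even count, the mean of the two central values).
#' Missing feature values (sentinels from degenerate images) are excluded
#' per feature; a woman whose values are all missing for a feature gets
#' `NA` there. The marginal median makes the per-woman value robust to a
#' single unusual mammogram and invariant to the ordering of her images.
#'
#' @param rows data frame with a `woman_id` column and one numeric column
#'   per feature (extra id columns `image_id`/`visit_index` are ignored).
#' @param feature_cols names of the feature columns; defaults to
#'   [glcm_feature_names] intersected with `names(rows)`.
#' @param single_earliest if `TRUE`, use only each woman's earliest
#'   mammogram (smallest `visit_index`, ties broken by row order) instead of
#'   the median over all of them - the single-mammogram sensitivity mode.
#' @return data frame: `woman_id`, `n_mammograms`, then the aggregated
#'   feature columns.
#' @export
aggregate_median <- function(rows, feature_cols = NULL, single_earliest = FALSE) {
  stopifnot(is.data.frame(rows), "woman_id" %in% names(rows))
  if (is.null(feature_cols))
    feature_cols <- intersect(glcm_feature_names(), names(rows))
  stopifnot(length(feature_cols) > 0, all(feature_cols %in% names(rows)))
  rows <- rows[!is.na(rows$woman_id), , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no rows to aggregate")
    return(data.frame(woman_id = character(), n_mammograms = integer()))
  }
  if (single_earliest) {
    ord <- if ("visit_index" %in% names(rows)) order(rows$visit_index) else seq_len(nrow(rows))
    rows_s <- rows[ord, , drop = FALSE]
    keep <- !duplicated(rows_s$woman_id)
    first <- rows_s[keep, c("woman_id", feature_cols), drop = FALSE]
    counts <- table(rows$woman_id)
    first$n_mammograms <- as.integer(counts[as.character(first$woman_id)])
    rownames(first) <- NULL
    return(first[, c("woman_id", "n_mammograms", feature_cols)])
  }
  ids <- unique(rows$woman_id)
  agg <- lapply(ids, function(w) {
    sub <- rows[rows$woman_id == w, feature_cols, drop = FALSE]
    med <- vapply(sub, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else median(v)
    }, numeric(1))
    c(n_mammograms = nrow(sub), med)
  })
  out <- as.data.frame(do.call(rbind, agg))
  out <- cbind(woman_id = ids, out, stringsAsFactors = FALSE)
  out$n_mammograms <- as.integer(out$n_mammograms)
  rownames(out) <- NULL
  out[, c("woman_id", "n_mammograms", feature_cols)]
}
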