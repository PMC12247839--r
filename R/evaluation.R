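#' Match predicted labels to ground truth
#'
#' For each truth bone, the matched predicted ids are those overlapping at
#' least `overlap_min` of the truth bone's volume AND whose own plurality
#' truth partner is that bone. The full overlap bookkeeping is retained for
#' diagnosis.
#'
#' @param pred,truth [label_volume()]s (or integer arrays) of equal shape.
#' @param overlap_min minimum overlap fraction of the truth volume
#'   (default 0.5).
#' @param expected_ids optional integer vector of truth ids that SHOULD be
#'   present (e.g. from a [bone_table()]); ids without any truth voxels
#'   (completely eroded bones) are carried through with empty match sets so
#'   they surface as `missing`.
#' @return a `label_correspondence`: per-truth match sets plus the overlap
#'   table.
#' @export
match_labels <- function(pred, truth, overlap_min = 0.5,
                         expected_ids = NULL) {
  p <- if (inherits(pred, "label_volume")) pred$labels else pred
  t <- if (inherits(truth, "label_volume")) truth$labels else truth
  if (!identical(dim(p), dim(t))) stop("pred/truth shapes differ")
  tids <- sort(union(label_ids(t), as.integer(expected_ids)))
  pids <- label_ids(p)
  sel <- t > 0L | p > 0L
  ov <- table(truth = factor(t[sel], levels = c(0L, tids)),
              pred = factor(p[sel], levels = c(0L, pids)))
  ov <- unclass(ov)
  tvol <- rowSums(ov)[as.character(tids)]
  # plurality truth partner of each predicted id (background excluded;
  # ties -> lower truth id, consistent with scan-order determinism)
  plur <- if (length(pids))
    vapply(as.character(pids), function(pp) {
      col <- ov[as.character(tids), pp]
      if (all(col == 0)) NA_integer_ else tids[which.max(col)]
    }, 0L)
  else integer(0)
  covering <- lapply(as.character(tids), function(tt) {
    if (tvol[tt] == 0 || length(pids) == 0L) return(integer(0))
    frac <- ov[tt, as.character(pids)] / tvol[tt]
    as.integer(pids[frac >= overlap_min])
  })
  names(covering) <- as.character(tids)
  matches <- lapply(as.character(tids), function(tt) {
    cand <- covering[[tt]]
    as.integer(cand[plur[as.character(cand)] == as.integer(tt)])
  })
  names(matches) <- as.character(tids)
  structure(list(truth_ids = tids, pred_ids = pids, matches = matches,
                 covering = covering, overlap = ov, truth_vol = tvol,
                 plurality = plur, overlap_min = overlap_min),
            class = "label_correspondence")
}

#' Classify per-bone segmentation outcomes
#'
#' Applies the bone-segmentation error taxonomy: a truth bone with no
#' matched prediction is `missing`; matched by two or more predictions,
#' `over_split` (one bone as 2+ materials); sharing its single matched
#' prediction with another truth bone, `over_connected` (2+ bones as one
#' material); otherwise `correct`.
#'
#' @param correspondence a [match_labels()] result.
#' @return data frame of `OutcomeRecord`s: `truth_id`, `outcome`,
#'   `matched_pred` (comma-separated ids), `overlap`.
#' @export
classify_outcomes <- function(correspondence) {
  stopifnot(inherits(correspondence, "label_correspondence"))
  co <- correspondence
  # how many truth bones does each predicted id cover at >= overlap_min?
  cover_count <- table(unlist(co$covering))
  recs <- lapply(seq_along(co$truth_ids), function(i) {
    tid <- co$truth_ids[i]
    cov <- co$covering[[as.character(tid)]]
    m <- co$matches[[as.character(tid)]]
    ovl <- if (length(cov))
      co$overlap[as.character(tid), as.character(cov)] /
        co$truth_vol[as.character(tid)]
    else numeric(0)
    shared <- length(cov) > 0L &&
      (any(cover_count[as.character(cov)] >= 2L) ||
         any(co$plurality[as.character(cov)] != tid))
    outcome <- if (length(cov) == 0L) "missing"
    else if (length(m) >= 2L) "over_split"
    else if (shared) "over_connected"
    else "correct"
    data.frame(truth_id = tid, outcome = outcome,
               matched_pred = paste(cov, collapse = ","),
               overlap = paste(signif(ovl, 4), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Segmentation accuracy
#'
#' The bone-segmentation accuracy percentage:
#' `(TP + TN) / (TP + TN + FP + FN) * 100` with TP = correctly segmented
#' bones, TN = 0 always (background is not quantified), FP = over-split
#' bones, FN = over-connected bones. Completely missing bones are counted as
#' false negatives by default (`include_missing = FALSE` reproduces the
#' strict formula, which names only over-split/over-connected errors).
#'
#' @param records outcome data frame from [classify_outcomes()].
#' @param include_missing count `missing` bones as false negatives
#'   (default `TRUE`, the conservative variant).
#' @return accuracy percentage in `[0, 100]`.
#' @export
accuracy <- function(records, include_missing = TRUE) {
  if (is.null(records) || nrow(records) == 0L)
    stop("accuracy is undefined for zero records")
  cnt <- outcome_counts(records, include_missing)
  with(cnt, (TP + TN) / (TP + TN + FP + FN) * 100)
}

outcome_counts <- function(records, include_missing = TRUE) {
  tp <- sum(records$outcome == "correct")
  fp <- sum(records$outcome == "over_split")
  fn <- sum(records$outcome == "over_connected") +
    if (include_missing) sum(records$outcome == "missing") else 0L
  list(TP = tp, TN = 0L, FP = fp, FN = fn)
}

#' Full segmentation report
#'
#' Convenience wrapper: match, classify, count and score in one step.
#'
#' @param pred,truth [label_volume()]s.
#' @param table optional [bone_table()] for the compartment summary.
#' @param overlap_min minimum overlap fraction (default 0.5).
#' @param include_missing see [accuracy()].
#' @return a `segmentation_report`: records, TP/TN/FP/FN counts, accuracy,
#'   and (when `table` given) the per-compartment table.
#' @export
segmentation_report <- function(pred, truth, table = NULL, overlap_min = 0.5,
                                include_missing = TRUE) {
  co <- match_labels(pred, truth, overlap_min,
                     expected_ids = if (!is.null(table)) table$id)
  recs <- classify_outcomes(co)
  cnt <- outcome_counts(recs, include_missing)
  rep <- list(records = recs, counts = cnt,
              accuracy = accuracy(recs, include_missing),
              compartments = if (!is.null(table))
                compartment_summary(recs, table, include_missing))
  class(rep) <- "segmentation_report"
  rep
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> %d bones, accuracy %.2f%%\n",
              nrow(x$records), x$accuracy))
  print(table(x$records$outcome))
  invisible(x)
}

#' Per-compartment accuracy summary
#'
#' Applies the accuracy formula within each anatomical compartment
#' (tarsals/carpals, metatarsals/metacarpals, proximal/distal phalanges,
#' sesamoids), the aggregation behind compartment accuracy heatmaps.
#'
#' @param records outcome data frame from [classify_outcomes()].
#' @param table a [bone_table()] covering every truth id in `records`.
#' @param include_missing see [accuracy()].
#' @return tidy data frame: `compartment`, `n`, `TP`, `FP`, `FN`,
#'   `accuracy`.
#' @export
compartment_summary <- function(records, table, include_missing = TRUE) {
  unknown <- setdiff(records$truth_id, table$id)
  if (length(unknown))
    stop("truth id(s) missing from bone table: ",
         paste(unknown, collapse = ", "))
  comp <- table$compartment[match(records$truth_id, table$id)]
  out <- lapply(split(seq_len(nrow(records)), comp), function(ix) {
    r <- records[ix, , drop = FALSE]
    cnt <- outcome_counts(r, include_missing)
    data.frame(compartment = comp[ix[1]], n = nrow(r), TP = cnt$TP,
               FP = cnt$FP, FN = cnt$FN,
               accuracy = accuracy(r, include_missing),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export a segmentation report
#'
#' Per-bone records as CSV, summary (counts + accuracy) as JSON, and the
#' compartment table as CSV.
#'
#' @param report a [segmentation_report()].
#' @param prefix output path prefix; files get `_records.csv`,
#'   `_summary.json`, `_compartments.csv` suffixes.
#' @return character vector of written paths, invisibly.
#' @export
export_report <- function(report, prefix) {
  stopifnot(inherits(report, "segmentation_report"))
  paths <- character(0)
  p1 <- paste0(prefix, "_records.csv")
  utils::write.csv(report$records, p1, row.names = FALSE)
  paths <- c(paths, p1)
  p2 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(c(report$counts, list(accuracy = report$accuracy)),
                       p2, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p2)
  if (!is.null(report$compartments)) {
    p3 <- paste0(prefix, "_compartments.csv")
    utils::write.csv(report$compartments, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Aggregate several segmentation reports
#'
#' Datasets can be combined either by averaging per-dataset accuracies
#' (each paw weighted equally) or by pooling all bone outcomes into one
#' accuracy computation (each bone weighted equally); both conventions are
#' provided.
#'
#' @param reports list of [segmentation_report()] objects.
#' @param include_missing see [accuracy()].
#' @return `list(average, pooled, n_datasets, n_bones)`.
#' @export
aggregate_reports <- function(reports, include_missing = TRUE) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, TRUE, "segmentation_report")))
  per <- vapply(reports, function(r) accuracy(r$records, include_missing), 0)
  all_recs <- do.call(rbind, lapply(reports, `[[`, "records"))
  list(average = mean(per), pooled = accuracy(all_recs, include_missing),
       n_datasets = length(reports), n_bones = nrow(all_recs))
}
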