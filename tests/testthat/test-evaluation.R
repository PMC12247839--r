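mk_lab <- function(d, assign) {
  a <- array(0L, d)
  for (nm in names(assign)) {
    ix <- assign[[nm]]
    a[ix] <- as.integer(nm)
  }
  a
}

test_that("perfect segmentation matches one-to-one with overlap 1", {
  set.seed(61)
  t <- random_label_map(c(8, 8, 8), 4, seed = 61)
  co <- match_labels(t, t, 0.5)
  recs <- classify_outcomes(co)
  expect_true(all(recs$outcome == "correct"))
  for (id in co$truth_ids)
    expect_identical(co$matches[[as.character(id)]], id)
  expect_identical(accuracy(recs), 100)
})

test_that("a split bone is over_split, a merged pair over_connected", {
  d <- c(8, 8, 8)
  truth <- array(0L, d)
  truth[2:7, 2:4, 2:7] <- 1L
  truth[2:7, 6:8, 2:7] <- 2L
  # split: bone 1 becomes preds 10 and 11 (equal halves)
  pred_split <- array(0L, d)
  pred_split[2:4, 2:4, 2:7] <- 10L
  pred_split[5:7, 2:4, 2:7] <- 11L
  pred_split[2:7, 6:8, 2:7] <- 12L
  recs <- classify_outcomes(match_labels(pred_split, truth, 0.1))
  expect_identical(recs$outcome[recs$truth_id == 1], "over_split")
  expect_identical(recs$outcome[recs$truth_id == 2], "correct")
  # merge: both bones inside one pred
  pred_merge <- array(0L, d)
  pred_merge[truth > 0] <- 7L
  recs2 <- classify_outcomes(match_labels(pred_merge, truth, 0.5))
  expect_true(all(recs2$outcome == "over_connected"))
  # zero overlap -> missing
  pred_none <- array(0L, d)
  pred_none[1, 1, 1] <- 3L
  recs3 <- classify_outcomes(match_labels(pred_none, truth, 0.5))
  expect_true(all(recs3$outcome == "missing"))
})

test_that("accuracy implements (TP+TN)/(TP+TN+FP+FN)*100 with TN = 0", {
  recs <- data.frame(
    truth_id = 1:30,
    outcome = c(rep("correct", 28), "over_split", "over_connected"),
    stringsAsFactors = FALSE)
  expect_equal(accuracy(recs), 28 / 30 * 100, tolerance = 1e-12)
  expect_equal(accuracy(recs), 93.33333, tolerance = 1e-5)
  cnt <- pawseg:::outcome_counts(recs)
  expect_identical(cnt$TN, 0L)
  expect_identical(cnt$TP, 28L)
  expect_identical(cnt$FP, 1L)
  expect_identical(cnt$FN, 1L)
  all_ok <- data.frame(truth_id = 1:30, outcome = rep("correct", 30))
  expect_identical(accuracy(all_ok), 100)
  all_bad <- data.frame(truth_id = 1:4, outcome = rep("over_connected", 4))
  expect_identical(accuracy(all_bad), 0)
  expect_error(accuracy(data.frame()), "zero records")
  # missing counts as FN by default, excluded by flag
  with_miss <- data.frame(truth_id = 1:3,
                          outcome = c("correct", "correct", "missing"))
  expect_equal(accuracy(with_miss), 2 / 3 * 100)
  expect_equal(accuracy(with_miss, include_missing = FALSE), 100)
})

test_that("accuracy is order-invariant and strictly decreasing in errors", {
  set.seed(67)
  recs <- data.frame(truth_id = 1:12,
                     outcome = sample(c(rep("correct", 9), "over_split",
                                        "over_connected", "missing")))
  expect_equal(accuracy(recs), accuracy(recs[sample(12), ]))
  flip <- recs
  i <- which(flip$outcome == "correct")[1]
  flip$outcome[i] <- "over_connected"
  expect_lt(accuracy(flip), accuracy(recs))
})

test_that("classification agrees with a brute-force classifier on random maps", {
  brute <- function(pred, truth, overlap_min = 0.5) {
    tids <- setdiff(sort(unique(as.vector(truth))), 0L)
    pids <- setdiff(sort(unique(as.vector(pred))), 0L)
    cover <- list(); plur <- list()
    for (p in pids) {
      counts <- vapply(tids, function(t) sum(pred == p & truth == t), 0)
      plur[[as.character(p)]] <- if (all(counts == 0)) NA else tids[which.max(counts)]
    }
    out <- character(length(tids))
    cov_sets <- lapply(tids, function(t) {
      vol <- sum(truth == t)
      Filter(function(p) sum(pred == p & truth == t) / vol >= overlap_min, pids)
    })
    for (i in seq_along(tids)) {
      t <- tids[i]
      cov <- cov_sets[[i]]
      m <- Filter(function(p) identical(plur[[as.character(p)]], t), cov)
      shared <- length(cov) > 0 &&
        any(vapply(cov, function(p)
          sum(vapply(cov_sets, function(s) p %in% s, TRUE)) >= 2 ||
            !identical(plur[[as.character(p)]], t), TRUE))
      out[i] <- if (length(cov) == 0) "missing"
      else if (length(m) >= 2) "over_split"
      else if (shared) "over_connected"
      else "correct"
    }
    data.frame(truth_id = tids, outcome = out, stringsAsFactors = FALSE)
  }
  for (s in 1:6) {
    truth <- random_label_map(c(9, 9, 9), sample(3:6, 1), seed = 70 + s)
    pred <- random_label_map(c(9, 9, 9), sample(3:6, 1), seed = 170 + s)
    got <- classify_outcomes(match_labels(pred, truth, 0.5))
    want <- brute(pred, truth, 0.5)
    expect_identical(got$outcome, want$outcome[match(got$truth_id, want$truth_id)])
  }
})

test_that("compartment summary partitions the global counts", {
  recs <- data.frame(
    truth_id = 1:10,
    outcome = c(rep("correct", 4), "over_connected", "over_connected",
                rep("correct", 4)),
    stringsAsFactors = FALSE)
  tab <- bone_table(1:10,
                    compartment = c(rep("tarsal_carpal", 6),
                                    rep("distal_phalanx", 4)))
  cs <- compartment_summary(recs, tab)
  expect_identical(sort(cs$compartment), sort(c("tarsal_carpal", "distal_phalanx")))
  expect_equal(cs$accuracy[cs$compartment == "tarsal_carpal"], 4 / 6 * 100)
  expect_equal(cs$accuracy[cs$compartment == "distal_phalanx"], 100)
  expect_identical(sum(cs$TP), 8L)
  expect_identical(sum(cs$FN), 2L)
  expect_true(all(cs$accuracy >= 0 & cs$accuracy <= 100))
  # all-correct -> every compartment 100
  ok <- recs; ok$outcome <- "correct"
  expect_true(all(compartment_summary(ok, tab)$accuracy == 100))
  expect_error(compartment_summary(recs, bone_table(1:9)), "missing from")
})

test_that("fusion registers as over_connected and erosion as missing", {
  ph <- generate_phantom(phantom_spec(seed = 115, fusion_pairs = list(c(11L, 12L))))
  run <- run_pipeline(ph$volume)
  rep <- segmentation_report(run$labels, ph$truth, ph$table)
  expect_identical(rep$records$outcome[rep$records$truth_id %in% c(11L, 12L)],
                   c("over_connected", "over_connected"))
  ph2 <- generate_phantom(phantom_spec(seed = 116, missing_bones = 5L))
  run2 <- run_pipeline(ph2$volume)
  rep2 <- segmentation_report(run2$labels, ph2$truth, ph2$table)
  expect_identical(rep2$records$outcome[rep2$records$truth_id == 5L], "missing")
})

test_that("report export writes records, summary and compartments", {
  t <- random_label_map(c(8, 8, 8), 4, seed = 91)
  rep <- segmentation_report(t, t, bone_table(sort(unique(t[t > 0]))))
  pre <- tempfile("rep")
  paths <- export_report(rep, pre)
  expect_true(all(file.exists(c(paste0(pre, "_records.csv"),
                                paste0(pre, "_summary.json"),
                                paste0(pre, "_compartments.csv")))))
  js <- jsonlite::read_json(paste0(pre, "_summary.json"))
  expect_equal(js$accuracy, 100)
})

test_that("report aggregation offers averaged and pooled conventions", {
  mk <- function(n_ok, n_err) {
    recs <- data.frame(truth_id = seq_len(n_ok + n_err),
                       outcome = c(rep("correct", n_ok),
                                   rep("over_connected", n_err)))
    structure(list(records = recs, counts = pawseg:::outcome_counts(recs),
                   accuracy = accuracy(recs), compartments = NULL),
              class = "segmentation_report")
  }
  agg <- aggregate_reports(list(mk(10, 0), mk(5, 5)))
  expect_equal(agg$average, mean(c(100, 50)))
  expect_equal(agg$pooled, 15 / 20 * 100)
  expect_identical(agg$n_datasets, 2L)
  expect_identical(agg$n_bones, 20L)
})
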