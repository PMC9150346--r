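# Cross-validation harness and metrics.  Per evaluated protein the predicted
# term set is compared with its held-out known set over the filtered GO-term
# universe; aggregate metrics are unweighted (macro) means over evaluated
# proteins.  The ROC is a prediction-depth sweep: at depth d each protein is
# annotated with its top-d ranked terms and mean TPR / mean FPR are traced;
# the AUROC integrates the curve as drawn (no extrapolation to (1,1), so the
# area of a partial curve can be well below 0.5).

#' Score one prediction against the known term set
#'
#' `TP` are predicted terms present in the known set, `FP` predicted terms
#' absent from it, `FN` known terms missed.  `TN` counts the rest of the
#' filtered term universe, the only consistent finite negative background:
#' `TN = universe_size - |known u predicted|`.  Precision is 0 for an empty
#' prediction; the F-score is the harmonic mean of precision and recall
#' (0 when both are 0).
#'
#' @param predicted character vector of predicted terms.
#' @param known character vector of known terms (non-empty).
#' @param universe_size size of the filtered GO-term universe.
#' @return one-row data frame `tp, fp, fn, tn, precision, tpr, fpr, f_score`.
#' @export
score_prediction <- function(predicted, known, universe_size) {
  predicted <- unique(as.character(predicted))
  known <- unique(as.character(known))
  stopifnot(length(known) >= 1)
  tp <- length(intersect(predicted, known))
  fp <- length(predicted) - tp
  fn <- length(known) - tp
  tn <- universe_size - length(union(predicted, known))
  precision <- if (length(predicted)) tp / length(predicted) else 0
  tpr <- tp / length(known)
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  f <- if (precision + tpr > 0) {
    2 * precision * tpr / (precision + tpr)
  } else 0
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
             tpr = tpr, fpr = fpr, f_score = f)
}

#' Matching statistics over a set of evaluated proteins
#'
#' * `OM` -- proteins with at least one matched function (`TP >= 1`);
#' * `FM` -- proteins whose known functions are fully covered
#'   (`known` a subset of `predicted`);
#' * `ZM` -- proteins with no mismatching prediction (`predicted` a
#'   non-empty subset of `known`);
#' * `PM` -- proteins whose prediction equals the known set exactly.
#'
#' @param predicted_sets list of predicted term sets.
#' @param known_sets list of known term sets (same length).
#' @return named integer vector `OM, FM, ZM, PM`.
#' @export
matching_stats <- function(predicted_sets, known_sets) {
  stopifnot(length(predicted_sets) == length(known_sets))
  om <- fm <- zm <- pm <- 0L
  for (k in seq_along(known_sets)) {
    p <- unique(predicted_sets[[k]]); g <- unique(known_sets[[k]])
    if (length(intersect(p, g)) >= 1) om <- om + 1L
    if (all(g %in% p)) fm <- fm + 1L
    if (length(p) >= 1 && all(p %in% g)) zm <- zm + 1L
    if (setequal(p, g) && length(p) >= 1) pm <- pm + 1L
  }
  c(OM = om, FM = fm, ZM = zm, PM = pm)
}

.roc_points <- function(rankings, known_sets, universe_size) {
  depths <- 0:max(c(0L, lengths(rankings)))
  pts <- t(vapply(depths, function(d) {
    m <- vapply(seq_along(rankings), function(k) {
      s <- score_prediction(head(rankings[[k]], d), known_sets[[k]],
                            universe_size)
      c(s$tpr, s$fpr)
    }, numeric(2))
    c(depth = d, tpr = mean(m[1, ]), fpr = mean(m[2, ]))
  }, numeric(3)))
  pts <- as.data.frame(pts)
  auroc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auroc = auroc)
}

#' ROC curve of an evaluation by prediction-depth sweep
#'
#' @param report an `rwrt_eval` from [loocv()] or [tenfold_cv()].
#' @return list with `points` (`depth`, mean `tpr`, mean `fpr`) and `auroc`
#'   (trapezoidal area under the swept curve as drawn).
#' @export
roc_curve <- function(report) {
  .roc_points(report$rankings, report$known_sets, report$universe_size)
}

.eval_one <- function(i, M, ann_masked, ann_truth, cfg) {
  pred <- suppressMessages(predict_functions(i, M, ann_masked, cfg))
  known <- ann_truth$terms_of[[i]]
  row <- score_prediction(pred$predicted, known, length(ann_truth$terms))
  list(row = cbind(data.frame(protein = i, n_known = length(known)), row),
       predicted = pred$predicted, known = known, ranking = pred$ranked$term)
}

.summarise_eval <- function(rows, predicted_sets, known_sets, rankings,
                            universe_size, mode) {
  per_protein <- do.call(rbind, rows)
  summary <- colMeans(per_protein[, c("precision", "tpr", "fpr", "f_score")])
  roc <- .roc_points(rankings, known_sets, universe_size)
  structure(list(mode = mode, per_protein = per_protein, summary = summary,
                 matching = matching_stats(predicted_sets, known_sets),
                 roc = roc$points, auroc = roc$auroc,
                 predicted_sets = predicted_sets, known_sets = known_sets,
                 rankings = rankings, universe_size = universe_size),
            class = "rwrt_eval")
}

#' Leave-one-out cross-validation
#'
#' Each annotated protein in turn is held out: its annotations are masked
#' (network, domain and complex data remain visible), its functions are
#' re-predicted from the remaining proteins, and the prediction is scored
#' against the held-out set.  The similarity matrix does not depend on
#' annotations, so it is computed once.
#'
#' @param dataset an [rwrt_dataset()] with annotations.
#' @param cfg a [walk_config()].
#' @param tensor optional prebuilt [similarity_tensor()] (e.g. the
#'   [single_network_baseline()]).
#' @param M optional precomputed similarity matrix, to share across harness
#'   runs.
#' @return an object of class `rwrt_eval` with `per_protein` metrics,
#'   macro `summary` (`precision`, `tpr`, `fpr`, `f_score`), `matching`
#'   counts, the depth-swept `roc` and `auroc`, and the per-protein
#'   predicted/known sets.
#' @export
loocv <- function(dataset, cfg = walk_config(), tensor = NULL, M = NULL) {
  ann <- dataset$annotations
  stopifnot(!is.null(ann))
  targets <- annotated_proteins(ann)
  if (length(targets) < 2) stop("leave-one-out needs >= 2 annotated proteins")
  if (is.null(M)) M <- functional_similarity(dataset, cfg, tensor = tensor)
  out <- lapply(targets, function(i) {
    .eval_one(i, M, mask_annotations(ann, i), ann, cfg)
  })
  .summarise_eval(lapply(out, `[[`, "row"),
                  lapply(out, `[[`, "predicted"),
                  lapply(out, `[[`, "known"),
                  lapply(out, `[[`, "ranking"),
                  length(ann$terms), "loocv")
}

#' Ten-fold cross-validation
#'
#' Annotated proteins are randomly partitioned into ten folds
#' (reproducibly from `seed`); all annotations of a test fold are masked
#' simultaneously and each test protein is re-predicted from the training
#' folds.  Metrics are averaged over folds, and over repeats (repeat `r`
#' uses `seed + r - 1`), so a two-repeat report is the mean of the two
#' single-repeat reports.
#'
#' @param dataset an [rwrt_dataset()] with at least 10 annotated proteins.
#' @param cfg a [walk_config()].
#' @param seed integer seed for the fold assignment.
#' @param repeats number of repetitions (default 1).
#' @param tensor,M as in [loocv()].
#' @return an `rwrt_eval`; `summary`, `matching` and `auroc` are means over
#'   repeats, `per_protein` pools all repeats (with a `repeat.` column).
#' @export
tenfold_cv <- function(dataset, cfg = walk_config(), seed, repeats = 1L,
                       tensor = NULL, M = NULL) {
  ann <- dataset$annotations
  stopifnot(!is.null(ann))
  targets <- annotated_proteins(ann)
  if (length(targets) < 10) stop("ten-fold needs >= 10 annotated proteins")
  if (is.null(M)) M <- functional_similarity(dataset, cfg, tensor = tensor)
  reps <- lapply(seq_len(repeats), function(r) {
    set.seed(seed + r - 1L)
    fold <- sample(rep(seq_len(10L), length.out = length(targets)))
    out <- vector("list", length(targets))
    fold_means <- matrix(0, 10, 4)
    for (f in seq_len(10L)) {
      test <- targets[fold == f]
      ann_f <- mask_annotations(ann, test)
      res <- lapply(test, .eval_one, M = M, ann_masked = ann_f,
                    ann_truth = ann, cfg = cfg)
      out[fold == f] <- res
      rows <- do.call(rbind, lapply(res, `[[`, "row"))
      fold_means[f, ] <- colMeans(rows[, c("precision", "tpr", "fpr",
                                           "f_score")])
    }
    rep_eval <- .summarise_eval(lapply(out, `[[`, "row"),
                                lapply(out, `[[`, "predicted"),
                                lapply(out, `[[`, "known"),
                                lapply(out, `[[`, "ranking"),
                                length(ann$terms), "tenfold")
    rep_eval$summary <- setNames(colMeans(fold_means),
                                 c("precision", "tpr", "fpr", "f_score"))
    rep_eval
  })
  if (repeats == 1L) return(reps[[1]])
  pooled <- do.call(rbind, lapply(seq_along(reps), function(r) {
    cbind(data.frame(repeat. = r), reps[[r]]$per_protein)
  }))
  structure(list(mode = "tenfold", per_protein = pooled,
                 summary = colMeans(do.call(rbind,
                                            lapply(reps, `[[`, "summary"))),
                 matching = colMeans(do.call(rbind,
                                             lapply(reps, `[[`, "matching"))),
                 auroc = mean(vapply(reps, `[[`, numeric(1), "auroc")),
                 repeats = reps, universe_size = length(ann$terms)),
            class = "rwrt_eval")
}

#' @export
print.rwrt_eval <- function(x, ...) {
  cat("rwrt_eval (", x$mode, "): ",
      if (!is.null(x$per_protein)) nrow(x$per_protein) else 0,
      " evaluated predictions\n", sep = "")
  print(round(x$summary, 4))
  if (!is.null(x$auroc)) cat("AUROC (depth sweep):", round(x$auroc, 4), "\n")
  if (!is.null(x$matching)) {
    cat("matching:", paste(names(x$matching), round(x$matching, 1),
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Single-network ablation baseline
#'
#' Collapses the three tensor layers into one weighted network
#' `SN = a * physical + b * co-structure + (1 - a - b) * co-module`
#' and wraps it as a one-layer tensor, so the identical walk / annotation /
#' evaluation pipeline runs with `m = 1` (the layer-significance vector `Y`
#' is then degenerate at 1).
#'
#' @param tensor a three-layer [similarity_tensor()].
#' @param a,b layer weights, each in `(0, 1)` with `a + b < 1`
#'   (default `1/3` each: the unweighted mean).
#' @return a one-layer `similarity_tensor`.
#' @export
single_network_baseline <- function(tensor, a = 1 / 3, b = 1 / 3) {
  stopifnot(tensor$m == 3)
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1 || a + b >= 1) {
    stop("single-network weights require a, b in (0,1) and a + b < 1")
  }
  SN <- a * tensor$layers[[1]] + b * tensor$layers[[2]] +
    (1 - a - b) * tensor$layers[[3]]
  similarity_tensor(list(SN), "single", tensor$index)
}

#' Stratify evaluation metrics by functional size
#'
#' Buckets evaluated proteins by the size of their known term set and
#' reports per-bucket mean FPR and F-score; buckets with fewer than five
#' proteins are flagged as low-support (their means are not statistically
#' meaningful).
#'
#' @param report an `rwrt_eval` with a `per_protein` table.
#' @return data frame `n_known, n, mean_fpr, mean_f, low_support`.
#' @export
stratify_by_size <- function(report) {
  pp <- report$per_protein
  sp <- split(pp, pp$n_known)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(n_known = d$n_known[1], n = nrow(d),
               mean_fpr = mean(d$fpr), mean_f = mean(d$f_score))
  }))
  out$low_support <- out$n < 5
  rownames(out) <- NULL
  out[order(out$n_known), ]
}
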