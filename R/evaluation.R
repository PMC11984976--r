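#' Condition-level classification over all 160 conditions (Test 1)
#'
#' Leave-one-repetition-out cross-validation where the class is the full
#' (gesture, load, position) condition label, yielding a 160 x 160
#' confusion matrix in canonical condition order. Accuracy is the
#' diagonal mean after row normalization; the best and worst conditions
#' (max/min diagonal entries of the row-normalized matrix) are reported
#' with their labels.
#'
#' @param features Feature table of one participant
#'   ([featurize_session()]), containing all 160 conditions x 3
#'   repetitions.
#' @param modality `"emg"`, `"fmg"` or `"emg_fmg"`.
#' @param lambda LDA shrinkage.
#' @return List with `confusion` (160 x 160 counts), `accuracy_pct`,
#'   `best`/`worst` (condition label + per-class accuracy).
#' @export
test1_combined <- function(features, modality = c("emg", "fmg", "emg_fmg"),
                           lambda = 1e-3) {
  modality <- match.arg(modality)
  lev <- condition_levels()
  missing <- setdiff(lev, unique(features$condition))
  if (length(missing)) {
    stop("condition(s) missing from the feature table: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ...", call. = FALSE)
  }
  cv <- loro_cv(features, feature_names(modality), features$condition,
                label_levels = lev, lambda = lambda)
  diag_pct <- diag(normalize_confusion(cv$confusion))
  list(confusion = cv$confusion, accuracy_pct = cv$accuracy_pct,
       best = list(condition = lev[which.max(diag_pct)],
                   accuracy_pct = max(diag_pct)),
       worst = list(condition = lev[which.min(diag_pct)],
                    accuracy_pct = min(diag_pct)))
}

#' Gesture classification at the neutral condition vs under varying
#' conditions (Test 1)
#'
#' `neutral` restricts the windows to the unloaded neutral posture
#' (position 2, 0 g) and cross-validates the 4 gestures; `varying` pools
#' the windows of all 40 (load, position) combinations and cross-validates
#' the same 4 gestures, quantifying how much condition variability erodes
#' gesture separability.
#'
#' @inheritParams test1_combined
#' @param neutral_position,neutral_load_g Definition of the neutral
#'   condition.
#' @return List of two elements `neutral` and `varying`, each with a 4 x 4
#'   `confusion` and `accuracy_pct`.
#' @export
test1_neutral_vs_varying <- function(features,
                                     modality = c("emg", "fmg", "emg_fmg"),
                                     lambda = 1e-3,
                                     neutral_position = 2L,
                                     neutral_load_g = 0L) {
  modality <- match.arg(modality)
  cols <- feature_names(modality)
  neutral_rows <- features$position == neutral_position &
    features$load_g == neutral_load_g
  if (!any(neutral_rows)) {
    stop("no windows at the neutral condition (position ", neutral_position,
         ", ", neutral_load_g, " g)", call. = FALSE)
  }
  list(
    neutral = loro_cv(features[neutral_rows, , drop = FALSE], cols,
                      features$gesture[neutral_rows],
                      label_levels = GESTURES, lambda = lambda),
    varying = loro_cv(features, cols, features$gesture,
                      label_levels = GESTURES, lambda = lambda)
  )
}

#' Cross-condition transfer accuracy (Test 2)
#'
#' `constant_load`: at each load level, train a 4-gesture classifier on all
#' three repetitions at one position and test it at every other position
#' (8 x 7 train/test cells per load). `constant_position` mirrors the
#' design with positions and loads swapped (5 x 4 cells per position).
#' Train and test cells are disjoint conditions, so all repetitions are
#' used on both sides without leakage.
#'
#' @inheritParams test1_combined
#' @param mode `"constant_load"` or `"constant_position"`.
#' @return Data.frame with columns `constant_level`, `train_level`,
#'   `test_level`, `accuracy_pct`.
#' @export
test2_transfer <- function(features, modality = c("emg", "fmg", "emg_fmg"),
                           mode = c("constant_load", "constant_position"),
                           lambda = 1e-3) {
  modality <- match.arg(modality)
  mode <- match.arg(mode)
  cols <- feature_names(modality)
  if (mode == "constant_load") {
    const_vals <- sort(unique(features$load_g))
    vary_col <- "position"
    const_col <- "load_g"
  } else {
    const_vals <- sort(unique(features$position))
    vary_col <- "load_g"
    const_col <- "position"
  }
  out <- list()
  for (cv_ in const_vals) {
    sub <- features[features[[const_col]] == cv_, , drop = FALSE]
    vary_vals <- sort(unique(sub[[vary_col]]))
    for (tr in vary_vals) {
      train <- sub[sub[[vary_col]] == tr, , drop = FALSE]
      fit <- fit_lda(as.matrix(train[, cols, drop = FALSE]),
                     factor(train$gesture, levels = GESTURES),
                     lambda = lambda)
      for (te in setdiff(vary_vals, tr)) {
        test <- sub[sub[[vary_col]] == te, , drop = FALSE]
        pred <- predict(fit, as.matrix(test[, cols, drop = FALSE]))
        conf <- confusion_matrix(factor(test$gesture, levels = GESTURES),
                                 pred, GESTURES)
        out[[length(out) + 1L]] <- data.frame(
          constant_level = cv_, train_level = tr, test_level = te,
          accuracy_pct = accuracy(conf)
        )
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "mode") <- mode
  res
}

#' Extreme-condition transfer (Test 3)
#'
#' Trains the 4-gesture classifier at the unloaded neutral posture
#' (position 2, 0 g) and evaluates it at the four most extreme conditions:
#' neutral itself (via leave-one-repetition-out so the baseline is not
#' train-on-test), loaded (position 2, 1000 g), outstretched (position 5,
#' 0 g) and outstretched+loaded (position 5, 1000 g). The three
#' non-neutral conditions are disjoint from training, so their model uses
#' all three neutral repetitions.
#'
#' @inheritParams test1_combined
#' @return Named list of four accuracies (`neutral`, `loaded`,
#'   `outstretched`, `outstretched_loaded`), each in percent.
#' @export
test3_extremes <- function(features, modality = c("emg", "fmg", "emg_fmg"),
                           lambda = 1e-3) {
  modality <- match.arg(modality)
  cols <- feature_names(modality)
  cell <- function(p, l) {
    features[features$position == p & features$load_g == l, , drop = FALSE]
  }
  neutral <- cell(2L, 0L)
  if (!nrow(neutral)) stop("no windows at position 2, 0 g", call. = FALSE)
  fit <- fit_lda(as.matrix(neutral[, cols, drop = FALSE]),
                 factor(neutral$gesture, levels = GESTURES), lambda = lambda)
  eval_cell <- function(df) {
    pred <- predict(fit, as.matrix(df[, cols, drop = FALSE]))
    accuracy(confusion_matrix(factor(df$gesture, levels = GESTURES),
                              pred, GESTURES))
  }
  list(
    neutral = loro_cv(neutral, cols, neutral$gesture,
                      label_levels = GESTURES, lambda = lambda)$accuracy_pct,
    loaded = eval_cell(cell(2L, 1000L)),
    outstretched = eval_cell(cell(5L, 0L)),
    outstretched_loaded = eval_cell(cell(5L, 1000L))
  )
}

#' Run the evaluation designs for a cohort of feature tables
#'
#' @param feature_tables Named list of per-participant feature tables.
#' @param modalities Modalities to evaluate.
#' @param tests Integer subset of `c(1, 2, 3)`.
#' @param lambda LDA shrinkage.
#' @return A tidy data.frame of accuracy records with columns
#'   `participant_id`, `modality`, `scheme`, `train_condition`,
#'   `test_condition`, `accuracy_pct`. Schemes are `test1_combined`,
#'   `test1_neutral`, `test1_varying`, `test2_const_load`,
#'   `test2_const_pos` and `test3`.
#' @export
run_evaluation <- function(feature_tables,
                           modalities = c("emg", "fmg", "emg_fmg"),
                           tests = c(1, 2, 3), lambda = 1e-3) {
  if (!length(feature_tables)) stop("no feature tables given", call. = FALSE)
  recs <- list()
  add <- function(pid, mod, scheme, train, test, acc) {
    recs[[length(recs) + 1L]] <<- data.frame(
      participant_id = pid, modality = mod, scheme = scheme,
      train_condition = train, test_condition = test, accuracy_pct = acc,
      stringsAsFactors = FALSE
    )
  }
  for (pid in names(feature_tables)) {
    tbl <- feature_tables[[pid]]
    for (mod in modalities) {
      if (1 %in% tests) {
        t1 <- test1_combined(tbl, mod, lambda)
        add(pid, mod, "test1_combined", "all_conditions_cv",
            "all_conditions_cv", t1$accuracy_pct)
        nv <- test1_neutral_vs_varying(tbl, mod, lambda)
        add(pid, mod, "test1_neutral", "neutral_cv", "neutral_cv",
            nv$neutral$accuracy_pct)
        add(pid, mod, "test1_varying", "all_cv", "all_cv",
            nv$varying$accuracy_pct)
      }
      if (2 %in% tests) {
        for (mode in c("constant_load", "constant_position")) {
          tt <- test2_transfer(tbl, mod, mode, lambda)
          scheme <- if (mode == "constant_load") "test2_const_load"
                    else "test2_const_pos"
          for (j in seq_len(nrow(tt))) {
            add(pid, mod, scheme,
                paste0("const", tt$constant_level[j], "_train",
                       tt$train_level[j]),
                paste0("const", tt$constant_level[j], "_test",
                       tt$test_level[j]),
                tt$accuracy_pct[j])
          }
        }
      }
      if (3 %in% tests) {
        t3 <- test3_extremes(tbl, mod, lambda)
        for (cond in names(t3)) {
          add(pid, mod, "test3", "neutral", cond, t3[[cond]])
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Average row-normalized confusion matrices across participants
#'
#' @param confusions List of count `confusion_matrix` objects with
#'   identical labels.
#' @return Element-wise mean of the row-normalized (percentage) matrices.
#' @export
average_confusion <- function(confusions) {
  if (!length(confusions)) stop("no confusion matrices given", call. = FALSE)
  norm <- lapply(confusions, normalize_confusion)
  Reduce(`+`, norm) / length(norm)
}

#' Descriptive summaries of accuracy records
#'
#' Per scheme x modality: mean, sample SD, standard error SD/sqrt(n),
#' median and IQR (type-7 linear-interpolation quantiles). With a single
#' observation the SE and SD are reported as `NA`.
#'
#' @param records Accuracy records from [run_evaluation()].
#' @return Data.frame with one row per scheme x modality.
#' @export
summarize_accuracy <- function(records) {
  if (!nrow(records)) stop("no accuracy records given", call. = FALSE)
  groups <- split(records,
                  list(scheme = records$scheme, modality = records$modality),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    x <- g$accuracy_pct
    n <- length(x)
    data.frame(
      scheme = g$scheme[1], modality = g$modality[1], n = n,
      mean = mean(x),
      sd = if (n > 1L) stats::sd(x) else NA_real_,
      se = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
      median = stats::median(x),
      iqr = stats::IQR(x, type = 7),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scheme, res$modality), ]
}
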