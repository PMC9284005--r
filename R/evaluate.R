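# Classical baselines on hand-crafted features and the two evaluation
# protocols (within-subject 70/30 trial split with stratified 4-fold CV
# over the training portion; cross-subject 7-train/3-test subjects
# repeated five times). Accuracy is per window; windows of one trial
# never straddle a train/test boundary.

#' Evaluation protocol specification
#'
#' @param mode `"within_subject"` or `"cross_subject"`.
#' @param train_ratio fraction of each subject's trials used for
#'   training (within-subject).
#' @param cv_folds stratified folds over the training trials
#'   (within-subject model selection / stopping).
#' @param n_train_subjects,n_test_subjects subject counts per
#'   cross-subject repeat.
#' @param n_repeats cross-subject repeats.
#' @param seed protocol seed (splits, repeats, baseline RNG).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("within_subject", "cross_subject"),
                          train_ratio = 0.7, cv_folds = 4L,
                          n_train_subjects = 7L, n_test_subjects = 3L,
                          n_repeats = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (train_ratio <= 0 || train_ratio >= 1) stopf("train_ratio must be in (0,1)")
  structure(list(mode = mode, train_ratio = train_ratio,
                 cv_folds = as.integer(cv_folds),
                 n_train_subjects = as.integer(n_train_subjects),
                 n_test_subjects = as.integer(n_test_subjects),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "protocol_spec")
}

## ---- baselines -----------------------------------------------------------

#' Fit a classical baseline classifier
#'
#' All baselines consume the same hand-crafted features as the fused
#' model. Features are standardized internally with training statistics
#' (applied again at prediction). Stochastic learners (RF) are seeded.
#'
#' @param kind one of `"lda"`, `"rbfsvm"`, `"knn"`, `"rf"`
#'   (case-insensitive).
#' @param x numeric feature matrix (windows x features).
#' @param y labels (factor or character).
#' @param seed RNG seed for stochastic learners.
#' @param k neighbours for KNN.
#' @param cost,gamma RBF-SVM hyperparameters (`gamma = NULL` uses
#'   1/n_features on standardized data).
#' @param ntree random-forest size.
#' @return object of class `baseline_model` with a [predict()] method
#'   returning labels.
#' @export
fit_baseline <- function(kind, x, y, seed = 1L, k = 5L, cost = 1,
                         gamma = NULL, ntree = 100L) {
  kinds <- c("lda", "rbfsvm", "knn", "rf")
  kind <- tolower(kind)
  if (!kind %in% kinds)
    stopf("unknown baseline '%s'; valid kinds: %s", kind,
          paste(kinds, collapse = ", "))
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stopf("need at least 2 classes to fit a baseline")
  x <- as.matrix(x)
  st <- standardizer_fit(x)
  xs <- standardizer_apply(x, st)
  fit <- switch(kind,
    lda = MASS::lda(xs, grouping = y),
    rbfsvm = {
      if (is.null(gamma)) gamma <- 1 / ncol(xs)
      with_seed(seed, e1071::svm(xs, y, kernel = "radial", cost = cost,
                                 gamma = gamma))
    },
    knn = list(x = xs, y = y, k = as.integer(k)),
    rf = with_seed(seed, randomForest::randomForest(xs, y, ntree = ntree))
  )
  structure(list(kind = kind, fit = fit, st = st, levels = levels(y),
                 seed = as.integer(seed)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  xs <- standardizer_apply(as.matrix(newdata), object$st)
  out <- switch(object$kind,
    lda = as.character(predict(object$fit, xs)$class),
    rbfsvm = as.character(predict(object$fit, xs)),
    # KNN vote ties are broken by RNG; seed for reproducible reports
    knn = with_seed(object$seed,
                    as.character(class::knn(object$fit$x, xs, object$fit$y,
                                            k = object$fit$k))),
    rf = as.character(predict(object$fit, xs)))
  out
}

## ---- splits --------------------------------------------------------------

# unique trials of a window set with their subject and label
#' @noRd
trial_table <- function(ws) {
  unique(ws$meta[, c("subject_id", "source_trial", "label")])
}

#' @noRd
stratified_assign <- function(labels, k, rng_perm) {
  # round-robin fold assignment within each class after a seeded shuffle;
  # per-fold class counts differ by at most one
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[rng_perm(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Within-subject trial-level splits
#'
#' For every subject: a stratified 70/30 trial split (rounded to the
#' nearest trial; all windows of a trial stay together) plus a
#' label-stratified `cv_folds`-fold assignment of the training trials
#' for model selection / validation stopping.
#'
#' @param ws a `window_set` over the whole dataset.
#' @param spec a [protocol_spec()].
#' @return named list (one element per subject) of data.frames with
#'   columns `source_trial`, `label`, `role` (`"train"`/`"test"`) and
#'   `fold` (NA for test trials).
#' @export
split_within_subject <- function(ws, spec = protocol_spec()) {
  trials <- trial_table(ws)
  seeds <- derive_seeds(spec$seed, length(unique(trials$subject_id)))
  subjects <- sort(unique(trials$subject_id))
  out <- list()
  for (s in seq_along(subjects)) {
    tt <- trials[trials$subject_id == subjects[s], , drop = FALSE]
    cls_counts <- table(tt$label)
    if (any(cls_counts < spec$cv_folds))
      stopf("subject %s has a class with %d trials; need >= %d per class",
            subjects[s], min(cls_counts), spec$cv_folds)
    with_seed(seeds[s], {
      role <- rep("test", nrow(tt))
      for (cl in unique(tt$label)) {
        idx <- which(tt$label == cl)
        n_tr <- round(spec$train_ratio * length(idx))
        role[sample(idx, n_tr)] <- "train"
      }
      fold <- rep(NA_integer_, nrow(tt))
      tr <- which(role == "train")
      fold[tr] <- stratified_assign(tt$label[tr], spec$cv_folds, sample.int)
      out[[subjects[s]]] <- data.frame(
        source_trial = tt$source_trial, label = tt$label,
        role = role, fold = fold, stringsAsFactors = FALSE)
    })
  }
  out
}

#' Cross-subject repeated subject-level partitions
#'
#' Five seeded repeats (by default), each assigning 7 training and 3
#' test subjects with no overlap; different repeats draw different
#' partitions.
#'
#' @param subject_ids character vector of available subjects.
#' @param spec a [protocol_spec()].
#' @return list of length `n_repeats`, each with `train` and `test`
#'   subject vectors.
#' @export
split_cross_subject <- function(subject_ids, spec = protocol_spec(mode = "cross_subject")) {
  subjects <- sort(unique(subject_ids))
  need <- spec$n_train_subjects + spec$n_test_subjects
  if (length(subjects) < need)
    stopf("need at least %d subjects, got %d", need, length(subjects))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_repeats), function(r) {
      test <- sample(subjects, spec$n_test_subjects)
      train <- sample(setdiff(subjects, test), spec$n_train_subjects)
      list(train = train, test = test)
    })
  })
}

## ---- protocol runner -----------------------------------------------------

#' @noRd
confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, classes), factor(pred, classes), dnn = c("truth", "pred"))
}

# carve a trial-grouped stratified validation subset out of training trials
#' @noRd
carve_validation <- function(trials, frac, seed) {
  with_seed(seed, {
    val <- logical(nrow(trials))
    for (cl in unique(trials$label)) {
      idx <- which(trials$label == cl)
      n_val <- max(1L, round(frac * length(idx)))
      val[sample(idx, n_val)] <- TRUE
    }
    val
  })
}

#' @noRd
ws_for_trials <- function(ws, subjects, trials = NULL) {
  sel <- ws$meta$subject_id %in% subjects
  if (!is.null(trials))
    sel <- sel & paste(ws$meta$subject_id, ws$meta$source_trial) %in%
      paste(trials$subject_id, trials$source_trial)
  subset_windows(ws, which(sel))
}

#' @noRd
fit_and_score <- function(model_name, tr_ws, va_ws, te_ws, Xcache, spec,
                          model_cfg, train_cfg, feature_cfg, classes) {
  key <- function(w) paste(w$meta$subject_id, w$meta$source_trial,
                           w$meta$start_sample)
  if (model_name == "hcsnet") {
    tc <- train_cfg; tc$seed <- spec$seed
    fit <- train_hcsnet(tr_ws, va_ws, model_cfg, tc, feature_cfg)
    pred <- predict_hcsnet(fit, te_ws)$label
  } else {
    xi <- match(key(tr_ws), Xcache$key); xv <- match(key(va_ws), Xcache$key)
    xt <- match(key(te_ws), Xcache$key)
    xtr <- rbind(Xcache$X[xi, , drop = FALSE], Xcache$X[xv, , drop = FALSE])
    ytr <- c(tr_ws$meta$label, va_ws$meta$label)
    fit <- fit_baseline(model_name, xtr, ytr, seed = spec$seed)
    pred <- predict(fit, Xcache$X[xt, , drop = FALSE])
  }
  truth <- te_ws$meta$label
  list(accuracy = mean(pred == truth),
       confusion = confusion_matrix(truth, pred, classes))
}

#' Run an evaluation protocol over a set of models
#'
#' Every model sees identical trial-level splits. For the fused model a
#' trial-grouped stratified 20% of the training trials is held out as
#' the validation-stopping set; baselines train on all training trials.
#' Accuracy is computed per window.
#'
#' @param ws preprocessed `window_set` over the whole dataset.
#' @param models character vector among
#'   `c("hcsnet", "lda", "rbfsvm", "knn", "rf")`.
#' @param spec a [protocol_spec()].
#' @param model_cfg,train_cfg,feature_cfg configurations forwarded to
#'   [train_hcsnet()] / [handcrafted_features()].
#' @param paper_protocol cross-subject only: if `TRUE`, the held-out
#'   test subjects also serve as the validation-stopping set (the
#'   literal protocol of the original design); the default `FALSE`
#'   carves the stopping set from the training subjects (no leakage).
#' @return object of class `evaluation_report`: `per_unit` accuracies
#'   (per subject or per repeat and model), `mean_accuracy` per model,
#'   `confusions`, the spec and seed.
#' @export
run_protocol <- function(ws, models = c("hcsnet", "lda", "rbfsvm", "knn", "rf"),
                         spec = protocol_spec(),
                         model_cfg = mcsnet_config(),
                         train_cfg = train_config(),
                         feature_cfg = feature_config(),
                         paper_protocol = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  models <- tolower(models)
  classes <- sort(unique(ws$meta$label))
  fc <- feature_cfg; fc$fs_hz <- ws$fs_hz
  X <- handcrafted_features(ws, fc)
  Xcache <- list(X = X,
                 key = paste(ws$meta$subject_id, ws$meta$source_trial,
                             ws$meta$start_sample))
  rows <- list(); confusions <- list()

  if (spec$mode == "within_subject") {
    splits <- split_within_subject(ws, spec)
    for (sid in names(splits)) {
      sp <- sp_all <- splits[[sid]]
      sp_all$subject_id <- sid
      tr <- sp_all[sp_all$role == "train", ]
      te <- sp_all[sp_all$role == "test", ]
      val_mask <- carve_validation(tr, 0.2, spec$seed + match(sid, names(splits)))
      tr_ws <- ws_for_trials(ws, sid, tr[!val_mask, ])
      va_ws <- ws_for_trials(ws, sid, tr[val_mask, ])
      te_ws <- ws_for_trials(ws, sid, te)
      for (m in models) {
        res <- tryCatch(
          fit_and_score(m, tr_ws, va_ws, te_ws, Xcache, spec,
                        model_cfg, train_cfg, fc, classes),
          error = function(e) stopf("model '%s' failed on subject %s: %s",
                                    m, sid, conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          unit = sid, model = m, accuracy = res$accuracy,
          stringsAsFactors = FALSE)
        confusions[[paste(m, sid, sep = ":")]] <- res$confusion
      }
    }
  } else {
    reps <- split_cross_subject(unique(ws$meta$subject_id), spec)
    for (r in seq_along(reps)) {
      tr_subj <- reps[[r]]$train; te_subj <- reps[[r]]$test
      te_ws <- ws_for_trials(ws, te_subj)
      tr_trials <- trial_table(ws_for_trials(ws, tr_subj))
      if (paper_protocol) {
        tr_ws <- ws_for_trials(ws, tr_subj)
        va_ws <- te_ws
      } else {
        val_mask <- carve_validation(tr_trials, 0.2, spec$seed + r)
        tr_ws <- ws_for_trials(ws, tr_subj, tr_trials[!val_mask, ])
        va_ws <- ws_for_trials(ws, tr_subj, tr_trials[val_mask, ])
      }
      for (m in models) {
        res <- tryCatch(
          fit_and_score(m, tr_ws, va_ws, te_ws, Xcache, spec,
                        model_cfg, train_cfg, fc, classes),
          error = function(e) stopf("model '%s' failed on repeat %d: %s",
                                    m, r, conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          unit = paste0("repeat", r), model = m, accuracy = res$accuracy,
          stringsAsFactors = FALSE)
        confusions[[paste(m, r, sep = ":")]] <- res$confusion
      }
    }
  }
  per_unit <- do.call(rbind, rows)
  mean_acc <- tapply(per_unit$accuracy, per_unit$model, mean)
  structure(list(per_unit = per_unit,
                 mean_accuracy = mean_acc[unique(per_unit$model)],
                 confusions = confusions, spec = spec, seed = spec$seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (seed %d)\n", x$spec$mode, x$seed))
  for (m in names(x$mean_accuracy))
    cat(sprintf("  %-8s mean accuracy %.4f\n", m, x$mean_accuracy[m]))
  invisible(x)
}

#' Sliding-window parameter sweep
#'
#' Re-windows the movement segments over a grid of window lengths and
#' step fractions, runs the within-subject protocol with the RBF-SVM
#' baseline on hand-crafted features, and tabulates mean accuracy per
#' grid cell.
#'
#' @param recordings list of [raw_recording()] (raw trials).
#' @param window_lengths integer vector of window lengths (samples).
#' @param step_fractions numeric vector of step sizes as fractions of
#'   the window length.
#' @param spec a within-subject [protocol_spec()].
#' @param cfg base [preprocess_config()] (its window fields are swept).
#' @return data.frame with columns `window_len`, `step_fraction`,
#'   `step`, `mean_accuracy`.
#' @export
window_sweep <- function(recordings, window_lengths = c(75L, 150L, 300L),
                         step_fractions = c(0.25, 0.5),
                         spec = protocol_spec(), cfg = preprocess_config()) {
  seg_len <- round(cfg$keep_duration_s * recordings[[1]]$fs_hz)
  if (any(window_lengths > seg_len))
    stopf("window length exceeds segment length %d", seg_len)
  if (any(step_fractions <= 0 | step_fractions > 1))
    stopf("step fractions must be in (0, 1]")
  out <- list()
  for (len in window_lengths) for (fr in step_fractions) {
    c2 <- cfg
    c2$window_len <- as.integer(len)
    c2$window_step <- max(1L, as.integer(round(len * fr)))
    ws <- preprocess_dataset(recordings, c2)
    rep <- run_protocol(ws, models = "rbfsvm", spec = spec)
    out[[length(out) + 1L]] <- data.frame(
      window_len = len, step_fraction = fr, step = c2$window_step,
      mean_accuracy = unname(rep$mean_accuracy["rbfsvm"]))
  }
  do.call(rbind, out)
}
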