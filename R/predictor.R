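#' Build a per-site training dataset
#'
#' For one genome site, the design matrix is the binary condition encoding of
#' every merged condition (unique strain/medium/stress combination) and the
#' label is whether the merged profile carries a mutation at the site. Sites
#' mutated under fewer than `inclusion_min_conditions` conditions (default:
#' at least 3, i.e. "more than two") are excluded and `NULL` is returned.
#'
#' @param compendium a `compendium`.
#' @param site canonical site name.
#' @param inclusion_min_conditions minimum positive conditions for inclusion.
#' @param profiles optional precomputed [build_condition_profiles()] result
#'   (saves recomputation when looping over sites).
#' @param vocabulary optional precomputed [condition_vocabulary()].
#' @return object of class `site_dataset` (list with `site`, `X`, `y`,
#'   `condition_keys`), or `NULL` when the site fails inclusion.
#' @export
build_site_dataset <- function(compendium, site, inclusion_min_conditions = 3L,
                               profiles = NULL, vocabulary = NULL) {
  stopifnot(inherits(compendium, "compendium"))
  profiles <- profiles %||% build_condition_profiles(compendium)
  if (!site %in% colnames(profiles$matrix)) stopf("unknown site: '%s'", site)
  vocabulary <- vocabulary %||% condition_vocabulary(compendium$conditions)
  y <- profiles$matrix[, site]
  if (sum(y) < inclusion_min_conditions) return(NULL)
  X <- t(vapply(seq_len(nrow(profiles$keys)), function(i) {
    k <- profiles$keys[i, ]
    encode_condition(list(strain = k$strain, medium = k$medium,
                          stresses = split_stresses(k$stresses)[[1]],
                          generations = k$generations), vocabulary)
  }, numeric(length(vocabulary$strains) + length(vocabulary$media) +
       length(vocabulary$stresses) + 7L)))
  rownames(X) <- profiles$keys$key
  new_site_dataset(site, X, unname(y), profiles$keys$key)
}

new_site_dataset <- function(site, X, y, condition_keys) {
  structure(list(site = site, X = as.matrix(X), y = as.integer(y),
                 condition_keys = condition_keys),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("site_dataset[%s]: %d conditions x %d attributes, %d positives\n",
              x$site, nrow(x$X), ncol(x$X), sum(x$y)))
  invisible(x)
}

#' Balance a site dataset by oversampling the minority class
#'
#' Minority rows are duplicated uniformly at random (with replacement) until
#' the class counts are equal. Balanced input is returned unchanged. Seeded.
#'
#' @param dataset a `site_dataset`.
#' @param seed RNG seed.
#' @return a balanced `site_dataset`.
#' @export
oversample <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "site_dataset"))
  y <- dataset$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("single-class dataset cannot be balanced")
  if (n1 == n0) return(dataset)
  minority <- if (n1 < n0) which(y == 1L) else which(y == 0L)
  extra <- local_seed(seed, sample(minority, abs(n0 - n1), replace = TRUE))
  idx <- c(seq_along(y), extra)
  new_site_dataset(dataset$site, dataset$X[idx, , drop = FALSE], y[idx],
                   dataset$condition_keys[idx])
}

## ---- component models -------------------------------------------------

#' Bernoulli naive Bayes with Laplace smoothing
#'
#' Per-feature conditional probabilities are estimated as
#' `(count + alpha) / (class count + 2 alpha)`, so no parameter is ever
#' exactly 0 or 1 and predictive probabilities stay strictly inside (0, 1).
#'
#' @param dataset a `site_dataset` (binary features).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return object of class `nb_model`.
#' @export
train_naive_bayes <- function(dataset, alpha = 1) {
  stopifnot(inherits(dataset, "site_dataset"))
  X <- dataset$X; y <- dataset$y
  if (length(unique(y)) < 2L)
    stopf("single-class dataset: oversample or skip this site")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  p1 <- (colSums(X[y == 1L, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  p0 <- (colSums(X[y == 0L, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  structure(list(prior1 = n1 / (n1 + n0), p1 = p1, p0 = p0, alpha = alpha,
                 feature_names = colnames(X)),
            class = "nb_model")
}

#' Predicted mutation probability from a component or ensemble model
#'
#' @param model a trained `nb_model`, `svm_model`, `ann_model` or
#'   `ensemble_model`.
#' @param X feature matrix or single feature vector.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.nb_model <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  ll1 <- X %*% log(model$p1) + (1 - X) %*% log(1 - model$p1) + log(model$prior1)
  ll0 <- X %*% log(model$p0) + (1 - X) %*% log(1 - model$p0) + log(1 - model$prior1)
  as.numeric(1 / (1 + exp(ll0 - ll1)))
}

#' RBF-kernel support vector machine with grid search
#'
#' Fits an RBF SVM over the grid of misclassification penalties `c` and
#' kernel widths `sigma`, choosing the pair with the best inner stratified
#' 3-fold cross-validated AUC (ties resolved in grid order for determinism).
#' Probabilities are obtained by a Platt-style logistic calibration of the
#' decision values, fitted on the training data.
#'
#' @param dataset a `site_dataset`.
#' @param c_grid penalty grid (default `c(0.001, 0.01, 0.1, 1, 10)`).
#' @param sigma_grid kernel width grid (default `c(0.001, 0.01, 0.1, 1)`).
#' @param seed RNG seed (controls the inner folds).
#' @return object of class `svm_model` with elements `fit`, `calibration`,
#'   `c`, `sigma`.
#' @export
train_svm <- function(dataset, c_grid = c(0.001, 0.01, 0.1, 1, 10),
                      sigma_grid = c(0.001, 0.01, 0.1, 1), seed = 1) {
  stopifnot(inherits(dataset, "site_dataset"))
  X <- dataset$X; y <- dataset$y
  if (length(unique(y)) < 2L) stopf("single-class dataset: oversample or skip this site")
  grid <- expand.grid(c = c_grid, sigma = sigma_grid, KEEP.OUT.ATTRS = FALSE)
  best <- c(auc = -Inf, row = 1L)
  if (nrow(grid) > 1L) {
    folds <- stratified_folds(y, k = 3, seed = seed)
    for (i in seq_len(nrow(grid))) {
      preds <- rep(NA_real_, length(y))
      ok <- TRUE
      for (f in unique(folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
        m <- svm_fit(X[tr, , drop = FALSE], y[tr], grid$c[i], grid$sigma[i])
        preds[!tr] <- svm_decision(m, X[!tr, , drop = FALSE])
      }
      if (!ok || anyNA(preds)) next
      a <- auc_roc(preds, y)
      a <- max(a, 1 - a)  # decision-value orientation resolved by calibration
      if (a > best["auc"]) best <- c(auc = a, row = i)
    }
  }
  c_sel <- grid$c[best["row"]]; sigma_sel <- grid$sigma[best["row"]]
  fit <- svm_fit(X, y, c_sel, sigma_sel)
  dv <- svm_decision(fit, X)
  calibration <- suppressWarnings(glm(y ~ dv, family = binomial()))
  structure(list(fit = fit, calibration = calibration,
                 c = c_sel, sigma = sigma_sel, cv_auc = unname(best["auc"]),
                 feature_names = colnames(X)),
            class = "svm_model")
}

svm_fit <- function(X, y, cost, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)), scale = FALSE,
             kernel = "radial", cost = cost, gamma = gamma)
}

svm_decision <- function(fit, X) {
  p <- predict(fit, X, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

#' @export
predict_prob.svm_model <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  dv <- svm_decision(model$fit, X)
  unname(predict(model$calibration, newdata = data.frame(dv = dv), type = "response"))
}

#' @export
predict_prob.ann_model <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  net <- model$net
  as.numeric(mlp_forward(net, X, dropout = 0, training = FALSE)$A[[length(net$W) + 1L]])
}

## ---- cross-validation plumbing ----------------------------------------

## stratified k-fold assignment: positives and negatives dealt round-robin
## after a seeded shuffle
stratified_folds <- function(y, k = 3, seed = 1) {
  folds <- integer(length(y))
  local_seed(seed, {
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

## pooled cross-validated AUC of an arbitrary trainer; the training fold is
## oversampled when requested, the held-out fold never is
cv_auc_trainer <- function(X, y, trainer, k = 3, seed = 1, balance = TRUE) {
  folds <- stratified_folds(y, k = k, seed = seed)
  preds <- rep(NA_real_, length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) return(NA_real_)
    Xtr <- X[tr, , drop = FALSE]
    if (balance) {
      ds <- oversample(new_site_dataset("cv", Xtr, ytr, seq_len(sum(tr))),
                       seed = seed + f)
      Xtr <- ds$X; ytr <- ds$y
    }
    m <- trainer(Xtr, ytr)
    preds[!tr] <- predict_prob(m, X[!tr, , drop = FALSE])
  }
  auc_roc(preds, y)
}

component_trainer <- function(name, seed = 1, alpha = 1,
                              c_grid = c(0.001, 0.01, 0.1, 1, 10),
                              sigma_grid = c(0.001, 0.01, 0.1, 1),
                              ann_hidden = c(57, 37), ann_epochs = 200,
                              ann_dropout = 0.4) {
  switch(name,
    nb = function(X, y) train_naive_bayes(new_site_dataset("tmp", X, y, seq_along(y)), alpha = alpha),
    svm = function(X, y) train_svm(new_site_dataset("tmp", X, y, seq_along(y)),
                                   c_grid = c_grid, sigma_grid = sigma_grid, seed = seed),
    ann = function(X, y) train_ann(X, y, hidden = ann_hidden, dropout = ann_dropout,
                                   epochs = ann_epochs, seed = seed),
    stopf("unknown component trainer '%s'", name))
}

#' Stepwise backward wrapper feature selection
#'
#' Starts from the full attribute set and greedily removes the feature whose
#' removal best improves (or at worst preserves) the inner cross-validated
#' AUC of the supplied component trainer; the loop stops when every removal
#' would decrease performance, and never returns an empty subset. Ties among
#' candidate removals are broken by the lowest feature index.
#'
#' @param dataset a `site_dataset`.
#' @param trainer `"nb"`, `"svm"`, `"ann"`, or a function `(X, y) -> model`
#'   answering [predict_prob()].
#' @param k inner folds (default 3).
#' @param seed RNG seed.
#' @return integer vector of retained feature indices (named by attribute).
#' @export
select_features_backward <- function(dataset, trainer = "nb", k = 3, seed = 1) {
  stopifnot(inherits(dataset, "site_dataset"))
  if (ncol(dataset$X) < 2L) stopf("need at least 2 features")
  fit <- if (is.function(trainer)) trainer else component_trainer(trainer, seed = seed)
  score <- function(subset) {
    cv_auc_trainer(dataset$X[, subset, drop = FALSE], dataset$y, fit,
                   k = k, seed = seed)
  }
  current <- seq_len(ncol(dataset$X))
  current_score <- score(current)
  repeat {
    if (length(current) == 1L) break
    cand_scores <- vapply(seq_along(current),
                          function(j) score(current[-j]), numeric(1))
    best_j <- which.max(cand_scores)  # first maximum = lowest index tie-break
    if (is.na(cand_scores[best_j]) || cand_scores[best_j] < current_score) break
    current_score <- cand_scores[best_j]
    current <- current[-best_j]
  }
  names(current) <- colnames(dataset$X)[current]
  current
}

## ---- ensemble ----------------------------------------------------------

#' Train the three-component ensemble for one genome site
#'
#' Trains a naive Bayes classifier, an RBF SVM (grid-searched) and a small
#' feedforward neural network on the (optionally feature-selected and
#' oversampled) site dataset. The ensemble prediction is the plain average
#' of the three component probabilities.
#'
#' @param dataset a `site_dataset`.
#' @param seed RNG seed (drives oversampling, folds and the ANN init).
#' @param feature_select `"backward"` (wrapper selection, default) or
#'   `"none"`.
#' @param fs_trainer component used to score subsets during selection
#'   (default `"nb"`, the fastest; see [select_features_backward()]).
#' @param fs_per_component run the wrapper once per component instead of
#'   sharing one subset.
#' @param alpha,c_grid,sigma_grid,ann_hidden,ann_epochs,ann_dropout component
#'   hyperparameters.
#' @param balance oversample the training data to class balance.
#' @return object of class `ensemble_model` with the three components, their
#'   feature subsets and equal weights 1/3.
#' @export
train_ensemble <- function(dataset, seed = 1,
                           feature_select = c("backward", "none"),
                           fs_trainer = "nb", fs_per_component = FALSE,
                           alpha = 1,
                           c_grid = c(0.001, 0.01, 0.1, 1, 10),
                           sigma_grid = c(0.001, 0.01, 0.1, 1),
                           ann_hidden = c(57, 37), ann_epochs = 200,
                           ann_dropout = 0.4, balance = TRUE) {
  stopifnot(inherits(dataset, "site_dataset"))
  feature_select <- match.arg(feature_select)
  if (length(unique(dataset$y)) < 2L)
    stopf("site '%s' has a single class; cannot train", dataset$site)
  comp_names <- c("nb", "svm", "ann")
  features <- if (feature_select == "none") {
    all <- setNames(seq_len(ncol(dataset$X)), colnames(dataset$X))
    list(nb = all, svm = all, ann = all)
  } else if (fs_per_component) {
    setNames(lapply(comp_names, function(nm) {
      tr <- component_trainer(nm, seed = seed, alpha = alpha,
                              c_grid = c_grid, sigma_grid = sigma_grid,
                              ann_hidden = ann_hidden, ann_epochs = ann_epochs,
                              ann_dropout = ann_dropout)
      select_features_backward(dataset, tr, seed = seed)
    }), comp_names)
  } else {
    shared <- select_features_backward(dataset, fs_trainer, seed = seed)
    list(nb = shared, svm = shared, ann = shared)
  }
  ds <- if (balance) oversample(dataset, seed = seed) else dataset
  sub <- function(ix) new_site_dataset(ds$site, ds$X[, ix, drop = FALSE],
                                       ds$y, ds$condition_keys)
  nb <- train_naive_bayes(sub(features$nb), alpha = alpha)
  svm <- train_svm(sub(features$svm), c_grid = c_grid,
                   sigma_grid = sigma_grid, seed = seed)
  ann <- train_ann(ds$X[, features$ann, drop = FALSE], ds$y,
                   hidden = ann_hidden, dropout = ann_dropout,
                   epochs = ann_epochs, seed = seed)
  structure(list(site = dataset$site, nb = nb, svm = svm, ann = ann,
                 features = features, weights = rep(1 / 3, 3),
                 n_attributes = ncol(dataset$X),
                 attribute_names = colnames(dataset$X)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model[%s]: NB + SVM(c=%g, sigma=%g) + ANN(%s), %d/%d attributes\n",
              x$site, x$svm$c, x$svm$sigma, paste(x$ann$hidden, collapse = "-"),
              length(unique(unlist(x$features))), x$n_attributes))
  invisible(x)
}

#' Ensemble mutation probability for a condition vector
#'
#' The emitted probability is exactly the arithmetic mean of the naive
#' Bayes, SVM and neural-network probabilities.
#'
#' @param model an `ensemble_model`.
#' @param condition_vector binary attribute vector (or matrix of rows) of the
#'   full vocabulary length used in training.
#' @param components also return the per-component probabilities.
#' @return numeric probability vector, or a data.frame when
#'   `components = TRUE`.
#' @export
ensemble_predict <- function(model, condition_vector, components = FALSE) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- if (is.matrix(condition_vector)) condition_vector else matrix(condition_vector, nrow = 1)
  if (ncol(X) != model$n_attributes)
    stopf("condition vector has %d attributes, model expects %d",
          ncol(X), model$n_attributes)
  p_nb <- predict_prob(model$nb, X[, model$features$nb, drop = FALSE])
  p_svm <- predict_prob(model$svm, X[, model$features$svm, drop = FALSE])
  p_ann <- predict_prob(model$ann, X[, model$features$ann, drop = FALSE])
  p <- (p_nb + p_svm + p_ann) / 3
  if (components)
    data.frame(p_nb = p_nb, p_svm = p_svm, p_ann = p_ann, p_ensemble = p)
  else p
}

## ---- evaluation --------------------------------------------------------

#' Leave-one-condition-out cross-validation of the ensemble
#'
#' One fold per merged condition: the ensemble is trained (feature selection
#' and oversampling inside the fold) on the remaining conditions and scores
#' the held-out one, so no condition ever appears in both train and test.
#' Performance is summarized over the pooled fold predictions by ROC and
#' precision-recall curves. The baseline ranks every held-out condition by
#' the site's mutation frequency in its training fold.
#'
#' @param x a `site_dataset`, or a `compendium` (then `site` is required).
#' @param site site name when `x` is a compendium.
#' @param seed RNG seed.
#' @param inclusion_min_conditions forwarded to [build_site_dataset()].
#' @param ... forwarded to [train_ensemble()] (e.g. `feature_select`,
#'   `ann_epochs`).
#' @return object of class `cv_result`: pooled `predictions` data.frame,
#'   `auc`, `auprc`, `baseline_auc`, `baseline_auprc`, `roc`, `pr`,
#'   `n_folds`.
#' @export
evaluate_loco <- function(x, site = NULL, seed = 1,
                          inclusion_min_conditions = 3L, ...) {
  dataset <- if (inherits(x, "compendium")) {
    if (is.null(site)) stopf("`site` required when passing a compendium")
    ds <- build_site_dataset(x, site, inclusion_min_conditions)
    if (is.null(ds)) stopf("site '%s' fails the inclusion threshold", site)
    ds
  } else x
  stopifnot(inherits(dataset, "site_dataset"))
  n <- nrow(dataset$X)
  if (n < 3L) stopf("need at least 3 conditions for leave-one-condition-out")
  preds <- baseline <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    tr_X <- dataset$X[-i, , drop = FALSE]
    tr_y <- dataset$y[-i]
    baseline[i] <- mean(tr_y)
    if (length(unique(tr_y)) < 2L) {  # degenerate fold: only the prior is available
      preds[i] <- mean(tr_y)
      skipped <- skipped + 1L
      next
    }
    sub <- new_site_dataset(dataset$site, tr_X, tr_y, dataset$condition_keys[-i])
    m <- train_ensemble(sub, seed = seed + i, ...)
    preds[i] <- ensemble_predict(m, dataset$X[i, ])
  }
  if (skipped) message(sprintf("evaluate_loco: %d degenerate folds used the prior", skipped))
  structure(list(
    site = dataset$site,
    predictions = data.frame(condition = dataset$condition_keys,
                             y = dataset$y, p = preds, baseline = baseline,
                             stringsAsFactors = FALSE),
    auc = auc_roc(preds, dataset$y),
    auprc = auprc(preds, dataset$y),
    baseline_auc = auc_roc(baseline, dataset$y),
    baseline_auprc = auprc(baseline, dataset$y),
    roc = roc_points(preds, dataset$y),
    pr = pr_points(preds, dataset$y),
    n_folds = n), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result[%s]: LOCO over %d conditions | AUC %.3f (baseline %.3f) | AUPRC %.3f (baseline %.3f)\n",
              x$site, x$n_folds, x$auc, x$baseline_auc, x$auprc, x$baseline_auprc))
  invisible(x)
}

#' Bootstrap forward validation against a novel condition
#'
#' Emulates prospective validation: in each bootstrap round the merged
#' conditions are resampled with replacement, every eligible site model is
#' retrained on the resample, and the sites whose predicted mutation
#' probability for the novel condition exceeds `decision_threshold` form that
#' round's prediction set. Round-wise precision and recall against the
#' observed mutation set are reported as mean +/- SD (rounds with an empty
#' prediction set have undefined precision: they are recorded as missing,
#' excluded from the mean and counted in `n_undefined_precision`). A site is
#' "called" when predicted in more than `call_threshold` rounds.
#'
#' @param compendium training `compendium`.
#' @param novel_condition list with `strain`, `medium`, `stresses`,
#'   `generations` (attributes must exist in the training vocabulary).
#' @param observed_sites character vector of canonical site names found in
#'   the validation experiment.
#' @param n_bootstrap bootstrap rounds (default 10).
#' @param call_threshold minimum rounds (exclusive) for a site call
#'   (default 5).
#' @param decision_threshold probability cut-off for "predicted mutated".
#' @param inclusion_min_conditions site inclusion threshold.
#' @param seed RNG seed.
#' @param ... forwarded to [train_ensemble()].
#' @return list with `precision_mean`, `precision_sd`, `recall_mean`,
#'   `recall_sd`, `rounds` (per-round data.frame), `calls` (per-site call
#'   counts with the `called` flag), `n_undefined_precision`.
#' @export
bootstrap_forward_validation <- function(compendium, novel_condition,
                                         observed_sites,
                                         n_bootstrap = 10, call_threshold = 5,
                                         decision_threshold = 0.5,
                                         inclusion_min_conditions = 3L,
                                         seed = 1, ...) {
  stopifnot(inherits(compendium, "compendium"))
  profiles <- build_condition_profiles(compendium)
  vocabulary <- condition_vocabulary(compendium$conditions)
  x_new <- encode_condition(novel_condition, vocabulary)
  sites <- compendium_sites(compendium)
  datasets <- Filter(Negate(is.null), setNames(lapply(sites, function(s)
    build_site_dataset(compendium, s, inclusion_min_conditions,
                       profiles = profiles, vocabulary = vocabulary)), sites))
  if (!length(datasets)) stopf("no site passes the inclusion threshold; nothing to train")
  n_cond <- nrow(profiles$matrix)
  calls <- setNames(integer(length(datasets)), names(datasets))
  rounds <- data.frame(round = seq_len(n_bootstrap), n_predicted = NA_integer_,
                       precision = NA_real_, recall = NA_real_)
  for (b in seq_len(n_bootstrap)) {
    idx <- local_seed(seed + b, sample.int(n_cond, n_cond, replace = TRUE))
    predicted <- character(0)
    for (s in names(datasets)) {
      ds <- datasets[[s]]
      yb <- ds$y[idx]
      if (length(unique(yb)) < 2L) next
      sub <- new_site_dataset(s, ds$X[idx, , drop = FALSE], yb,
                              ds$condition_keys[idx])
      m <- train_ensemble(sub, seed = seed + b, ...)
      if (ensemble_predict(m, x_new) > decision_threshold)
        predicted <- c(predicted, s)
    }
    calls[predicted] <- calls[predicted] + 1L
    tp <- length(intersect(predicted, observed_sites))
    rounds$n_predicted[b] <- length(predicted)
    rounds$precision[b] <- if (length(predicted)) tp / length(predicted) else NA_real_
    rounds$recall[b] <- tp / length(observed_sites)
  }
  n_undef <- sum(is.na(rounds$precision))
  if (n_undef)
    message(sprintf("bootstrap_forward_validation: %d round(s) predicted no sites; precision undefined there", n_undef))
  call_tab <- data.frame(site = names(calls), n_called = unname(calls),
                         called = unname(calls) > call_threshold,
                         observed = names(calls) %in% observed_sites,
                         stringsAsFactors = FALSE)
  call_tab <- call_tab[order(-call_tab$n_called, call_tab$site), ]
  rownames(call_tab) <- NULL
  list(precision_mean = mean(rounds$precision, na.rm = TRUE),
       precision_sd = sd(rounds$precision, na.rm = TRUE),
       recall_mean = mean(rounds$recall),
       recall_sd = sd(rounds$recall),
       rounds = rounds, calls = call_tab,
       n_undefined_precision = n_undef)
}
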