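#' Per-replicate mutation counts versus generations
#'
#' One point per evolved replicate: the number of recorded mutation events,
#' the generations elapsed (taken from its condition), the implied fixation
#' rate (mutations per generation) and the hypermutator flag.
#'
#' @param compendium a `compendium`.
#' @return data.frame with columns `replicate_id`, `condition_id`,
#'   `generations`, `n_mutations`, `rate`, `hypermutator`.
#' @export
fixation_series <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  reps <- compendium$replicates
  cond <- compendium$conditions
  gen <- cond$generations[match(reps$condition_id, cond$condition_id)]
  counts <- table(compendium$events$replicate_id)
  n <- as.integer(counts[reps$replicate_id])
  n[is.na(n)] <- 0L
  out <- data.frame(replicate_id = reps$replicate_id,
                    condition_id = reps$condition_id,
                    generations = gen, n_mutations = n,
                    rate = n / gen, hypermutator = reps$hypermutator,
                    stringsAsFactors = FALSE)
  skipped <- sum(is.na(out$generations))
  if (skipped) {
    message(sprintf("fixation_series: %d replicates without generations skipped", skipped))
    out <- out[!is.na(out$generations), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

new_fit_result <- function(model, coefficients, r_squared, n_points, fit = NULL) {
  structure(list(model = model, coefficients = coefficients,
                 r_squared = r_squared, n_points = n_points, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  co <- paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients), collapse = ", ")
  cat(sprintf("fit_result[%s]: %s (R^2 = %.3f, n = %d)\n",
              x$model, co, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit mutation accumulation against generations
#'
#' Linear model: ordinary least squares of mutation count on generations
#' (free intercept). Exponential model: log-linear least squares of
#' `log(count)` on generations over the points with a positive count, i.e.
#' `count = amplitude * exp(rate * generations)`; the reported R-squared is
#' always computed on the original count scale.
#'
#' @param series a [fixation_series()] data.frame.
#' @param model `"linear"` or `"exponential"`.
#' @param include_hypermutators keep hypermutator replicates? Mutation
#'   accumulation is close to linear without them and exponential-looking
#'   with them.
#' @return a `fit_result` with coefficients `intercept`/`slope` (linear) or
#'   `amplitude`/`rate` (exponential).
#' @export
fit_fixation <- function(series, model = c("linear", "exponential"),
                         include_hypermutators = FALSE) {
  model <- match.arg(model)
  dat <- series
  if (!include_hypermutators) dat <- dat[!dat$hypermutator, , drop = FALSE]
  if (nrow(dat) < 3L && length(unique(dat$generations)) > 2L)
    stopf("need at least 3 points to fit")
  if (nrow(dat) < 2L) stopf("need at least 2 points to fit")
  g <- dat$generations
  n <- dat$n_mutations
  ss_tot <- sum((n - mean(n))^2)
  if (model == "linear") {
    fit <- lm(n ~ g)
    pred <- fitted(fit)
    r2 <- if (ss_tot > 0) 1 - sum((n - pred)^2) / ss_tot else 1
    new_fit_result("linear",
                   c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
                   r2, nrow(dat), fit)
  } else {
    pos <- n > 0
    if (!any(pos)) stopf("exponential fit impossible: all counts are zero")
    fit <- lm(log(n[pos]) ~ g[pos])
    a <- exp(unname(coef(fit)[1]))
    b <- unname(coef(fit)[2])
    pred <- a * exp(b * g)
    r2 <- if (ss_tot > 0) 1 - sum((n - pred)^2) / ss_tot else 1
    new_fit_result("exponential", c(amplitude = a, rate = b), r2, nrow(dat), fit)
  }
}

#' Classify a replicate as hypermutator from its fixation rate
#'
#' A clone is a hypermutator when its fixation rate exceeds 0.1 mutations per
#' genome per generation (strict inequality).
#'
#' @param rate non-negative numeric vector of mutations per generation.
#' @param threshold rate cut-off (default 0.1).
#' @return logical vector.
#' @examples
#' classify_hypermutator(c(0.26, 0.0068, 0.1))
#' @export
classify_hypermutator <- function(rate, threshold = 0.1) {
  if (any(is.na(rate))) stopf("rate must not be missing")
  if (any(rate < 0)) stopf("rate must be non-negative")
  rate > threshold
}

replicate_site_sets <- function(compendium, condition_id) {
  reps <- compendium$replicates
  ids <- reps$replicate_id[reps$condition_id == condition_id]
  ev <- compendium$events[compendium$events$condition_id == condition_id, , drop = FALSE]
  sets <- split(ev$site, factor(ev$replicate_id, levels = ids))
  lapply(sets, unique)
}

#' Replicate-convergence overlap statistics for one condition
#'
#' With replicate site sets `A_1..A_N` and union `U`:
#' the averaged frequency `F` is the mean over distinct mutations of the
#' fraction of replicates carrying each; the global overlap `G` is the mean
#' over replicates of `|A_i| / |U|` (each replicate's overlap with the
#' condition-wide union); the pairwise overlap `P` is the mean Jaccard index
#' `|A_i ∩ A_j| / |A_i ∪ A_j|` over unordered replicate pairs. Mutation types
#' are ignored throughout. Note `F` and `G` coincide algebraically (both
#' equal `sum_i |A_i| / (N |U|)`); both are reported because they answer
#' different questions operationally. An empty replicate contributes 0 to
#' `G`; a pair of empty replicates has Jaccard 1 by the identical-empty
#' convention (a message is emitted). With a single replicate `P` is `NA`.
#'
#' @param compendium a `compendium`.
#' @param condition_id condition identifier.
#' @return one-row data.frame: `condition_id`, `n_replicates`, `n_sites`,
#'   `averaged_frequency`, `global_overlap`, `pairwise_overlap`.
#' @export
overlap_ratios <- function(compendium, condition_id) {
  stopifnot(inherits(compendium, "compendium"))
  if (!condition_id %in% compendium$conditions$condition_id)
    stopf("unknown condition: '%s'", condition_id)
  sets <- replicate_site_sets(compendium, condition_id)
  N <- length(sets)
  if (N == 0L) stopf("condition '%s' has no replicates", condition_id)
  U <- unique(unlist(sets))
  if (!length(U)) {
    return(data.frame(condition_id = condition_id, n_replicates = N,
                      n_sites = 0L, averaged_frequency = NA_real_,
                      global_overlap = NA_real_, pairwise_overlap = NA_real_,
                      stringsAsFactors = FALSE))
  }
  counts <- table(unlist(sets))
  F <- mean(as.numeric(counts)) / N
  G <- mean(vapply(sets, length, integer(1)) / length(U))
  P <- NA_real_
  if (N >= 2L) {
    pairs <- combn(N, 2)
    jac <- apply(pairs, 2, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      u <- length(union(a, b))
      if (u == 0) return(NA_real_)  # identical-empty pair
      length(intersect(a, b)) / u
    })
    if (anyNA(jac)) {
      message(sprintf("overlap_ratios: %d empty replicate pair(s) in '%s' scored as identical (Jaccard 1)",
                      sum(is.na(jac)), condition_id))
      jac[is.na(jac)] <- 1
    }
    P <- mean(jac)
  }
  data.frame(condition_id = condition_id, n_replicates = N, n_sites = length(U),
             averaged_frequency = F, global_overlap = G, pairwise_overlap = P,
             stringsAsFactors = FALSE)
}

overlap_table <- function(compendium, min_replicates = 2L) {
  cond <- compendium$conditions$condition_id
  n_reps <- table(compendium$replicates$condition_id)
  keep <- cond[as.integer(n_reps[cond]) >= min_replicates & !is.na(n_reps[cond])]
  out <- do.call(rbind, lapply(keep, overlap_ratios, compendium = compendium))
  out[!is.na(out$averaged_frequency), , drop = FALSE]
}

#' Overlap laws as a function of replicate number
#'
#' Conditions with the same number of replicates `N` are aggregated into one
#' data point (mean, with SD recorded); the averaged frequency `F` and global
#' overlap `G` are then regressed on `1/N` by ordinary least squares, which
#' under pure contingency (every mutation private to one replicate) gives
#' slope 1 and intercept 0, while a positive intercept measures the
#' deterministic, shared component of evolution. The pairwise overlap `P` is
#' summarized per `N` and its trend fitted linearly against `N` (near-zero
#' slope means pair-level convergence is independent of replicate number).
#'
#' @param compendium a `compendium`.
#' @param min_replicates minimum replicates per condition (default 2).
#' @return list with `f_fit`, `g_fit`, `p_trend` (fit_result objects),
#'   `by_n` (aggregated table) and `per_condition`.
#' @export
overlap_vs_replicates <- function(compendium, min_replicates = 2L) {
  tab <- overlap_table(compendium, min_replicates)
  if (is.null(tab) || !nrow(tab)) stopf("no conditions with >= %d replicates", min_replicates)
  Ns <- sort(unique(tab$n_replicates))
  if (length(Ns) < 3L) stopf("need at least 3 distinct replicate counts, got %d", length(Ns))
  agg <- do.call(rbind, lapply(Ns, function(N) {
    sub <- tab[tab$n_replicates == N, ]
    data.frame(n_replicates = N, n_conditions = nrow(sub),
               F_mean = mean(sub$averaged_frequency), F_sd = sd(sub$averaged_frequency),
               G_mean = mean(sub$global_overlap), G_sd = sd(sub$global_overlap),
               P_mean = mean(sub$pairwise_overlap), P_sd = sd(sub$pairwise_overlap))
  }))
  inv_n <- 1 / agg$n_replicates
  fit_on <- function(y, label) {
    fit <- lm(y ~ inv_n)
    pred <- fitted(fit)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum((y - pred)^2) / ss_tot else 1
    new_fit_result(label,
                   c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
                   r2, length(y), fit)
  }
  f_fit <- fit_on(agg$F_mean, "reciprocal")
  g_fit <- fit_on(agg$G_mean, "reciprocal")
  p_lm <- lm(agg$P_mean ~ agg$n_replicates)
  ss_tot <- sum((agg$P_mean - mean(agg$P_mean))^2)
  p_trend <- new_fit_result("linear",
                            c(intercept = unname(coef(p_lm)[1]),
                              slope = unname(coef(p_lm)[2])),
                            if (ss_tot > 0) 1 - sum((agg$P_mean - fitted(p_lm))^2) / ss_tot else 1,
                            nrow(agg), p_lm)
  list(f_fit = f_fit, g_fit = g_fit, p_trend = p_trend,
       by_n = agg, per_condition = tab)
}

#' Compare convergence statistics between two groups
#'
#' For `statistic = "pairwise_overlap"` the per-condition pairwise overlap is
#' compared between two sets of conditions (e.g. antibiotic vs no stress, or
#' minimal vs rich medium). For `statistic = "dna_gene_fraction"` replicates
#' are split by fixation rate above/below the mean rate (or by a supplied
#' partition) and the per-replicate indicator "carries at least one mutation
#' in the DNA-maintenance gene list" is compared. The test is a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) by default, with Welch's t as an
#' alternative.
#'
#' @param compendium a `compendium`.
#' @param groups for `pairwise_overlap`: list of two character vectors of
#'   condition ids (named; names become group labels). For
#'   `dna_gene_fraction`: optional list of two vectors of replicate ids;
#'   default splits non-hypermutator replicates at the mean fixation rate.
#' @param statistic which statistic to compare.
#' @param dna_genes gene list, required for `dna_gene_fraction`.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return list with `group_stats` (n, mean, sd per group), `p_value`,
#'   `statistic`, `test`.
#' @export
compare_groups <- function(compendium, groups = NULL,
                           statistic = c("pairwise_overlap", "dna_gene_fraction"),
                           dna_genes = NULL, test = c("wilcoxon", "welch")) {
  stopifnot(inherits(compendium, "compendium"))
  statistic <- match.arg(statistic)
  test <- match.arg(test)
  if (statistic == "pairwise_overlap") {
    if (!is.list(groups) || length(groups) != 2L)
      stopf("`groups` must be a list of two condition-id vectors")
    tab <- overlap_table(compendium)
    vals <- lapply(groups, function(ids) {
      v <- tab$pairwise_overlap[tab$condition_id %in% ids]
      v[!is.na(v)]
    })
  } else {
    if (is.null(dna_genes)) stopf("`dna_genes` required for dna_gene_fraction")
    ser <- fixation_series(compendium)
    ser <- ser[!ser$hypermutator, , drop = FALSE]
    site_hit <- vapply(compendium_sites(compendium), function(site) {
      core <- strip_is_tag(site)
      if (grepl("-", core, fixed = TRUE))
        any(strsplit(core, "-", fixed = TRUE)[[1]] %in% dna_genes)
      else core %in% dna_genes
    }, logical(1))
    listed <- names(site_hit)[site_hit]
    reps_with_hit <- unique(unlist(lapply(compendium$site_index[listed],
                                          function(ix) ix$replicate_id)))
    indicator <- setNames(as.numeric(ser$replicate_id %in% reps_with_hit),
                          ser$replicate_id)
    if (is.null(groups)) {
      cut_rate <- mean(ser$rate)
      groups <- list(high_rate = ser$replicate_id[ser$rate > cut_rate],
                     low_rate = ser$replicate_id[ser$rate <= cut_rate])
    }
    vals <- lapply(groups, function(ids) unname(indicator[intersect(ids, names(indicator))]))
  }
  labels <- names(groups) %||% c("group1", "group2")
  if (is.null(names(vals)) || any(!nzchar(labels))) labels <- c("group1", "group2")
  if (any(!lengths(vals))) stopf("both groups must be non-empty")
  p <- if (test == "wilcoxon")
    suppressWarnings(wilcox.test(vals[[1]], vals[[2]], exact = FALSE)$p.value)
  else t.test(vals[[1]], vals[[2]])$p.value
  if (is.nan(p)) p <- 1  # identical constant groups: no evidence of difference
  list(group_stats = data.frame(group = labels, n = lengths(vals),
                                mean = vapply(vals, mean, numeric(1)),
                                sd = vapply(vals, sd, numeric(1)),
                                row.names = NULL, stringsAsFactors = FALSE),
       p_value = p, statistic = statistic, test = test)
}
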