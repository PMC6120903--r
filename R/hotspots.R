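#' Per-site condition frequency
#'
#' For every genome site, the number and fraction of culture conditions in
#' which it was mutated, plus its raw event count and the number of distinct
#' stresses and media it appears under.
#'
#' @param compendium a `compendium`.
#' @return data.frame with columns `site`, `n_conditions_hit`,
#'   `fraction_of_conditions`, `n_events`, `n_stresses`, `n_media`, sorted by
#'   decreasing fraction.
#' @export
site_condition_frequency <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  n_cond <- nrow(compendium$conditions)
  if (n_cond < 1L) stopf("compendium has no conditions")
  breadth <- summarize_compendium(compendium)$site_breadth
  ev_counts <- table(compendium$events$site)
  out <- data.frame(site = breadth$site,
                    n_conditions_hit = breadth$n_conditions,
                    fraction_of_conditions = breadth$n_conditions / n_cond,
                    n_events = as.integer(ev_counts[breadth$site]),
                    n_stresses = breadth$n_stresses,
                    n_media = breadth$n_media,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction_of_conditions, out$site), ]
  rownames(out) <- NULL
  out
}

## null universe for the length-proportional model: all annotated genes plus
## any site observed in the events (intergenic / IS-tagged), weighted by
## genomic length
null_universe <- function(compendium, annotation) {
  sites <- union(annotation$genes$name, compendium_sites(compendium))
  sites <- sort(sites)
  data.frame(site = sites, weight = site_lengths(sites, annotation),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo hotspot p-values under a length-proportional null
#'
#' The null hypothesis is that, absent selection, mutations land anywhere on
#' the genome with probability proportional to target length. Each evolution
#' run (replicate) `r` mutated `m_r` distinct sites; a null world redraws
#' those `m_r` sites per run without replacement with length-proportional
#' probabilities, and a site's p-value is the fraction of worlds in which it
#' is hit in at least as many runs as observed, with add-one smoothing
#' `p = (1 + exceedances) / (1 + n_samples)` so p is never 0.
#'
#' The per-run draw is hypergeometric-like (without replacement, weighted);
#' with equal lengths it reduces to the binomial special case used as the
#' exact oracle in the tests.
#'
#' @param compendium a `compendium`.
#' @param annotation a [genome_annotation]; every observed site must be
#'   resolvable against it.
#' @param sites sites to report (default: all sites with at least one event).
#' @param n_samples Monte-Carlo sample count (default 100,000).
#' @param seed RNG seed.
#' @param replicate_ids optional subset of replicates defining the runs (used
#'   for mutator/non-mutator stratification).
#' @return data.frame with `site`, `observed_k`, `p_value`, `mc_se`,
#'   `mc_samples`, sorted by increasing p.
#' @seealso [mc_hotspot_pvalue()] for a single site.
#' @export
mc_hotspot_pvalues <- function(compendium, annotation, sites = NULL,
                               n_samples = 1e5, seed = 1,
                               replicate_ids = NULL) {
  stopifnot(inherits(compendium, "compendium"),
            inherits(annotation, "genome_annotation"))
  uni <- null_universe(compendium, annotation)
  ev <- compendium$events
  if (!is.null(replicate_ids)) ev <- ev[ev$replicate_id %in% replicate_ids, , drop = FALSE]
  per_run <- split(ev$site, ev$replicate_id)
  m_runs <- vapply(per_run, function(s) length(unique(s)), integer(1))
  if (any(m_runs > nrow(uni)))
    stopf("a run mutates more distinct sites (%d) than the null universe holds (%d)",
          max(m_runs), nrow(uni))
  k_obs <- setNames(integer(nrow(uni)), uni$site)
  hit_tab <- table(unlist(lapply(per_run, unique)))
  k_obs[names(hit_tab)] <- as.integer(hit_tab)

  exceed <- local_seed(seed,
    .mc_exceed_counts(uni$weight, as.integer(m_runs), as.integer(k_obs),
                      as.integer(n_samples)))
  p <- (1 + exceed) / (1 + n_samples)
  out <- data.frame(site = uni$site, observed_k = unname(k_obs),
                    p_value = p, mc_se = sqrt(p * (1 - p) / n_samples),
                    mc_samples = as.integer(n_samples),
                    stringsAsFactors = FALSE)
  if (is.null(sites)) sites <- names(hit_tab)
  bad <- setdiff(sites, out$site)
  if (length(bad)) stopf("site absent from null universe: %s", paste(bad, collapse = ", "))
  out <- out[match(sites, out$site), , drop = FALSE]
  out <- out[order(out$p_value, out$site), ]
  rownames(out) <- NULL
  out
}

#' Hotspot p-value for a single site
#'
#' Convenience wrapper around [mc_hotspot_pvalues()].
#'
#' @inheritParams mc_hotspot_pvalues
#' @param site canonical site name.
#' @return one-row data.frame (a hotspot call).
#' @export
mc_hotspot_pvalue <- function(site, compendium, annotation,
                              n_samples = 1e5, seed = 1) {
  mc_hotspot_pvalues(compendium, annotation, sites = site,
                     n_samples = n_samples, seed = seed)
}

#' Sliding-window mutation-density scan
#'
#' Counts positioned mutation events in windows along the genome (default:
#' non-overlapping 5-kb tiles), fits a gamma distribution to the tiling
#' counts by maximum likelihood (zero windows get a 0.5 pseudo-count for the
#' fit only) and reports the upper-tail 0.05 gamma quantile as the
#' significance line. Hotspot windows are the top 5% by raw count; depletion
#' windows are those never hit. Events without a recorded position are
#' skipped and counted in `n_unpositioned`.
#'
#' @param compendium a `compendium`.
#' @param annotation a [genome_annotation] (supplies the genome length).
#' @param window window width in bases.
#' @param step step between window starts; steps smaller than `window` give
#'   overlapping windows, which are reported but excluded from the gamma fit.
#' @param hotspot_quantile fraction of windows flagged as hotspots (0.05).
#' @return object of class `window_profile`: list with `windows` (data.frame
#'   of start/end/count/hotspot flags), `gamma_shape`, `gamma_scale`,
#'   `hotspot_threshold`, `signif_line`, `depletion_windows`,
#'   `n_unpositioned`.
#' @export
window_scan <- function(compendium, annotation, window = 5000, step = window,
                        hotspot_quantile = 0.05) {
  stopifnot(inherits(compendium, "compendium"),
            inherits(annotation, "genome_annotation"))
  L <- annotation$genome_length
  pos <- compendium$events$position
  n_unpos <- sum(is.na(pos))
  pos <- pos[!is.na(pos)]
  if (any(pos < 1 | pos > L)) stopf("event positions outside [1, genome_length]")
  starts <- seq.int(1L, L, by = as.integer(step))
  ends <- pmin(starts + as.integer(window) - 1L, L)
  if (length(starts) < 10L) stopf("fewer than 10 windows; enlarge the genome or shrink the window")
  pos_sorted <- sort(pos)
  counts <- findInterval(ends, pos_sorted) - findInterval(starts - 1L, pos_sorted)
  tiling <- step >= window
  thr <- as.numeric(quantile(counts, 1 - hotspot_quantile, type = 1))
  fit_counts <- counts
  fit_counts[fit_counts == 0] <- 0.5
  gfit <- suppressWarnings(MASS::fitdistr(fit_counts, "gamma"))
  shape <- unname(gfit$estimate["shape"])
  scale <- 1 / unname(gfit$estimate["rate"])
  windows <- data.frame(start = starts, end = ends, count = counts,
                        hotspot = counts >= thr & counts > 0,
                        depletion = counts == 0)
  structure(list(windows = windows, window = window, step = step,
                 tiling = tiling,
                 gamma_shape = shape, gamma_scale = scale,
                 hotspot_threshold = thr,
                 signif_line = qgamma(1 - hotspot_quantile, shape = shape, scale = scale),
                 depletion_windows = which(counts == 0),
                 n_unpositioned = n_unpos,
                 n_positioned = length(pos)),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile: %d windows of %d bp (step %d), %d events binned (%d unpositioned)\n",
              nrow(x$windows), x$window, x$step, x$n_positioned, x$n_unpositioned))
  cat(sprintf("gamma fit shape=%.3f scale=%.3f | hotspot count threshold %g | %d depletion windows\n",
              x$gamma_shape, x$gamma_scale, x$hotspot_threshold,
              length(x$depletion_windows)))
  invisible(x)
}

#' Share of all events carried by the most-mutated sites
#'
#' Ranks sites by event count and returns the fraction of all mutation
#' events falling in the top `ceiling(fraction * n_sites)` sites. With the
#' default 0.5% this measures the heavy tail of the per-site mutation-count
#' distribution.
#'
#' @param compendium a `compendium`.
#' @param fraction fraction of sites considered "top", in (0, 1].
#' @return numeric scalar in (0, 1].
#' @export
top_share <- function(compendium, fraction = 0.005) {
  stopifnot(inherits(compendium, "compendium"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stopf("`fraction` must be in (0, 1]")
  counts <- sort(table(compendium$events$site), decreasing = TRUE)
  if (!length(counts)) stopf("compendium has no events")
  k <- ceiling(fraction * length(counts))
  sum(counts[seq_len(k)]) / sum(counts)
}

#' Mutator / non-mutator hotspot contrast
#'
#' Computes per-site condition frequencies separately for the non-mutator and
#' hypermutator strata. Within a stratum, the denominator is the number of
#' conditions with at least one replicate in the stratum and a site counts as
#' hit when any stratum replicate carries it. Optionally adds Monte-Carlo
#' hotspot p-values per stratum and, given a list of DNA-maintenance genes,
#' the fraction of replicates in each stratum with at least one hit in that
#' list (intergenic sites count if either flank is listed; IS tags are
#' ignored for matching).
#'
#' @param compendium a `compendium`.
#' @param dna_genes optional character vector of DNA-related gene names.
#' @param annotation optional [genome_annotation]; when supplied, stratum
#'   p-values are computed via [mc_hotspot_pvalues()].
#' @param n_samples,seed Monte-Carlo settings for the p-values.
#' @return list with data.frames `nonmutator` and `mutator` (site,
#'   n_conditions_hit, frequency, and p_value/mc_se when requested) and, when
#'   `dna_genes` is given, `dna_gene_fraction` (named numeric of length 2).
#' @export
mutator_contrast <- function(compendium, dna_genes = NULL, annotation = NULL,
                             n_samples = 2e4, seed = 1) {
  stopifnot(inherits(compendium, "compendium"))
  reps <- compendium$replicates
  strata <- list(nonmutator = reps$replicate_id[!reps$hypermutator],
                 mutator = reps$replicate_id[reps$hypermutator])
  freq_tab <- function(ids) {
    if (!length(ids))
      return(data.frame(site = character(0), n_conditions_hit = integer(0),
                        frequency = numeric(0), stringsAsFactors = FALSE))
    cond_ids <- unique(reps$condition_id[reps$replicate_id %in% ids])
    hits <- lapply(compendium$site_index, function(ix) {
      unique(ix$condition_id[ix$replicate_id %in% ids])
    })
    n_hit <- vapply(hits, length, integer(1))
    keep <- n_hit > 0
    out <- data.frame(site = names(hits)[keep],
                      n_conditions_hit = unname(n_hit[keep]),
                      frequency = unname(n_hit[keep]) / length(cond_ids),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$site), ]
    rownames(out) <- NULL
    out
  }
  out <- lapply(strata, freq_tab)
  if (!is.null(annotation)) {
    for (nm in names(out)) {
      if (!nrow(out[[nm]])) next
      pv <- mc_hotspot_pvalues(compendium, annotation, sites = out[[nm]]$site,
                               n_samples = n_samples, seed = seed,
                               replicate_ids = strata[[nm]])
      out[[nm]]$p_value <- pv$p_value[match(out[[nm]]$site, pv$site)]
      out[[nm]]$mc_se <- pv$mc_se[match(out[[nm]]$site, pv$site)]
    }
  }
  if (!is.null(dna_genes)) {
    hit_list <- function(site) {
      core <- strip_is_tag(site)
      if (grepl("-", core, fixed = TRUE))
        any(strsplit(core, "-", fixed = TRUE)[[1]] %in% dna_genes)
      else core %in% dna_genes
    }
    site_in_list <- vapply(compendium_sites(compendium), hit_list, logical(1))
    listed_sites <- names(site_in_list)[site_in_list]
    reps_with_hit <- unique(unlist(lapply(compendium$site_index[listed_sites],
                                          function(ix) ix$replicate_id)))
    out$dna_gene_fraction <- vapply(strata, function(ids) {
      if (!length(ids)) return(NA_real_)
      mean(ids %in% reps_with_hit)
    }, numeric(1))
  }
  out
}
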