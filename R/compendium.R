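#' Duration bin of an evolution experiment
#'
#' Experiment durations (in generations) are discretized into seven
#' left-exclusive, right-inclusive intervals:
#' (0,500], (500,1000], (1000,5000], (5000,10000], (10000,20000],
#' (20000,30000], (30000,40000]. Durations above 40,000 generations are not
#' representable and raise an error.
#'
#' @param generations positive numeric vector.
#' @return character vector of bin labels.
#' @examples
#' duration_bin(c(500, 501))
#' @export
duration_bin <- function(generations) {
  g <- as.numeric(generations)
  if (anyNA(g)) stopf("generations must not be missing")
  if (any(g <= 0)) stopf("generations must be positive")
  if (any(g > max(DURATION_BREAKS)))
    stopf("generations above %d not supported (got %g)",
          max(DURATION_BREAKS), max(g))
  DURATION_LABELS[findInterval(g, DURATION_BREAKS, left.open = TRUE)]
}

#' Attribute vocabulary of a condition table
#'
#' The binary encoding of a culture condition is defined over a fixed
#' vocabulary of strain, medium and stress attributes (plus the seven
#' duration bins). The vocabulary is data-driven: it collects the sorted
#' unique values observed in a condition table.
#'
#' @param conditions data.frame with columns `strain`, `medium`, `stresses`
#'   (semicolon-joined), e.g. the `conditions` element of a compendium.
#' @return object of class `condition_vocabulary`: list with `strains`,
#'   `media`, `stresses`.
#' @export
condition_vocabulary <- function(conditions) {
  stopifnot(is.data.frame(conditions))
  structure(list(
    strains = sort(unique(as.character(conditions$strain))),
    media = sort(unique(as.character(conditions$medium))),
    stresses = sort(unique(unlist(split_stresses(conditions$stresses))))
  ), class = "condition_vocabulary")
}

#' @export
print.condition_vocabulary <- function(x, ...) {
  cat(sprintf("condition_vocabulary: %d strains, %d media, %d stresses, 7 duration bins (%d attributes)\n",
              length(x$strains), length(x$media), length(x$stresses),
              length(x$strains) + length(x$media) + length(x$stresses) + 7L))
  invisible(x)
}

#' Encode a culture condition as a binary attribute vector
#'
#' A condition is described by exactly one strain, exactly one medium, a
#' (possibly empty) set of stresses and an experiment duration. The encoding
#' is a fixed-length 0/1 vector over the vocabulary: one strain bit, one
#' medium bit, multi-hot stress bits and exactly one duration-bin bit.
#'
#' @param descriptor list with elements `strain`, `medium`, `stresses`
#'   (character vector, possibly empty) and `generations`.
#' @param vocabulary a [condition_vocabulary].
#' @return named integer vector of 0/1 of length
#'   `|strains| + |media| + |stresses| + 7`.
#' @export
encode_condition <- function(descriptor, vocabulary) {
  stopifnot(inherits(vocabulary, "condition_vocabulary"))
  strain <- as.character(descriptor$strain)
  medium <- as.character(descriptor$medium)
  stresses <- descriptor$stresses
  if (is.character(stresses) && length(stresses) == 1L && grepl(";", stresses))
    stresses <- split_stresses(stresses)[[1]]
  stresses <- as.character(stresses %||% character(0))
  stresses <- stresses[nzchar(stresses)]
  if (length(strain) != 1L || !strain %in% vocabulary$strains)
    stopf("strain not in vocabulary: '%s'", paste(strain, collapse = ","))
  if (length(medium) != 1L || !medium %in% vocabulary$media)
    stopf("medium not in vocabulary: '%s'", paste(medium, collapse = ","))
  bad <- setdiff(stresses, vocabulary$stresses)
  if (length(bad)) stopf("stress not in vocabulary: '%s'", paste(bad, collapse = "', '"))
  bin <- duration_bin(descriptor$generations)
  v <- c(setNames(as.integer(vocabulary$strains == strain), paste0("strain:", vocabulary$strains)),
         setNames(as.integer(vocabulary$media == medium), paste0("medium:", vocabulary$media)),
         setNames(as.integer(vocabulary$stresses %in% stresses), paste0("stress:", vocabulary$stresses)),
         setNames(as.integer(DURATION_LABELS == bin), paste0("duration:", DURATION_LABELS)))
  v
}

validate_conditions <- function(conditions) {
  need <- c("condition_id", "strain", "medium", "stresses", "generations")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stopf("conditions table lacks columns: %s", paste(miss, collapse = ", "))
  conditions$condition_id <- as.character(conditions$condition_id)
  if (anyDuplicated(conditions$condition_id)) stopf("duplicate condition_id")
  conditions$strain <- as.character(conditions$strain)
  conditions$medium <- as.character(conditions$medium)
  conditions$stresses <- vapply(split_stresses(conditions$stresses),
                                paste, character(1), collapse = ";")
  conditions$generations <- as.numeric(conditions$generations)
  conditions$duration_bin <- duration_bin(conditions$generations)
  rownames(conditions) <- NULL
  conditions[, c(need, "duration_bin")]
}

build_site_index <- function(events) {
  if (!nrow(events)) return(list())
  key <- paste(events$condition_id, events$replicate_id, sep = "\r")
  idx <- lapply(split(key, events$site), function(k) {
    k <- sort(unique(k))
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(condition_id = vapply(parts, `[`, character(1), 1L),
               replicate_id = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  })
  idx[order(names(idx))]
}

#' Construct a mutation compendium
#'
#' The compendium is the single source of truth for all downstream analyses:
#' a condition table, a replicate table (with hypermutator flags) and an
#' event table, plus a site index mapping each genome site to the
#' (condition, replicate) pairs that carry it.
#'
#' @param conditions data.frame with columns `condition_id`, `strain`,
#'   `medium`, `stresses` (semicolon-joined, possibly empty string) and
#'   `generations`.
#' @param replicates data.frame with columns `replicate_id`, `condition_id`
#'   and logical `hypermutator`.
#' @param events data.frame with columns `replicate_id`, `condition_id`,
#'   `site`, `mutation_type` and optionally `position` (1-based, `NA`
#'   allowed). Site names are taken as already canonical.
#' @return object of class `compendium`.
#' @export
new_compendium <- function(conditions, replicates, events) {
  conditions <- validate_conditions(as.data.frame(conditions))
  replicates <- as.data.frame(replicates)
  need <- c("replicate_id", "condition_id", "hypermutator")
  miss <- setdiff(need, names(replicates))
  if (length(miss)) stopf("replicates table lacks columns: %s", paste(miss, collapse = ", "))
  replicates$replicate_id <- as.character(replicates$replicate_id)
  replicates$condition_id <- as.character(replicates$condition_id)
  replicates$hypermutator <- as.logical(replicates$hypermutator)
  if (anyDuplicated(replicates$replicate_id)) stopf("duplicate replicate_id")
  bad <- setdiff(replicates$condition_id, conditions$condition_id)
  if (length(bad)) stopf("replicates reference unknown conditions: %s", paste(bad, collapse = ", "))
  replicates <- replicates[, need]
  rownames(replicates) <- NULL

  events <- as.data.frame(events)
  if (!nrow(events)) {
    events <- data.frame(replicate_id = character(0), condition_id = character(0),
                         site = character(0), mutation_type = character(0),
                         position = integer(0), stringsAsFactors = FALSE)
  }
  need_e <- c("replicate_id", "condition_id", "site", "mutation_type")
  miss <- setdiff(need_e, names(events))
  if (length(miss)) stopf("events table lacks columns: %s", paste(miss, collapse = ", "))
  events$replicate_id <- as.character(events$replicate_id)
  events$condition_id <- as.character(events$condition_id)
  events$site <- as.character(events$site)
  events$mutation_type <- as.character(events$mutation_type)
  if (!"position" %in% names(events)) events$position <- NA_integer_
  events$position <- suppressWarnings(as.integer(events$position))
  bad <- setdiff(unique(events$mutation_type), MUTATION_TYPES)
  if (length(bad)) stopf("unknown mutation_type: %s", paste(bad, collapse = ", "))
  if (any(!nzchar(events$site))) stopf("empty site name in events")
  bad <- setdiff(unique(events$replicate_id), replicates$replicate_id)
  if (length(bad)) stopf("events reference unknown replicates: %s", paste(head(bad, 5), collapse = ", "))
  key_ok <- events$condition_id == replicates$condition_id[match(events$replicate_id, replicates$replicate_id)]
  if (any(!key_ok)) stopf("event condition_id disagrees with its replicate's condition")
  events <- events[, c(need_e, "position")]
  rownames(events) <- NULL

  structure(list(conditions = conditions, replicates = replicates,
                 events = events, site_index = build_site_index(events)),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d mutation events at %d sites, %d replicates, %d conditions\n",
              nrow(x$events), length(x$site_index), nrow(x$replicates), nrow(x$conditions)))
  invisible(x)
}

#' Sites tracked by a compendium
#'
#' @param compendium a [new_compendium()] object.
#' @return sorted character vector of canonical site names.
#' @export
compendium_sites <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  names(compendium$site_index)
}

#' Load a mutation compendium from tab-separated files
#'
#' `events.tsv` columns: `replicate_id`, `condition_id`, `site_raw`,
#' `mutation_type`, `position`, `is_element`, `flank_a`, `flank_b`.
#' `conditions.tsv` columns: `condition_id`, `strain`, `medium`, `stresses`
#' (semicolon-joined), `generations`, `hypermutator_ids` (semicolon-joined
#' replicate ids). Empty fields are missing values.
#'
#' Site names are normalized against the annotation (synonym resolution,
#' intergenic flank ordering, IS tagging). Deletion rows carrying both
#' `flank_a` and `flank_b` are spans reported only by their flanks and are
#' expanded to one event per covered gene. Replicates are the union of
#' replicate ids seen in events and ids flagged as hypermutators.
#'
#' @param events_path,conditions_path file paths.
#' @param annotation a [genome_annotation] (required for alias resolution and
#'   span expansion; `NULL` accepts site names as canonical).
#' @return a `compendium`. Attributes `n_input_rows` and `n_expanded_rows`
#'   record the span-expansion accounting.
#' @export
load_compendium <- function(events_path, conditions_path, annotation = NULL) {
  cond_raw <- read.delim(conditions_path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  need <- c("condition_id", "strain", "medium", "stresses", "generations", "hypermutator_ids")
  miss <- setdiff(need, names(cond_raw))
  if (length(miss)) stopf("%s lacks columns: %s", conditions_path, paste(miss, collapse = ", "))
  conditions <- cond_raw[, c("condition_id", "strain", "medium", "stresses", "generations")]

  ev <- read.delim(events_path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  need_e <- c("replicate_id", "condition_id", "site_raw", "mutation_type",
              "position", "is_element", "flank_a", "flank_b")
  miss <- setdiff(need_e, names(ev))
  if (length(miss)) stopf("%s lacks columns: %s", events_path, paste(miss, collapse = ", "))
  n_input <- nrow(ev)

  if (n_input) {
    bad <- which(!ev$mutation_type %in% MUTATION_TYPES)
    if (length(bad))
      stopf("row %d of %s: malformed mutation_type '%s'",
            bad[1], events_path, ev$mutation_type[bad[1]])
    bad <- which(!ev$condition_id %in% conditions$condition_id)
    if (length(bad))
      stopf("row %d of %s: unknown condition_id '%s'",
            bad[1], events_path, ev$condition_id[bad[1]])
  }

  is_span <- nzchar(ev$flank_a) & nzchar(ev$flank_b)
  out <- vector("list", 2L)

  plain <- ev[!is_span, , drop = FALSE]
  if (nrow(plain)) {
    key <- paste(plain$site_raw, plain$is_element, sep = "\r")
    uk <- !duplicated(key)
    canon <- mapply(function(raw, tag) {
      tryCatch(normalize_site_name(raw, annotation,
                                   if (nzchar(tag)) tag else NULL),
               error = function(e) stopf("unresolvable site alias: %s", conditionMessage(e)))
    }, plain$site_raw[uk], plain$is_element[uk], USE.NAMES = FALSE)
    out[[1]] <- data.frame(replicate_id = plain$replicate_id,
                           condition_id = plain$condition_id,
                           site = canon[match(key, key[uk])],
                           mutation_type = plain$mutation_type,
                           position = plain$position,
                           stringsAsFactors = FALSE)
  }

  span <- ev[is_span, , drop = FALSE]
  if (nrow(span)) {
    if (is.null(annotation))
      stopf("deletion spans present in %s but no annotation given", events_path)
    expanded <- lapply(seq_len(nrow(span)), function(i) {
      genes <- expand_deletion_span(span$flank_a[i], span$flank_b[i], annotation)
      data.frame(replicate_id = span$replicate_id[i],
                 condition_id = span$condition_id[i],
                 site = genes,
                 mutation_type = span$mutation_type[i],
                 position = span$position[i],
                 stringsAsFactors = FALSE)
    })
    out[[2]] <- do.call(rbind, expanded)
  }
  events <- do.call(rbind, out[!vapply(out, is.null, logical(1))]) %||%
    data.frame(replicate_id = character(0), condition_id = character(0),
               site = character(0), mutation_type = character(0),
               position = character(0), stringsAsFactors = FALSE)
  events$position <- suppressWarnings(as.integer(events$position))

  hyper_ids <- unlist(split_stresses(cond_raw$hypermutator_ids))
  rep_ids <- unique(c(events$replicate_id, hyper_ids))
  rep_cond <- events$condition_id[match(rep_ids, events$replicate_id)]
  if (length(hyper_ids)) {
    cond_of_hyper <- rep(cond_raw$condition_id,
                         lengths(split_stresses(cond_raw$hypermutator_ids)))
    names(cond_of_hyper) <- hyper_ids
    missing_cond <- is.na(rep_cond)
    rep_cond[missing_cond] <- cond_of_hyper[rep_ids[missing_cond]]
  }
  replicates <- data.frame(replicate_id = rep_ids, condition_id = rep_cond,
                           hypermutator = rep_ids %in% hyper_ids,
                           stringsAsFactors = FALSE)
  replicates <- replicates[order(replicates$condition_id, replicates$replicate_id), ]

  comp <- new_compendium(conditions, replicates, events)
  attr(comp, "n_input_rows") <- n_input
  attr(comp, "n_expanded_rows") <- nrow(events)
  comp
}

#' Write a compendium back to its tab-separated representation
#'
#' Produces `events.tsv` / `conditions.tsv` in the canonical dialect read by
#' [load_compendium()]: tab-separated UTF-8, fixed headers, empty string for
#' missing values, sites already canonical (so `flank_a`/`flank_b` are empty
#' and IS tags live inside the site name). Loading a canonical file and
#' writing it again reproduces it byte for byte.
#'
#' @param compendium a `compendium`.
#' @param events_path,conditions_path output paths.
#' @return invisibly, a list with both paths.
#' @export
write_compendium <- function(compendium, events_path, conditions_path) {
  stopifnot(inherits(compendium, "compendium"))
  ev <- compendium$events
  ev_out <- data.frame(replicate_id = ev$replicate_id,
                       condition_id = ev$condition_id,
                       site_raw = ev$site,
                       mutation_type = ev$mutation_type,
                       position = ifelse(is.na(ev$position), "", as.character(ev$position)),
                       is_element = "", flank_a = "", flank_b = "",
                       stringsAsFactors = FALSE)
  write.table(ev_out, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  reps <- compendium$replicates
  hyper <- vapply(compendium$conditions$condition_id, function(cid) {
    ids <- reps$replicate_id[reps$condition_id == cid & reps$hypermutator]
    paste(sort(ids), collapse = ";")
  }, character(1))
  cond <- compendium$conditions
  cond_out <- data.frame(condition_id = cond$condition_id, strain = cond$strain,
                         medium = cond$medium, stresses = cond$stresses,
                         generations = format(cond$generations, trim = TRUE, scientific = FALSE),
                         hypermutator_ids = unname(hyper), stringsAsFactors = FALSE)
  write.table(cond_out, conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(events = events_path, conditions = conditions_path))
}

#' Merge the replicates of a condition into one binary site profile
#'
#' The profile bit for a site is 1 if any replicate of the condition carries
#' any mutation event there; the mutation type is deliberately ignored, so a
#' SNP in one replicate and a deletion in another set the same single bit.
#'
#' @param compendium a `compendium`.
#' @param condition_id condition identifier.
#' @return named integer 0/1 vector over all tracked sites (sorted).
#' @export
merge_replicates <- function(compendium, condition_id) {
  stopifnot(inherits(compendium, "compendium"))
  if (!condition_id %in% compendium$conditions$condition_id)
    stopf("unknown condition: '%s'", condition_id)
  sites <- compendium_sites(compendium)
  hit <- vapply(compendium$site_index,
                function(ix) condition_id %in% ix$condition_id, logical(1))
  setNames(as.integer(hit), sites)
}

## binary profile restricted to an arbitrary set of replicate ids
replicate_set_profile <- function(compendium, replicate_ids) {
  sites <- compendium_sites(compendium)
  hit <- vapply(compendium$site_index,
                function(ix) any(ix$replicate_id %in% replicate_ids), logical(1))
  setNames(as.integer(hit), sites)
}

#' Summary statistics of a mutation compendium
#'
#' Reports event counts by mutation type, site counts with the
#' coding/intergenic split (intergenic sites are the dash-separated flank
#' pairs), condition and replicate counts, and per-site breadth: in how many
#' distinct stresses and media each site was hit, along with the fraction of
#' sites appearing in more than 10% of stresses and media.
#'
#' @param compendium a `compendium`.
#' @return object of class `compendium_summary` (a list).
#' @export
summarize_compendium <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  ev <- compendium$events
  type_counts <- setNames(integer(length(MUTATION_TYPES)), MUTATION_TYPES)
  if (nrow(ev)) {
    tc <- table(factor(ev$mutation_type, levels = MUTATION_TYPES))
    type_counts[names(tc)] <- as.integer(tc)
  }
  sites <- compendium_sites(compendium)
  intergenic <- is_intergenic_site(sites)
  cond <- compendium$conditions
  stress_of <- setNames(split_stresses(cond$stresses), cond$condition_id)
  medium_of <- setNames(cond$medium, cond$condition_id)
  n_stresses <- length(unique(unlist(stress_of)))
  n_media <- length(unique(cond$medium))
  breadth <- if (length(sites)) {
    do.call(rbind, lapply(sites, function(s) {
      cids <- unique(compendium$site_index[[s]]$condition_id)
      data.frame(site = s,
                 n_conditions = length(cids),
                 n_stresses = length(unique(unlist(stress_of[cids]))),
                 n_media = length(unique(medium_of[cids])),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(site = character(0), n_conditions = integer(0),
                    n_stresses = integer(0), n_media = integer(0))
  structure(list(
    n_events = nrow(ev),
    type_counts = type_counts,
    n_sites = length(sites),
    n_coding_sites = sum(!intergenic),
    n_intergenic_sites = sum(intergenic),
    n_conditions = nrow(cond),
    n_replicates = nrow(compendium$replicates),
    n_hypermutators = sum(compendium$replicates$hypermutator),
    site_breadth = breadth,
    frac_sites_broad_stress = if (length(sites) && n_stresses > 0)
      mean(breadth$n_stresses > 0.1 * n_stresses) else NA_real_,
    frac_sites_broad_medium = if (length(sites) && n_media > 0)
      mean(breadth$n_media > 0.1 * n_media) else NA_real_
  ), class = "compendium_summary")
}

#' @export
print.compendium_summary <- function(x, ...) {
  cat(sprintf("%d events | %d sites (%d coding, %d intergenic) | %d conditions | %d replicates (%d hypermutators)\n",
              x$n_events, x$n_sites, x$n_coding_sites, x$n_intergenic_sites,
              x$n_conditions, x$n_replicates, x$n_hypermutators))
  cat("events by type:", paste(sprintf("%s=%d", names(x$type_counts), x$type_counts),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Forward-validation mutation table (35 osmotic-stress ALE lines)
#'
#' Loads the packaged table of mutations identified by whole-genome
#' resequencing of 35 Escherichia coli MG1655 lines evolved for 500
#' generations in M9 glucose under osmotic (0.3 M NaCl) stress: 23 genome
#' sites with the number of replicate lines carrying each mutation. The
#' table is also materialized as a one-condition compendium in which
#' mutation `m` with frequency `f` is assigned to the first `f` replicate
#' lines (only the per-mutation margins are published, so per-line
#' co-assignment is a convention; all marginal statistics are unaffected).
#'
#' @param path TSV with columns `site`, `mutation_type`, `n_replicates`,
#'   `product`; defaults to the packaged table.
#' @param n_lines number of evolved lines (35).
#' @return list with `table` (data.frame) and `compendium`.
#' @export
load_forward_validation <- function(path = NULL, n_lines = 35L) {
  path <- path %||% system.file("extdata", "forward_validation_mutations.tsv",
                                package = "evoforecast", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "mutation_type", "n_replicates")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("%s lacks columns: %s", path, paste(miss, collapse = ", "))
  rep_ids <- sprintf("osmo_r%02d", seq_len(n_lines))
  conditions <- data.frame(condition_id = "osmotic_nacl",
                           strain = "MG1655", medium = "M9 glucose",
                           stresses = "osmotic", generations = 500,
                           stringsAsFactors = FALSE)
  replicates <- data.frame(replicate_id = rep_ids, condition_id = "osmotic_nacl",
                           hypermutator = FALSE, stringsAsFactors = FALSE)
  events <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$n_replicates[i]
    if (k > n_lines) stopf("frequency %d exceeds number of lines", k)
    data.frame(replicate_id = rep_ids[seq_len(k)], condition_id = "osmotic_nacl",
               site = tab$site[i], mutation_type = tab$mutation_type[i],
               position = NA_integer_, stringsAsFactors = FALSE)
  }))
  list(table = tab, compendium = new_compendium(conditions, replicates, events))
}
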