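# Shared fixture builders: everything is generated in code, nothing on disk.

tiny_annotation <- function() {
  genome_annotation(
    data.frame(name = c("araC", "pykF", "pyrE", "rph"),
               start = c(1, 301, 801, 1501),
               end = c(200, 700, 1400, 1900)),
    genome_length = 2200,
    synonyms = c(b0064 = "araC", b1676 = "pykF", b3642 = "rph"))
}

## minimal compendium: one condition, explicit per-replicate site sets
set_compendium <- function(run_sites, sites = NULL, generations = 500,
                           types = "SNP", hyper = NULL) {
  n <- length(run_sites)
  rep_ids <- sprintf("r%02d", seq_len(n))
  cond <- data.frame(condition_id = "c1", strain = "MG1655", medium = "LB",
                     stresses = "", generations = generations)
  reps <- data.frame(replicate_id = rep_ids, condition_id = "c1",
                     hypermutator = hyper %||% rep(FALSE, n))
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- run_sites[[i]]
    if (!length(s)) return(NULL)
    data.frame(replicate_id = rep_ids[i], condition_id = "c1", site = s,
               mutation_type = rep_len(types, length(s)),
               position = NA_integer_, stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(replicate_id = character(0), condition_id = character(0),
                     site = character(0), mutation_type = character(0),
                     position = integer(0))
  new_compendium(cond, reps, ev)
}

## multi-condition compendium where every replicate carries only private
## (singleton) mutations; one condition per entry of n_replicates
singleton_compendium <- function(n_replicates) {
  conds <- data.frame(condition_id = sprintf("c%02d", seq_along(n_replicates)),
                      strain = "MG1655", medium = "LB", stresses = "",
                      generations = 500)
  reps <- list(); evs <- list(); site_counter <- 0L
  for (i in seq_along(n_replicates)) {
    ids <- sprintf("c%02d_r%03d", i, seq_len(n_replicates[i]))
    reps[[i]] <- data.frame(replicate_id = ids, condition_id = conds$condition_id[i],
                            hypermutator = FALSE)
    evs[[i]] <- data.frame(replicate_id = ids, condition_id = conds$condition_id[i],
                           site = sprintf("s%05d", site_counter + seq_along(ids)),
                           mutation_type = "SNP", position = NA_integer_,
                           stringsAsFactors = FALSE)
    site_counter <- site_counter + length(ids)
  }
  new_compendium(conds, do.call(rbind, reps), do.call(rbind, evs))
}

`%||%` <- evoforecast:::`%||%`

withr_like_tempdir <- function() {
  d <- tempfile("evoforecast-test-")
  dir.create(d)
  d
}

## independent reference entropy (bits) for a Bernoulli(p)
binary_entropy_ref <- function(p) {
  vapply(p, function(q) {
    if (q <= 0 || q >= 1) return(0)
    -q * log2(q) - (1 - q) * log2(1 - q)
  }, numeric(1))
}
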