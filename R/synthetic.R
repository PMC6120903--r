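#' Parameters of the synthetic-compendium generator
#'
#' The generator emulates the structure of a curated ALE mutation compendium:
#' conditions described by strain/medium/stress/duration attributes with 1 to
#' 115 replicates each; per-replicate mutation counts accumulating
#' Poisson-like with generations at a background fixation rate; a
#' condition-specific shared core of genes that each fix independently in
#' every replicate (the deterministic component of evolution); optional
#' planted condition-attribute-to-gene associations; a hypermutator
#' subpopulation with a multiplied rate biased toward a designated
#' DNA-maintenance gene set; and a mutation-type mixture matching the
#' empirical compendium composition (SNP 57%, deletion 26%, insertion 9%,
#' amplification 8%, inversion ~0%).
#'
#' @param seed integer seed; every draw derives from it.
#' @param n_genes,genome_length,coding_fraction,gene_sdlog annotation shape:
#'   log-normal gene lengths scaled so genes cover `coding_fraction` (0.86)
#'   of the genome.
#' @param n_conditions number of distinct culture conditions.
#' @param replicate_counts explicit per-condition replicate counts (recycled),
#'   or `NULL` to draw from a negative-binomial (support 1-115, mean ~3).
#' @param strains,media,stresses attribute vocabularies.
#' @param stress_count_probs probabilities of a condition having 0, 1, 2, ...
#'   stresses.
#' @param generations_choices,generations_probs duration distribution.
#' @param lambda background fixation rate, mutations per genome per
#'   generation (0.0068, the compendium-wide median for normal clones).
#' @param core_size,core_prob size `S` of each condition's shared core and
#'   per-replicate fixation probability `q` of each core gene.
#' @param associations optional data.frame (`attribute`, `gene`, `prob`)
#'   planting condition-attribute-specific gene targets, e.g.
#'   `"stress:osmotic"`.
#' @param hypermutator_fraction,hypermutator_multiplier fraction of
#'   replicates with a mutator phenotype and their rate multiplier (40x the
#'   background rate clears the 0.1/generation classification threshold).
#' @param n_dna_genes,mutator_dna_bias size of the designated DNA-maintenance
#'   gene set and the factor by which hypermutator background mutations are
#'   biased toward it.
#' @param type_mix named probability vector over the five mutation types.
#' @return object of class `synthetic_params` (a validated list).
#' @export
synthetic_params <- function(seed = 1,
                             n_genes = 4000,
                             genome_length = 4641652,
                             coding_fraction = 0.86,
                             gene_sdlog = 0.45,
                             n_conditions = 178,
                             replicate_counts = NULL,
                             strains = c("MG1655", "BW25113", "W3110", "REL606", "B", "DH10B"),
                             media = c("LB", "M9 glucose", "M9 glycerol",
                                       "MOPS glucose", "M9 acetate", "LB low-salt"),
                             stresses = c("antibiotic", "osmotic", "acid", "heat",
                                          "anaerobic", "oxidative", "butanol",
                                          "ethanol", "alkaline", "cold"),
                             stress_count_probs = c(0.15, 0.6, 0.25),
                             generations_choices = c(500, 1000, 2000, 5000, 10000,
                                                     20000, 30000, 40000),
                             generations_probs = c(0.45, 0.2, 0.12, 0.1, 0.06,
                                                   0.04, 0.02, 0.01),
                             lambda = 0.0068,
                             core_size = 6,
                             core_prob = 0.4,
                             associations = NULL,
                             hypermutator_fraction = 36 / 574,
                             hypermutator_multiplier = 40,
                             n_dna_genes = 30,
                             mutator_dna_bias = 3,
                             type_mix = c(SNP = 0.57, deletion = 0.26,
                                          insertion = 0.09, amplification = 0.08,
                                          inversion = 0)) {
  p <- as.list(environment())
  if (p$n_genes < 2) stopf("n_genes must be >= 2")
  if (p$lambda <= 0) stopf("lambda must be positive")
  if (abs(sum(p$type_mix) - 1) > 1e-8) stopf("type_mix must sum to 1")
  if (!all(names(p$type_mix) %in% MUTATION_TYPES)) stopf("unknown mutation type in type_mix")
  probs <- c(p$core_prob, p$hypermutator_fraction, p$stress_count_probs,
             p$generations_probs, unname(p$type_mix))
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (length(p$generations_probs) != length(p$generations_choices))
    stopf("generations_probs must match generations_choices")
  if (!is.null(p$replicate_counts) &&
      (any(p$replicate_counts < 1) || any(p$replicate_counts > 115)))
    stopf("replicate counts must lie in 1..115")
  if (!is.null(p$associations)) {
    need <- c("attribute", "gene", "prob")
    if (!is.data.frame(p$associations) || !all(need %in% names(p$associations)))
      stopf("associations must be a data.frame with attribute, gene, prob")
  }
  structure(p, class = "synthetic_params")
}

#' @export
print.synthetic_params <- function(x, ...) {
  cat(sprintf("synthetic_params: %d genes / %d bp, %d conditions, lambda=%g, core %dx q=%g, seed %d\n",
              x$n_genes, x$genome_length, x$n_conditions, x$lambda,
              x$core_size, x$core_prob, x$seed))
  invisible(x)
}

#' Read generator parameters from a YAML file
#'
#' The packaged `synthetic_default.yaml` documents every field; values in the
#' file override [synthetic_params()] defaults.
#'
#' @param path YAML file.
#' @return a `synthetic_params` object.
#' @export
read_synthetic_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$type_mix)) vals$type_mix <- unlist(vals$type_mix)
  if (!is.null(vals$associations)) {
    vals$associations <- as.data.frame(vals$associations, stringsAsFactors = FALSE)
  }
  do.call(synthetic_params, vals)
}

#' Generate a synthetic genome annotation
#'
#' Non-overlapping, ordered genes with log-normal lengths scaled to the
#' configured coding fraction of the genome; the remaining bases are spread
#' over intergenic gaps. About a third of the genes also receive a b-number
#' style alias in the synonym map. Deterministic given the seed.
#'
#' @param params a [synthetic_params()] object.
#' @return a [genome_annotation].
#' @export
make_annotation <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  n <- params$n_genes
  L <- params$genome_length
  local_seed(params$seed, {
    target_mean <- params$coding_fraction * L / n
    lens <- rlnorm(n, meanlog = log(target_mean) - params$gene_sdlog^2 / 2,
                   sdlog = params$gene_sdlog)
    lens <- pmax(30L, as.integer(round(lens * (params$coding_fraction * L) / sum(lens))))
    slack <- L - sum(lens)
    if (slack < n + 1) stopf("genes do not fit: increase genome_length or reduce n_genes")
    gaps <- as.integer(rmultinom(1, slack - (n + 1), rep(1, n + 1))) + 1L
    starts <- integer(n)
    starts[1] <- gaps[1] + 1L
    if (n > 1) for (i in 2:n) starts[i] <- starts[i - 1] + lens[i - 1] + gaps[i]
    ends <- starts + lens - 1L
    if (ends[n] > L) stopf("genes do not fit the genome")
    names_ <- sprintf("g%04d", seq_len(n))
    alias_ix <- sort(sample(n, floor(n / 3)))
    syn <- setNames(names_[alias_ix], sprintf("b%04d", alias_ix))
    genome_annotation(data.frame(name = names_, start = starts, end = ends),
                      genome_length = L, synonyms = syn)
  })
}

#' Expected averaged mutation frequency under the planted model
#'
#' Exact (numerically evaluated) expectation of the averaged frequency `F`
#' for one condition of the generator's model: `S` shared-core genes fixing
#' independently with probabilities `fix_probs` in each of `N` replicates,
#' plus a Poisson(`background_mean`) number of background singleton mutations
#' per replicate (assumed non-colliding). The core contribution is enumerated
#' by dynamic programming over the joint distribution of (total core
#' presences, distinct core genes) and the background is integrated with a
#' truncated Poisson sum; conditions with no mutation at all are excluded, as
#' in the empirical estimator.
#'
#' @param N number of replicates.
#' @param fix_probs per-gene fixation probabilities of the shared core
#'   (vector; may be empty).
#' @param background_mean expected background mutations per replicate
#'   (`lambda * generations`).
#' @return expected value of `F` (numeric scalar).
#' @export
expected_overlap_f <- function(N, fix_probs, background_mean) {
  S <- length(fix_probs)
  # DP over (t = sum of core counts, d = distinct core genes)
  P <- matrix(0, nrow = S * N + 1, ncol = S + 1)
  P[1, 1] <- 1
  for (q in fix_probs) {
    newP <- matrix(0, nrow = nrow(P), ncol = ncol(P))
    pc <- dbinom(0:N, N, q)
    for (c in 0:N) {
      w <- pc[c + 1]
      if (w == 0) next
      src <- P * w
      if (c == 0) newP <- newP + src
      else {
        rows <- seq_len(nrow(P) - c)
        newP[rows + c, -1] <- newP[rows + c, -1] + src[rows, -ncol(P)]
        # d increments by exactly 1 when c > 0
      }
    }
    P <- newP
  }
  mu <- N * background_mean
  Bmax <- max(20, qpois(1 - 1e-13, mu) + 10)
  pb <- dpois(0:Bmax, mu)
  # E[(t+B)/(d+B)] = 1 + (t-d) * E[1/(d+B)]
  inv_mom <- vapply(0:S, function(d) sum(pb / (d + 0:Bmax + (d == 0 & 0:Bmax == 0))) -
                      if (d == 0) pb[1] else 0, numeric(1))
  # for d = 0 the B = 0 atom is excluded (no mutations at all); its f-value
  # placeholder above contributes pb[1]/1 which we subtract back out
  total <- 0
  norm <- 0
  for (d in 0:S) {
    col <- P[, d + 1]
    ts <- which(col > 0) - 1L
    if (!length(ts)) next
    for (t in ts) {
      w <- col[t + 1L]
      if (d == 0) {
        # t must be 0 here; F = 1/N for any B >= 1
        total <- total + w * (1 - pb[1]) * (1 / N)
        norm <- norm + w * (1 - pb[1])
      } else {
        ef <- (1 + (t - d) * inv_mom[d + 1]) / N
        total <- total + w * ef
        norm <- norm + w
      }
    }
  }
  total / norm
}

#' Expected F-versus-1/N law for a generated design
#'
#' Computes the exact model-implied expectation of the averaged frequency for
#' every condition with at least two replicates, aggregates by replicate
#' count (mean over conditions sharing an `N`, matching the estimator) and
#' fits the same ordinary least squares of `F` on `1/N`, giving the analytic
#' intercept and slope that a correct pipeline should recover.
#'
#' @param n_replicates integer vector of per-condition replicate counts.
#' @param fix_prob_list list of per-condition core fixation-probability
#'   vectors (recycled if length 1).
#' @param background_means per-condition `lambda * generations` (recycled).
#' @return list with `by_condition`, `by_n`, `intercept`, `slope`.
#' @export
expected_f_law <- function(n_replicates, fix_prob_list, background_means) {
  n_cond <- length(n_replicates)
  if (!is.list(fix_prob_list)) fix_prob_list <- list(fix_prob_list)
  fix_prob_list <- rep_len(fix_prob_list, n_cond)
  background_means <- rep_len(background_means, n_cond)
  keep <- n_replicates >= 2
  ef <- vapply(which(keep), function(i)
    expected_overlap_f(n_replicates[i], fix_prob_list[[i]], background_means[i]),
    numeric(1))
  by_condition <- data.frame(n_replicates = n_replicates[keep], expected_F = ef)
  agg <- aggregate(expected_F ~ n_replicates, data = by_condition, FUN = mean)
  fit <- lm(expected_F ~ I(1 / n_replicates), data = agg)
  list(by_condition = by_condition, by_n = agg,
       intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Generate a synthetic mutation compendium with planted ground truth
#'
#' Draws conditions (unique strain/medium/stress combinations), replicates,
#' and mutation events under the model described in [synthetic_params()]:
#' per-replicate event counts are Poisson(`lambda * generations *
#' multiplier`) background mutations assigned to genes proportionally to
#' length, plus each condition's shared-core genes fixing independently with
#' probability `core_prob` and any planted attribute-association genes fixing
#' with their own probabilities. Hypermutator replicates use the multiplied
#' rate and length weights biased toward the DNA-maintenance gene set.
#'
#' @param params a [synthetic_params()] object.
#' @return list with `compendium`, `annotation` and `ground_truth` (planted
#'   propensities, condition cores, associations, hypermutator labels, the
#'   expected per-replicate event counts, and the analytic F-law when no
#'   hypermutators are planted).
#' @export
make_compendium <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  annotation <- make_annotation(params)
  genes <- annotation$genes$name
  glen <- annotation$genes$end - annotation$genes$start + 1
  local_seed(params$seed + 1L, {
    dna_genes <- sort(sample(genes, min(params$n_dna_genes, length(genes))))

    ## conditions: unique attribute combinations
    draw_condition <- function() {
      ns <- sample(seq_along(params$stress_count_probs), 1,
                   prob = params$stress_count_probs) - 1L
      list(strain = sample(params$strains, 1),
           medium = sample(params$media, 1),
           stresses = if (ns > 0) sort(sample(params$stresses, ns)) else character(0))
    }
    seen <- character(0)
    conds <- list()
    tries <- 0
    while (length(conds) < params$n_conditions) {
      tries <- tries + 1
      if (tries > 200 * params$n_conditions)
        stopf("cannot draw %d unique conditions from the vocabulary", params$n_conditions)
      cd <- draw_condition()
      key <- paste(cd$strain, cd$medium, join_stresses(cd$stresses), sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      conds[[length(conds) + 1L]] <- cd
    }
    n_cond <- length(conds)
    cond_ids <- sprintf("cond%03d", seq_len(n_cond))
    gens <- params$generations_choices[sample.int(length(params$generations_choices),
                                                  n_cond, replace = TRUE,
                                                  prob = params$generations_probs)]
    conditions <- data.frame(
      condition_id = cond_ids,
      strain = vapply(conds, `[[`, character(1), "strain"),
      medium = vapply(conds, `[[`, character(1), "medium"),
      stresses = vapply(conds, function(x) join_stresses(x$stresses), character(1)),
      generations = gens, stringsAsFactors = FALSE)

    ## planted structure: shared cores and attribute associations
    cores <- lapply(seq_len(n_cond), function(i) sort(sample(genes, params$core_size)))
    names(cores) <- cond_ids
    fix_probs <- lapply(seq_len(n_cond), function(i) {
      fp <- setNames(rep(params$core_prob, params$core_size), cores[[i]])
      if (!is.null(params$associations)) {
        attrs <- c(paste0("strain:", conditions$strain[i]),
                   paste0("medium:", conditions$medium[i]),
                   paste0("stress:", split_stresses(conditions$stresses[i])[[1]]))
        hit <- params$associations[params$associations$attribute %in% attrs, , drop = FALSE]
        for (j in seq_len(nrow(hit))) {
          g <- as.character(hit$gene[j])
          fp[g] <- max(fp[g], hit$prob[j], na.rm = TRUE)
        }
      }
      fp
    })
    names(fix_probs) <- cond_ids

    n_reps <- if (!is.null(params$replicate_counts))
      rep_len(as.integer(params$replicate_counts), n_cond)
    else pmin(1L + rnbinom(n_cond, size = 0.55, mu = 2.2), 115L)

    rep_rows <- list()
    ev_rep <- list(); ev_cond <- list(); ev_gene <- list()
    for (i in seq_len(n_cond)) {
      ids <- sprintf("%s_r%03d", cond_ids[i], seq_len(n_reps[i]))
      hyper <- runif(n_reps[i]) < params$hypermutator_fraction
      rep_rows[[i]] <- data.frame(replicate_id = ids, condition_id = cond_ids[i],
                                  hypermutator = hyper, stringsAsFactors = FALSE)
      fp <- fix_probs[[i]]
      for (r in seq_len(n_reps[i])) {
        fixed <- names(fp)[runif(length(fp)) < fp]
        mult <- if (hyper[r]) params$hypermutator_multiplier else 1
        w <- glen
        if (hyper[r]) w[genes %in% dna_genes] <- w[genes %in% dna_genes] * params$mutator_dna_bias
        n_bg <- rpois(1, params$lambda * gens[i] * mult)
        bg <- if (n_bg > 0) sample(genes, n_bg, replace = TRUE, prob = w) else character(0)
        hit <- c(fixed, bg)
        if (!length(hit)) next
        ev_rep[[length(ev_rep) + 1L]] <- rep(ids[r], length(hit))
        ev_cond[[length(ev_cond) + 1L]] <- rep(cond_ids[i], length(hit))
        ev_gene[[length(ev_gene) + 1L]] <- hit
      }
    }
    replicates <- do.call(rbind, rep_rows)
    gene_vec <- unlist(ev_gene) %||% character(0)
    gi <- match(gene_vec, genes)
    n_ev <- length(gene_vec)
    types <- if (n_ev) sample(names(params$type_mix), n_ev, replace = TRUE,
                              prob = params$type_mix) else character(0)
    positions <- if (n_ev)
      as.integer(floor(runif(n_ev, annotation$genes$start[gi],
                             annotation$genes$end[gi] + 1))) else integer(0)
    events <- data.frame(replicate_id = unlist(ev_rep) %||% character(0),
                         condition_id = unlist(ev_cond) %||% character(0),
                         site = gene_vec, mutation_type = types,
                         position = positions, stringsAsFactors = FALSE)

    ## drop replicates that ended up with no events and no flag: they are not
    ## representable in the tabular exchange format
    has_event <- replicates$replicate_id %in% events$replicate_id
    replicates <- replicates[has_event | replicates$hypermutator, , drop = FALSE]

    compendium <- new_compendium(conditions, replicates, events)
    bmeans <- params$lambda * gens
    expected_events <- vapply(seq_len(n_cond),
                              function(i) sum(fix_probs[[i]]) + bmeans[i], numeric(1))
    law <- if (params$hypermutator_fraction == 0 && any(n_reps >= 2))
      expected_f_law(n_reps, fix_probs, bmeans) else NULL
    ground_truth <- list(
      gene_lengths = setNames(glen, genes),
      dna_genes = dna_genes,
      cores = cores,
      fix_probs = fix_probs,
      associations = params$associations,
      hypermutators = replicates$replicate_id[replicates$hypermutator],
      lambda = params$lambda,
      core_size = params$core_size,
      core_prob = params$core_prob,
      n_replicates = setNames(n_reps, cond_ids),
      expected_events_per_replicate = setNames(expected_events, cond_ids),
      type_mix = params$type_mix,
      expected_f_law = law)
    list(compendium = compendium, annotation = annotation,
         ground_truth = ground_truth)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Materializes a [make_compendium()] result as the standard exchange files:
#' `events.tsv`, `conditions.tsv`, `annotation.gff3`, `ground_truth.json` and
#' `params.yaml`.
#'
#' @param sim result of [make_compendium()].
#' @param dir output directory (created if missing).
#' @param params the `synthetic_params` used (optional, for `params.yaml`).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_compendium(sim$compendium, file.path(dir, "events.tsv"),
                   file.path(dir, "conditions.tsv"))
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  gt <- sim$ground_truth
  gt$expected_f_law <- gt$expected_f_law[c("intercept", "slope", "by_n")]
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(params)) {
    pl <- unclass(params)
    pl$type_mix <- as.list(pl$type_mix)  # keep names through YAML
    yaml::write_yaml(pl, file.path(dir, "params.yaml"))
  }
  invisible(dir)
}
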