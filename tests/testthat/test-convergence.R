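test_that("fixation series counts events per replicate against generations", {
  comp <- set_compendium(list(c("a", "b", "c"), "a"), generations = 500)
  ser <- fixation_series(comp)
  expect_identical(ser$n_mutations[ser$replicate_id == "r01"], 3L)
  expect_identical(ser$generations, c(500, 500))
  expect_equal(ser$rate[1], 3 / 500)
  # Poisson accumulation: sample mean rate within 3 SE of lambda (n = 300)
  p <- synthetic_params(seed = 77, n_genes = 500, genome_length = 700000,
                        n_conditions = 100, replicate_counts = 3,
                        core_size = 0, lambda = 0.02,
                        generations_choices = 1000, generations_probs = 1,
                        hypermutator_fraction = 0)
  sim <- make_compendium(p)
  ser2 <- fixation_series(sim$compendium)
  lam_hat <- mean(ser2$rate)
  se <- sd(ser2$rate) / sqrt(nrow(ser2))
  expect_lt(abs(lam_hat - 0.02), 3 * se)
})

test_that("fixation fits recover noiseless and noisy trends", {
  # exact line: R^2 = 1 and exact coefficients
  g <- seq(100, 2000, by = 100)
  ser <- data.frame(replicate_id = as.character(seq_along(g)),
                    condition_id = "c", generations = g,
                    n_mutations = 2 + 0.01 * g, rate = (2 + 0.01 * g) / g,
                    hypermutator = FALSE)
  fit <- fit_fixation(ser, "linear")
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients), c(2, 0.01))

  # exponential recovery: planted b = 1.2e-4 with 10% multiplicative noise
  set.seed(5)
  g2 <- runif(200, 100, 20000)
  n2 <- 5.6 * exp(1.2e-4 * g2) * exp(rnorm(200, 0, 0.1))
  ser2 <- data.frame(replicate_id = as.character(seq_along(g2)),
                     condition_id = "c", generations = g2,
                     n_mutations = n2, rate = n2 / g2, hypermutator = FALSE)
  fit2 <- fit_fixation(ser2, "exponential")
  expect_lt(abs(fit2$coefficients[["rate"]] - 1.2e-4) / 1.2e-4, 0.15)
  expect_error(fit_fixation(transform(ser2, n_mutations = 0), "exponential"),
               "all counts are zero")
})

test_that("hypermutator classification uses a strict 0.1 threshold", {
  expect_identical(classify_hypermutator(c(0.26, 0.0068, 0.1, 0.1000001)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_hypermutator(-0.1), "non-negative")
})

test_that("overlap ratios follow their definitions and edge conventions", {
  # all replicates identical and nonempty: F = G = P = 1
  comp <- set_compendium(list(c("a", "b"), c("a", "b"), c("a", "b")))
  ov <- overlap_ratios(comp, "c1")
  expect_equal(c(ov$averaged_frequency, ov$global_overlap, ov$pairwise_overlap),
               c(1, 1, 1))
  # single replicate: F = G = 1, P undefined
  ov1 <- overlap_ratios(set_compendium(list(c("a", "b"))), "c1")
  expect_equal(c(ov1$averaged_frequency, ov1$global_overlap), c(1, 1))
  expect_true(is.na(ov1$pairwise_overlap))
  # the published forward-validation condition: F = 139/805
  fv <- load_forward_validation()
  ovf <- overlap_ratios(fv$compendium, "osmotic_nacl")
  expect_equal(ovf$averaged_frequency, 139 / 805)
  expect_equal(ovf$global_overlap, 139 / 805)  # F and G coincide by construction
  # empty pair convention: two empty replicates score Jaccard 1
  comp_e <- set_compendium(list(character(0), character(0), "a"))
  expect_message(ov_e <- overlap_ratios(comp_e, "c1"), "identical")
  expect_equal(ov_e$pairwise_overlap, 1 / 3)  # pairs: (e,e)=1, (e,a)=0, (e,a)=0
})

test_that("all-singleton compendia give F = 1/N and P = 0 exactly", {
  comp <- singleton_compendium(2:20)
  for (cid in comp$conditions$condition_id) {
    ov <- overlap_ratios(comp, cid)
    expect_identical(ov$averaged_frequency, 1 / ov$n_replicates)
    expect_identical(ov$pairwise_overlap, 0)
  }
  # and the fitted law recovers slope 1, intercept 0 to machine precision
  law <- overlap_vs_replicates(comp)
  expect_equal(law$f_fit$coefficients[["slope"]], 1, tolerance = 1e-12)
  expect_equal(law$f_fit$coefficients[["intercept"]], 0, tolerance = 1e-12)
  expect_equal(law$g_fit$coefficients[["slope"]], 1, tolerance = 1e-12)
})

test_that("F and G coincide and stay in [0,1] on generated compendia", {
  p <- synthetic_params(seed = 9, n_genes = 150, genome_length = 200000,
                        n_conditions = 20, replicate_counts = c(2, 3, 5, 8),
                        core_size = 3, hypermutator_fraction = 0.1)
  sim <- make_compendium(p)
  tab <- do.call(rbind, lapply(sim$compendium$conditions$condition_id,
                               overlap_ratios, compendium = sim$compendium))
  tab <- tab[!is.na(tab$averaged_frequency), ]
  expect_equal(tab$averaged_frequency, tab$global_overlap)
  expect_true(all(tab$averaged_frequency >= 0 & tab$averaged_frequency <= 1))
  expect_true(all(is.na(tab$pairwise_overlap) |
                    (tab$pairwise_overlap >= 0 & tab$pairwise_overlap <= 1)))
})

test_that("overlap_vs_replicates wants three distinct replicate counts", {
  comp <- singleton_compendium(c(2, 2, 3))
  expect_error(overlap_vs_replicates(comp), "3 distinct")
})

test_that("group comparison finds planted convergence differences", {
  # identical groups: p = 1 under the tie convention
  comp <- singleton_compendium(rep(3, 6))
  ids <- comp$conditions$condition_id
  res <- compare_groups(comp, groups = list(a = ids[1:3], b = ids[4:6]),
                        statistic = "pairwise_overlap")
  expect_equal(res$p_value, 1)

  # planted: "antibiotic" conditions get a doubled shared-fixation probability
  set.seed(23)
  n_per <- 30
  build_group <- function(prefix, q, stress) {
    conds <- data.frame(condition_id = sprintf("%s%02d", prefix, 1:n_per),
                        strain = "s", medium = "m", stresses = stress,
                        generations = 500)
    reps <- list(); evs <- list()
    for (i in 1:n_per) {
      ids <- sprintf("%s%02d_r%d", prefix, i, 1:4)
      reps[[i]] <- data.frame(replicate_id = ids, condition_id = conds$condition_id[i],
                              hypermutator = FALSE)
      core <- sprintf("%s%02d_core%d", prefix, i, 1:6)
      evs[[i]] <- do.call(rbind, lapply(seq_along(ids), function(r) {
        hit <- c(core[rbinom(6, 1, q) == 1], sprintf("%s_priv_%d_%d", ids[r], r, 1:2))
        data.frame(replicate_id = ids[r], condition_id = conds$condition_id[i],
                   site = hit, mutation_type = "SNP", position = NA_integer_)
      }))
    }
    list(conds = conds, reps = do.call(rbind, reps), evs = do.call(rbind, evs))
  }
  g1 <- build_group("ab", 0.8, "antibiotic")
  g2 <- build_group("ns", 0.4, "")
  comp2 <- new_compendium(rbind(g1$conds, g2$conds), rbind(g1$reps, g2$reps),
                          rbind(g1$evs, g2$evs))
  res2 <- compare_groups(comp2,
                         groups = list(antibiotic = g1$conds$condition_id,
                                       none = g2$conds$condition_id),
                         statistic = "pairwise_overlap")
  means <- setNames(res2$group_stats$mean, res2$group_stats$group)
  expect_gt(means[["antibiotic"]], means[["none"]])
  expect_lt(res2$p_value, 0.01)
})

test_that("DNA-gene fraction split recovers the planted direction", {
  p <- synthetic_params(seed = 31, n_genes = 200, genome_length = 250000,
                        n_conditions = 40, replicate_counts = 4, core_size = 0,
                        lambda = 0.004, generations_choices = 500,
                        generations_probs = 1, hypermutator_fraction = 0.5,
                        hypermutator_multiplier = 4, n_dna_genes = 40,
                        mutator_dna_bias = 4)
  sim <- make_compendium(p)
  # treat every replicate as "normal" so the rate split is the planted one:
  # high-rate replicates are exactly the biased (flagged) ones
  comp <- sim$compendium
  flagged <- comp$replicates$hypermutator
  comp$replicates$hypermutator <- FALSE
  res <- compare_groups(comp, statistic = "dna_gene_fraction",
                        dna_genes = sim$ground_truth$dna_genes)
  means <- setNames(res$group_stats$mean, res$group_stats$group)
  expect_gt(means[["high_rate"]], means[["low_rate"]])
})
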