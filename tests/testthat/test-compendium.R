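test_that("site-name normalization resolves aliases, orders flanks and is idempotent", {
  ann <- tiny_annotation()
  expect_identical(normalize_site_name("b3642", ann), "rph")
  expect_identical(normalize_site_name("rph", ann), "rph")
  # intergenic pair rendered in genome coordinate order, either way round
  expect_identical(normalize_site_name("pyrE-rph", ann), "pyrE-rph")
  expect_identical(normalize_site_name("rph-pyrE", ann), "pyrE-rph")
  expect_identical(normalize_site_name("rph-b0064", ann), "araC-rph")
  # IS tagging with the fixed separator
  expect_identical(normalize_site_name("pykF", ann, is_element = "IS5"), "pykF::IS5")
  expect_identical(normalize_site_name("b1676", ann, is_element = "IS5"), "pykF::IS5")
  expect_error(normalize_site_name("nonGene", ann), "not found")
  expect_error(normalize_site_name("", ann), "non-empty")

  # idempotence on every canonical output, including tagged and intergenic
  canon <- c("rph", "pyrE-rph", "araC-rph", "pykF::IS5", "pyrE-rph::IS1")
  for (s in canon) expect_identical(normalize_site_name(s, ann), s)
})

test_that("deletion spans expand to covered genes, orientation-insensitive", {
  ann <- tiny_annotation()
  expect_identical(expand_deletion_span("araC", "rph", ann),
                   c("araC", "pykF", "pyrE", "rph"))
  expect_identical(expand_deletion_span("rph", "araC", ann),
                   c("araC", "pykF", "pyrE", "rph"))
  expect_identical(expand_deletion_span("pykF", "pykF", ann), "pykF")
  expect_error(expand_deletion_span("missing", "rph", ann), "not found")
})

test_that("duration bins are left-exclusive right-inclusive with a hard ceiling", {
  expect_identical(duration_bin(c(1, 500, 501, 1000, 40000)),
                   c("(0,500]", "(0,500]", "(500,1000]", "(500,1000]",
                     "(30000,40000]"))
  expect_error(duration_bin(40001), "above")
  expect_error(duration_bin(0), "positive")
})

test_that("condition encoding is one-hot per category, multi-hot on stress", {
  vocab <- condition_vocabulary(data.frame(
    strain = c("MG1655", "BW25113"), medium = c("M9 glucose", "LB"),
    stresses = c("osmotic;acid", "heat")))
  desc <- list(strain = "MG1655", medium = "M9 glucose",
               stresses = "osmotic", generations = 500)
  v <- encode_condition(desc, vocab)
  expect_length(v, 2 + 2 + 3 + 7)
  on_bits <- names(v)[v == 1]
  expect_setequal(on_bits, c("strain:MG1655", "medium:M9 glucose",
                             "stress:osmotic", "duration:(0,500]"))
  # determinism
  expect_identical(encode_condition(desc, vocab), v)
  # duration boundary flips the bin bit only
  v501 <- encode_condition(modifyList(desc, list(generations = 501)), vocab)
  expect_identical(unname(v501["duration:(500,1000]"]), 1L)
  expect_identical(unname(v501["duration:(0,500]"]), 0L)
  expect_error(encode_condition(modifyList(desc, list(stresses = "vacuum")), vocab),
               "vacuum")
  expect_error(encode_condition(modifyList(desc, list(strain = "K12")), vocab),
               "strain")
})

test_that("condition encoding invariants hold across random descriptors", {
  vocab <- condition_vocabulary(data.frame(
    strain = c("A", "B", "C"), medium = c("m1", "m2", "m3"),
    stresses = c("s1;s2", "s3", "s4;s5")))
  set.seed(42)
  for (i in 1:25) {
    desc <- list(strain = sample(vocab$strains, 1),
                 medium = sample(vocab$media, 1),
                 stresses = sample(vocab$stresses, sample(0:3, 1)),
                 generations = sample(c(1, 499, 500, 5000, 39999), 1))
    v <- encode_condition(desc, vocab)
    expect_identical(sum(v[startsWith(names(v), "strain:")]), 1L)
    expect_identical(sum(v[startsWith(names(v), "medium:")]), 1L)
    expect_identical(sum(v[startsWith(names(v), "duration:")]), 1L)
    expect_identical(sum(v[startsWith(names(v), "stress:")]),
                     length(unique(desc$stresses)))
  }
})

test_that("tabular round trip is lossless and byte-identical for canonical files", {
  p <- synthetic_params(seed = 3, n_genes = 60, genome_length = 80000,
                        n_conditions = 8, replicate_counts = 3,
                        core_size = 2, hypermutator_fraction = 0.2)
  sim <- make_compendium(p)
  d <- withr_like_tempdir()
  write_compendium(sim$compendium, file.path(d, "events.tsv"),
                   file.path(d, "conditions.tsv"))
  comp2 <- load_compendium(file.path(d, "events.tsv"),
                           file.path(d, "conditions.tsv"), sim$annotation)
  expect_identical(comp2$events, sim$compendium$events)
  expect_identical(comp2$conditions, sim$compendium$conditions)
  expect_identical(comp2$site_index, sim$compendium$site_index)
  expect_setequal(comp2$replicates$replicate_id, sim$compendium$replicates$replicate_id)
  # write(load(x)) reproduces the canonical files byte for byte
  write_compendium(comp2, file.path(d, "e2.tsv"), file.path(d, "c2.tsv"))
  expect_identical(readLines(file.path(d, "e2.tsv")),
                   readLines(file.path(d, "events.tsv")))
  expect_identical(readLines(file.path(d, "c2.tsv")),
                   readLines(file.path(d, "conditions.tsv")))
})

test_that("loader normalizes sites, expands spans and validates hard", {
  ann <- tiny_annotation()
  d <- withr_like_tempdir()
  writeLines(c("condition_id\tstrain\tmedium\tstresses\tgenerations\thypermutator_ids",
               "c1\tMG1655\tLB\t\t500\t"),
             file.path(d, "conditions.tsv"))
  ev_lines <- c(
    "replicate_id\tcondition_id\tsite_raw\tmutation_type\tposition\tis_element\tflank_a\tflank_b",
    "r1\tc1\tb3642\tSNP\t1510\t\t\t",             # alias -> rph
    "r1\tc1\trph-pyrE\tSNP\t1450\t\t\t",          # flank order fixed
    "r2\tc1\tpykF\tinsertion\t400\tIS5\t\t",      # IS tag appended
    "r2\tc1\t\tdeletion\t\t\tpyrE\taraC")         # span -> araC,pykF,pyrE
  writeLines(ev_lines, file.path(d, "events.tsv"))
  comp <- load_compendium(file.path(d, "events.tsv"), file.path(d, "conditions.tsv"), ann)
  expect_identical(attr(comp, "n_input_rows"), 4L)
  expect_identical(attr(comp, "n_expanded_rows"), 6L)  # 3 plain + 3 from the span
  expect_setequal(compendium_sites(comp),
                  c("rph", "pyrE-rph", "pykF::IS5", "araC", "pykF", "pyrE"))

  # unknown condition names the row; malformed type and bad alias are hard errors
  writeLines(c(ev_lines[1], "r1\tcX\trph\tSNP\t\t\t\t"), file.path(d, "bad1.tsv"))
  expect_error(load_compendium(file.path(d, "bad1.tsv"), file.path(d, "conditions.tsv"), ann),
               "row 1.*cX")
  writeLines(c(ev_lines[1], "r1\tc1\trph\tSNV\t\t\t\t"), file.path(d, "bad2.tsv"))
  expect_error(load_compendium(file.path(d, "bad2.tsv"), file.path(d, "conditions.tsv"), ann),
               "mutation_type")
  writeLines(c(ev_lines[1], "r1\tc1\tzzz9\tSNP\t\t\t\t"), file.path(d, "bad3.tsv"))
  expect_error(load_compendium(file.path(d, "bad3.tsv"), file.path(d, "conditions.tsv"), ann),
               "zzz9")

  # empty events + one condition: valid empty compendium
  writeLines(ev_lines[1], file.path(d, "empty.tsv"))
  comp0 <- load_compendium(file.path(d, "empty.tsv"), file.path(d, "conditions.tsv"), ann)
  expect_identical(nrow(comp0$events), 0L)
  expect_identical(nrow(comp0$conditions), 1L)
  expect_length(comp0$site_index, 0L)
  s0 <- summarize_compendium(comp0)
  expect_identical(s0$n_events, 0L)
  expect_identical(sum(s0$type_counts), 0L)
})

test_that("merging replicates is a type-blind set union", {
  comp <- set_compendium(list(c("g1", "g2"), c("g2", "g3")))
  prof <- merge_replicates(comp, "c1")
  expect_identical(prof, c(g1 = 1L, g2 = 1L, g3 = 1L))
  # one replicate: profile equals its own site set
  comp1 <- set_compendium(list(c("g1", "g3")))
  expect_identical(merge_replicates(comp1, "c1"), c(g1 = 1L, g3 = 1L))
  # SNP in one replicate, deletion in another: one bit
  comp2 <- set_compendium(list("g1", "g1"), types = c("SNP"))
  comp2$events$mutation_type <- c("SNP", "deletion")
  expect_identical(sum(merge_replicates(comp2, "c1")), 1L)
  expect_error(merge_replicates(comp, "nope"), "unknown condition")
})

test_that("summary counts are consistent and invariant to replicate order", {
  p <- synthetic_params(seed = 8, n_genes = 50, genome_length = 70000,
                        n_conditions = 6, replicate_counts = 4, core_size = 2)
  sim <- make_compendium(p)
  s <- summarize_compendium(sim$compendium)
  expect_identical(sum(s$type_counts), s$n_events)
  expect_identical(s$n_coding_sites + s$n_intergenic_sites, s$n_sites)
  expect_identical(s$n_events, nrow(sim$compendium$events))
  # reorder events: same summary
  comp_r <- sim$compendium
  set.seed(1)
  perm <- sample(nrow(comp_r$events))
  comp_r <- new_compendium(comp_r$conditions, comp_r$replicates,
                           comp_r$events[perm, ])
  s2 <- summarize_compendium(comp_r)
  expect_identical(s2$type_counts, s$type_counts)
  expect_identical(s2$n_sites, s$n_sites)
})

test_that("the packaged forward-validation table parses to its published margins", {
  fv <- load_forward_validation()
  expect_identical(nrow(fv$table), 23L)
  expect_identical(length(unique(fv$table$site)), 23L)
  tc <- table(fv$table$mutation_type)
  expect_identical(as.integer(tc[c("SNP", "insertion", "deletion")]),
                   c(15L, 3L, 5L))
  expect_identical(max(fv$table$n_replicates), 34L)
  expect_identical(fv$table$n_replicates[fv$table$site == "rph"], 27L)
  expect_identical(sum(fv$table$n_replicates), 139L)
  # materialized compendium carries the same sites over 35 replicate lines
  expect_identical(length(compendium_sites(fv$compendium)), 23L)
  expect_identical(nrow(fv$compendium$replicates), 35L)
})
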