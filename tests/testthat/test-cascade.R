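simple_network <- function(disease = "G1",
                           edges = tibble::tibble(regulator = character(),
                                                  target = character())) {
  gene_network(edges, disease)
}

test_that("confidence filter applies the quality threshold per carrier group", {
  cfg <- cascade_config()
  # both case carriers at exactly 20.0: the threshold is inclusive
  v_ok <- mk_variant(gts = c("0/0", "0/1", "0/1"), quals = c(5, 20, 20))
  expect_true(confidence_filter(v_ok, trio_ped(), cfg)$kept)
  # all carrier qualities just below: removed
  v_low <- mk_variant(gts = c("0/0", "0/1", "0/1"), quals = c(50, 19.9, 19.9))
  dec_low <- confidence_filter(v_low, trio_ped(), cfg)
  expect_false(dec_low$kept)
  expect_equal(dec_low$reason, "low call quality")
  # case carriers low but a confident control carrier: group rule matters
  v_mix <- mk_variant(gts = c("0/1", "0/1", "0/1"), quals = c(25, 10, 10))
  expect_true(confidence_filter(v_mix, trio_ped(), cfg)$kept)
  cfg_and <- cascade_config(quality_group_rule = "all_groups")
  expect_false(confidence_filter(v_mix, trio_ped(), cfg_and)$kept)
  # carrier qualities all missing: no usable information
  v_na <- mk_variant(gts = c("0/0", "0/1", "0/1"), quals = c(50, NA, NA))
  dec_na <- confidence_filter(v_na, trio_ped(), cfg)
  expect_false(dec_na$kept)
  expect_equal(dec_na$reason, "no qualified call")
})

test_that("common-variant filter is inclusive at 3% and treats missing as rare", {
  cfg <- cascade_config()
  v <- mk_variant()
  ann_common <- mk_annotation(af_1kg = 0.031)
  expect_false(common_variant_filter(v, ann_common, cfg)$kept)
  ann_rare <- mk_annotation(af_1kg = 0.029, af_cg69 = 0.029, af_esp = 0.029)
  expect_true(common_variant_filter(v, ann_rare, cfg)$kept)
  ann_missing <- mk_annotation()
  expect_true(common_variant_filter(v, ann_missing, cfg)$kept)
  # any single panel at the cutoff removes the variant
  ann_esp <- mk_annotation(af_esp = 0.03)
  expect_false(common_variant_filter(v, ann_esp, cfg)$kept)
})

test_that("deleteriousness filter keeps evidence-bearing variants only", {
  cfg <- cascade_config()
  v <- mk_variant()
  keep_cases <- list(
    mk_annotation(consequence = "missense", sift_score = 0.010),
    mk_annotation(consequence = "missense"),  # missing SIFT does not rescue
    mk_annotation(consequence = "frameshift"),
    mk_annotation(consequence = "structural"),
    mk_annotation(clinical_assertion = "unknown_significance"),
    mk_annotation(mirna_site = TRUE),
    mk_annotation(consequence = "splice_region", splice_intron_offset = 2),
    mk_annotation(consequence = "splice_region", splice_intron_offset = -2)
  )
  for (ann in keep_cases) {
    expect_true(deleteriousness_filter(v, ann, cfg)$kept)
  }
  drop_cases <- list(
    mk_annotation(consequence = "synonymous"),
    mk_annotation(consequence = "missense", sift_score = 0.2),
    mk_annotation(consequence = "splice_region", splice_intron_offset = 3),
    mk_annotation(clinical_assertion = "benign"),
    mk_annotation()  # no annotation evidence at all
  )
  for (ann in drop_cases) {
    expect_false(deleteriousness_filter(v, ann, cfg)$kept)
  }
})

test_that("genetic filter counts case carriers at the gene level", {
  cfg <- cascade_config()
  # dominant trio pattern: kept
  v <- mk_variant(gts = c("0/0", "0/1", "0/1"))
  expect_true(genetic_model_filter(v, trio_ped(), cfg)$kept)
  # compound heterozygous: one case carrier at each of two variants of a gene
  vv <- mk_variants(
    mk_variant(pos = 100L, gts = c("0/0", "0/1", "0/0")),
    mk_variant(pos = 200L, gts = c("0/0", "0/0", "0/1"))
  )
  expect_equal(genetic_model_filter(vv, trio_ped(), cfg)$kept, c(TRUE, TRUE))
  # same two variants in different genes: only one case carrier each
  vw <- mk_variants(
    mk_variant(pos = 100L, gene = "G1", gts = c("0/0", "0/1", "0/0")),
    mk_variant(pos = 200L, gene = "G2", gts = c("0/0", "0/0", "0/1"))
  )
  dec <- genetic_model_filter(vw, trio_ped(), cfg)
  expect_equal(dec$kept, c(FALSE, FALSE))
  expect_equal(unique(dec$reason), "insufficient case carriers at gene level")
  # a control carrier removes the variant regardless of case carriers
  v_ctl <- mk_variant(gts = c("0/1", "0/1", "0/1"))
  dec_ctl <- genetic_model_filter(v_ctl, trio_ped(), cfg)
  expect_false(dec_ctl$kept)
  expect_equal(dec_ctl$reason, "control carrier")
  # a control carrier at v1 removes exactly v1, not its gene mate
  v_pair <- mk_variants(
    mk_variant(pos = 100L, gts = c("0/1", "0/1", "0/1")),
    mk_variant(pos = 200L, gts = c("0/0", "0/1", "0/1"))
  )
  expect_equal(genetic_model_filter(v_pair, trio_ped(), cfg)$kept,
               c(FALSE, TRUE))
  # too few cases in the pedigree is a configuration error
  small_ped <- tibble::tibble(sample = c("III-1", "III-2"),
                              role = c("control", "case"),
                              relation = c("father", "mother"))
  expect_error(genetic_model_filter(v, small_ped, cfg), "requires 2")
})

test_that("biological-context filter keeps the 1-hop disease neighbourhood", {
  net <- simple_network(
    disease = "D",
    edges = tibble::tibble(regulator = c("G1", "D"), target = c("D", "G2"))
  )
  vv <- mk_variants(
    mk_variant(pos = 100L, gene = "D"),    # disease gene itself
    mk_variant(pos = 200L, gene = "G1"),   # upstream of a disease gene
    mk_variant(pos = 300L, gene = "G2"),   # downstream target
    mk_variant(pos = 400L, gene = "G3"),   # isolated
    mk_variant(pos = 500L, gene = NA_character_)
  )
  dec <- biological_context_filter(vv, net)
  expect_equal(dec$kept, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(dec$reason[5], "no gene")
})

test_that("the cascade recovers the planted variant and keeps a full trace", {
  sim <- simulate_trio(trio_sim_spec(n_background = 500, seed = 17))
  res <- run_cascade(sim$variants, sim$annotations, sim$pedigree, sim$network)
  expect_true(sim$truth$variant_id %in% res$kept$variant_id)
  # conservation: every input variant is either kept through all stages or
  # removed at exactly one stage, with no later trace entries
  per_variant <- split(res$trace, res$trace$variant_id)
  expect_setequal(names(per_variant), sim$variants$variant_id)
  for (tr in per_variant) {
    n_stage <- nrow(tr)
    expect_true(all(tr$kept[-n_stage]))
    expect_equal(tr$stage, intersect(
      c("confidence", "common_variants", "deleteriousness",
        "genetic_model", "biological_context"), tr$stage
    ))
    if (!tr$kept[n_stage]) {
      expect_false(tr$variant_id[1] %in% res$kept$variant_id)
    } else {
      expect_equal(n_stage, 5L)
      expect_true(tr$variant_id[1] %in% res$kept$variant_id)
    }
  }
  # stage bookkeeping chains: removed + kept = in, and kept feeds the next
  s <- res$summary
  expect_equal(s$n_removed + s$n_kept, s$n_in)
  expect_equal(s$n_in[-1], s$n_kept[-5])
  expect_equal(s$n_kept[5], nrow(res$kept))
})

test_that("the kept set is invariant under permutation of the variant list", {
  sim <- simulate_trio(trio_sim_spec(n_background = 200, seed = 23))
  res <- run_cascade(sim$variants, sim$annotations, sim$pedigree, sim$network)
  shuffled <- sim$variants[withr::with_seed(1, sample(nrow(sim$variants))), ]
  res_shuffled <- run_cascade(shuffled, sim$annotations, sim$pedigree,
                              sim$network)
  expect_setequal(res$kept$variant_id, res_shuffled$kept$variant_id)
  expect_equal(res$summary$n_kept, res_shuffled$summary$n_kept)
})

test_that("raising the planted panel frequency removes it at stage 2 only", {
  sim <- simulate_trio(trio_sim_spec(n_background = 100, seed = 29))
  ann <- sim$annotations
  ann$af_1kg[ann$variant_id == sim$truth$variant_id] <- 0.05
  res <- run_cascade(sim$variants, ann, sim$pedigree, sim$network)
  expect_false(sim$truth$variant_id %in% res$kept$variant_id)
  tr <- res$trace[res$trace$variant_id == sim$truth$variant_id, ]
  expect_equal(tr$stage, c("confidence", "common_variants"))
  expect_equal(tr$kept, c(TRUE, FALSE))
})

test_that("an empty variant list yields an empty result", {
  sim <- simulate_trio(trio_sim_spec(n_background = 0, seed = 1))
  empty <- sim$variants[0, ]
  res <- run_cascade(empty, sim$annotations, sim$pedigree, sim$network)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(nrow(res$trace), 0L)
})

test_that("cascade results expose tidy, glance and autoplot views", {
  sim <- simulate_trio(trio_sim_spec(n_background = 100, seed = 31))
  res <- run_cascade(sim$variants, sim$annotations, sim$pedigree, sim$network)
  expect_equal(tidy(res), res$trace)
  g <- glance(res)
  expect_equal(g$n_input, 101L)
  expect_equal(g$n_kept, nrow(res$kept))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("cascade configuration rejects negative thresholds", {
  expect_error(cascade_config(quality_threshold = -1), "non-negative")
  expect_error(cascade_config(af_cutoff = NA), "non-negative")
})
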