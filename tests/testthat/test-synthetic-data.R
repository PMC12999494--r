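test_that("simulation spec validates its invariants", {
  expect_s3_class(sim_spec(), "SimulationSpec")
  expect_error(sim_spec(censor_rate = 1))
  expect_error(sim_spec(phenotype_mix = c(a = 0.5, b = 0.2)))
  expect_error(sim_spec(n_genes = 10, n_up = 8, n_dn = 8))
  expect_error(sim_spec(effect_size = Inf))
})

test_that("expression cohort plants the signature effect, reproducibly", {
  spec <- sim_spec(n_genes = 300, n_samples_per_group = 50, effect_size = 2,
                   seed = 71)
  co <- gen_expression_cohort(spec)
  expect_equal(dim(co$expr), c(300L, 100L))
  expect_identical(co$expr, gen_expression_cohort(spec)$expr)
  expect_length(intersect(co$signature$up, co$signature$dn), 0)

  sc <- score_signature(co$expr, co$signature)
  expect_gt(mean(sc$es_combined[co$labels == "tumour"]),
            mean(sc$es_combined[co$labels == "non_tumour"]))
})

test_that("null effect gives no systematic score difference (20 replicates)", {
  diffs <- vapply(1:20, function(s) {
    co <- gen_expression_cohort(sim_spec(n_genes = 200,
                                         n_samples_per_group = 20,
                                         effect_size = 0, seed = s))
    sc <- score_signature(co$expr, co$signature)
    mean(sc$es_combined[co$labels == "tumour"]) -
      mean(sc$es_combined[co$labels == "non_tumour"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("signature recovery holds in every replicate at effect >= 1", {
  for (s in 1:20) {
    co <- gen_expression_cohort(sim_spec(n_genes = 200,
                                         n_samples_per_group = 15,
                                         effect_size = 1, seed = 100 + s))
    sc <- score_signature(co$expr, co$signature)
    expect_gt(mean(sc$es_combined[co$labels == "tumour"]),
              mean(sc$es_combined[co$labels == "non_tumour"]))
  }
})

test_that("tissue generator packs discs with known pixelization", {
  spec <- sim_spec(n_cells = 10, cell_radius_px = 5, seed = 72)
  tis <- gen_tissue_image(spec)
  expect_length(label_ids(tis$cells), 10)
  expect_length(label_ids(tis$nuclei), 10)
  st <- object_stats(tis$cells)
  expect_true(all(st$area >= 69 & st$area <= 81))
  # every nucleus centroid lies inside its cell's pixel set
  ns <- object_stats(tis$nuclei)
  for (i in seq_len(nrow(ns))) {
    expect_equal(as.integer(tis$cells[round(ns$row[i]), round(ns$col[i])]),
                 ns$label[i])
  }
  expect_identical(unclass(gen_tissue_image(spec)$cells),
                   unclass(tis$cells))
  # packing failure is reported with advice
  expect_error(gen_tissue_image(sim_spec(n_cells = 500, img_size_px = 60,
                                         cell_radius_px = 5, seed = 72)),
               "lower n_cells")
})

test_that("CNA generator plants exact concordance counts", {
  spec1 <- sim_spec(n_regions = 20, concordance_frac = 1, seed = 73)
  d1 <- gen_cna_dataset(spec1)
  expect_true(all(d1$truth))
  pairs1 <- map_homologues(d1$mouse, d1$map, d1$human)$pairs
  expect_true(all(pairs1$human_frequency > 0.05))

  d0 <- gen_cna_dataset(sim_spec(n_regions = 20, concordance_frac = 0,
                                 seed = 73))
  expect_false(any(d0$truth))

  dh <- gen_cna_dataset(sim_spec(n_regions = 20, concordance_frac = 0.5,
                                 seed = 73))
  expect_equal(sum(dh$truth), 10)
  tab <- concordance_table(map_homologues(dh$mouse, dh$map, dh$human)$pairs,
                           dh$background, "gain")
  expect_equal(unname(tab$table["cna", ]), c(5L, 5L))
})

test_that("feature-table generator plants exactly the requested violations", {
  spec <- sim_spec(n_cells = 50, seed = 74)
  ft <- gen_sc_feature_table(spec, violations = c(area_low = 3,
                                                  nuclear_dim = 2,
                                                  prop_high = 1))
  qc <- qc_filter_cells(ft)
  expect_equal(unname(qc$excluded_counts[c("area_low", "nuclear_dim",
                                           "prop_high")]),
               c(3L, 2L, 1L))
  expect_equal(unname(qc$excluded_counts[c("area_high", "prop_low")]),
               c(0L, 0L))
  expect_equal(nrow(qc$retained), 50)

  clean <- gen_sc_feature_table(spec)
  expect_equal(nrow(qc_filter_cells(clean)$retained), nrow(clean))
  expect_identical(gen_sc_feature_table(spec), clean)
})
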