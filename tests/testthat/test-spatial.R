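test_that("cytoplasm derivation is pixel-set subtraction", {
  cells <- disc_image(11, data.frame(row = 6, col = 6, r = 2, label = 1L))
  nuc <- matrix(0L, 11, 11); nuc[6, 6] <- 1L
  cyto <- derive_cytoplasm(cells, as_label_image(nuc))
  expect_equal(sum(cyto == 1L), sum(cells == 1L) - 1L)

  # nucleus = cell: no cytoplasm object
  cyto2 <- derive_cytoplasm(cells, cells)
  expect_equal(label_ids(cyto2), integer(0))

  # empty nucleus image: identity
  cyto3 <- derive_cytoplasm(cells, as_label_image(matrix(0L, 11, 11)))
  expect_equal(unclass(cyto3), unclass(cells))

  expect_error(derive_cytoplasm(cells, as_label_image(matrix(0L, 4, 4))),
               "shape")
})

test_that("compartment mapping assigns concentric nuclei and conserves area", {
  cells <- disc_image(15, data.frame(row = 8, col = 8, r = 5, label = 1L))
  nuc <- disc_image(15, data.frame(row = 8, col = 8, r = 2, label = 7L))
  rec <- map_compartments(cells, nuc)
  expect_equal(rec$nucleus_id, 7L)
  expect_equal(rec$area, rec$nucleus_area + rec$cytoplasm_area)

  # nucleus centroid on background stays unassigned
  nuc2 <- matrix(0L, 15, 15); nuc2[1, 1] <- 3L
  cellsB <- disc_image(15, data.frame(row = 8, col = 8, r = 3, label = 1L))
  rec2 <- map_compartments(cellsB, as_label_image(nuc2))
  expect_true(is.na(rec2$nucleus_id))

  # two nuclei inside one cell: larger overlap wins
  nuc3 <- disc_image(15, data.frame(row = c(8, 8), col = c(6, 10),
                                    r = c(2, 1), label = c(4L, 9L)))
  rec3 <- map_compartments(cells, nuc3)
  expect_equal(rec3$nucleus_id, 4L)
})

test_that("mapping recovers ground truth on simulated tissue (oracle check)", {
  tis <- gen_tissue_image(sim_spec(n_cells = 50, seed = 61))
  rec <- map_compartments(tis$cells, tis$nuclei)
  expect_equal(nrow(rec), 50)
  expect_true(all(rec$nucleus_id == rec$cell_id))
  want <- oracle_assignments(tis$cells, tis$nuclei)
  for (nl in names(want)) {
    expect_equal(rec$nucleus_id[rec$cell_id == want[[nl]]], as.integer(nl))
  }
})

test_that("mapping and intensities are invariant to label renumbering", {
  tis <- gen_tissue_image(sim_spec(n_cells = 20, seed = 62))
  perm <- sample(20)
  relab <- function(img) {
    out <- unclass(img)
    out[out > 0L] <- perm[out[out > 0L]]
    as_label_image(out)
  }
  rec <- map_compartments(tis$cells, tis$nuclei)
  recp <- map_compartments(relab(tis$cells), relab(tis$nuclei))
  m <- match(perm[rec$cell_id], recp$cell_id)
  expect_equal(recp$area[m], rec$area)
  expect_equal(recp$nucleus_id[m], perm[rec$nucleus_id])
})

test_that("intensity extraction equals a per-pixel loop oracle", {
  tis <- gen_tissue_image(sim_spec(n_cells = 20, seed = 63))
  rec <- map_compartments(tis$cells, tis$nuclei)
  rec <- extract_intensities(tis$planes, rec, tis$cells, tis$nuclei)
  plane <- tis$planes[[1]]
  marker <- names(tis$planes)[1]
  for (i in sample(nrow(rec), 5)) {
    px <- which(unclass(tis$cells) == rec$cell_id[i])
    expect_equal(rec[[paste0("cell_", marker)]][i], mean(plane[px]))
    npx <- which(unclass(tis$nuclei) == rec$nucleus_id[i])
    expect_equal(rec[[paste0("nucleus_", marker)]][i], mean(plane[npx]))
  }
  # constant plane: every mean equals the constant
  const <- list(K = matrix(7, nrow(tis$cells), ncol(tis$cells)))
  recc <- extract_intensities(const, rec, tis$cells, tis$nuclei)
  expect_true(all(recc$cell_K == 7))
  expect_true(all(recc$nucleus_K == 7))
})

test_that("gating is boundary-inclusive and recovers planted lineages", {
  rec <- data.frame(cell_id = 1:3, cell_m = c(5, 4.999, 6))
  gates <- data.frame(marker = "m", compartment = "cell", threshold = 5)
  out <- gate_markers(rec, gates)
  expect_equal(out$cell_m_pos, c(TRUE, FALSE, TRUE))
  out2 <- gate_markers(rec, transform(gates, threshold = Inf))
  expect_false(any(out2$cell_m_pos))
  expect_error(gate_markers(rec, data.frame(marker = "zz",
                                            compartment = "cell",
                                            threshold = 1)), "unknown")

  spec <- sim_spec(n_cells = 80, seed = 64)
  tis <- gen_tissue_image(spec)
  rec <- map_compartments(tis$cells, tis$nuclei)
  rec <- extract_intensities(tis$planes, rec, tis$cells, tis$nuclei)
  gates <- data.frame(marker = names(tis$planes), compartment = "cell",
                      threshold = exp(spec$marker_sep_sd *
                                        spec$marker_sdlog / 2))
  rules <- stats::setNames(
    lapply(names(spec$phenotype_mix),
           function(l) paste0("cell_M_", l, "_pos")),
    names(spec$phenotype_mix))
  rec <- gate_markers(rec, gates, rules)
  expect_gte(mean(rec$lineage == tis$truth$phenotype), 0.99)
})

test_that("tissue hi/low classification recovers planted regions", {
  rec <- data.frame(region = rep(c("r1", "r2"), each = 10),
                    pos = rep(c(TRUE, FALSE), c(8, 12)))
  cls <- classify_tissue_atf6(rec, "pos")
  expect_equal(cls$class[cls$region == "r1"], "hi")
  expect_equal(cls$class[cls$region == "r2"], "low")

  # identical fractions tie to low
  rec2 <- data.frame(region = rep(c("a", "b"), each = 4),
                     pos = rep(c(TRUE, FALSE), 4))
  expect_true(all(classify_tissue_atf6(rec2, "pos")$class == "low"))

  # planted 6-region design, 3 high-fraction
  set.seed(65)
  fr <- c(0.8, 0.75, 0.9, 0.1, 0.15, 0.2)
  rec3 <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(region = paste0("R", i),
               pos = runif(200) < fr[i])
  }))
  cls3 <- classify_tissue_atf6(rec3, "pos")
  expect_equal(cls3$class[order(cls3$region)],
               c("hi", "hi", "hi", "low", "low", "low"))
  expect_error(classify_tissue_atf6(rec3[0, ], "pos"), "zero cells|regions")
})

test_that("neighborhoods follow the radius geometry and a brute-force oracle", {
  mk <- function(rows, cols) {
    data.frame(cell_id = seq_along(rows), row = rows, col = cols,
               area = pi * 5^2, lineage = "x")
  }
  # two far cells: no neighbors at r ~ 15
  far <- neighborhood_profile(mk(c(10, 10), c(10, 1000)))
  expect_true(all(lengths(far$neighbors) == 0))

  # three collinear cells spaced just under r
  r <- 1.5 * 10  # mean diameter 10
  lin <- neighborhood_profile(mk(c(0, 0, 0) + 50, c(0, r - 1, 2 * (r - 1)) + 50))
  expect_equal(unname(lengths(lin$neighbors)), c(1L, 2L, 1L))

  # brute-force oracle on 100-cell tissue + symmetry
  tis <- gen_tissue_image(sim_spec(n_cells = 100, seed = 66))
  rec <- map_compartments(tis$cells, tis$nuclei)
  rec$lineage <- tis$truth$phenotype
  prof <- neighborhood_profile(rec)
  for (i in sample(nrow(rec), 20)) {
    d <- sqrt((rec$row - rec$row[i])^2 + (rec$col - rec$col[i])^2)
    want <- rec$cell_id[d <= prof$radius & rec$cell_id != rec$cell_id[i]]
    expect_setequal(prof$neighbors[[i]], want)
  }
  for (i in seq_len(nrow(rec))) {
    for (j in prof$neighbors[[i]]) {
      expect_true(rec$cell_id[i] %in% prof$neighbors[[as.character(j)]])
    }
  }
  ok <- lengths(prof$neighbors) > 0
  expect_equal(rowSums(prof$profile[ok, , drop = FALSE]),
               rep(1, sum(ok)), ignore_attr = TRUE)
})

test_that("segregated lineages show same-lineage neighborhood enrichment", {
  # two spatial blocks, one lineage each: same-lineage frequency must beat
  # the global proportion (the colocalization readout)
  set.seed(67)
  n <- 60
  rec <- data.frame(
    cell_id = 1:n,
    row = c(runif(n / 2, 0, 80), runif(n / 2, 180, 256)),
    col = runif(n, 0, 256),
    area = pi * 25,
    lineage = rep(c("a", "b"), each = n / 2))
  prof <- neighborhood_profile(rec, radius = 40)
  agg <- aggregate_neighborhoods(rec, prof)
  expect_gt(agg["a", "a"], 0.5)
  expect_gt(agg["b", "b"], 0.5)
})
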