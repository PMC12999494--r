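#' Simulation specification for the synthetic-data generators
#'
#' One object holds every tunable of the generators, mirroring the study
#' conditions the pipeline was built for: multi-dataset tumour/non-tumour
#' expression cohorts with an embedded up/down signature (22 datasets, 50
#' samples per group, per-gene shift 0.8 noise SD, signature sizes scaled
#' to the 888-up/266-down proportions of a 20k-gene transcriptome),
#' survival for a 370-patient cohort with score-dependent exponential
#' hazard, disc-packed tissue images, mouse/human CNA call sets with a
#' tunable concordance fraction, and per-cell QC feature tables.
#'
#' @param n_genes Number of genes per cohort.
#' @param n_samples_per_group Tumour and non-tumour group size per dataset.
#' @param n_datasets Number of datasets for multi-cohort generation.
#' @param effect_size Standardized mean shift (units of `noise_sd`) applied
#'   to UP genes in tumour samples; DN genes receive the negated shift. For
#'   [gen_score_panel()] it is directly the planted standardized mean
#'   difference.
#' @param noise_sd Gaussian log-expression noise scale.
#' @param tau Between-dataset SD of the true effect (0 = homogeneous).
#' @param n_up,n_dn Signature set sizes (defaults scale 888/266 of 20,000
#'   to `n_genes`, minimum 5).
#' @param n_patients Survival cohort size.
#' @param hazard_beta Log-hazard per standardized unit of score.
#' @param baseline_median_months Median survival at score 0 (sets the
#'   baseline exponential hazard).
#' @param censor_rate Fraction of patients with an independent uniform
#'   censoring time (in `[0, 1)`).
#' @param follow_up_months Horizon of the uniform censoring distribution.
#' @param n_cells Cells per simulated tissue image.
#' @param cell_radius_px Cell disc radius in pixels.
#' @param img_size_px Square image side length.
#' @param phenotype_mix Named proportions per lineage (must sum to 1).
#' @param marker_sep_sd Separation, in units of the log-scale pixel SD,
#'   between a lineage's own-marker mean and the background mean.
#' @param marker_sdlog Log-scale SD of per-pixel lognormal intensities.
#' @param n_regions Mouse CNA regions (split evenly into gains/losses).
#' @param concordance_frac Fraction of homologous pairs whose human
#'   same-type frequency is planted above the 5% threshold.
#' @param background_frac Same fraction for the background region stratum.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return list of class `SimulationSpec`.
#' @export
sim_spec <- function(n_genes = 1000, n_samples_per_group = 50,
                     n_datasets = 22, effect_size = 0.8, noise_sd = 1,
                     tau = 0,
                     n_up = max(5L, round(n_genes * 888 / 20000)),
                     n_dn = max(5L, round(n_genes * 266 / 20000)),
                     n_patients = 370, hazard_beta = 1,
                     baseline_median_months = 30, censor_rate = 0.3,
                     follow_up_months = 120,
                     n_cells = 100, cell_radius_px = 5, img_size_px = 256,
                     phenotype_mix = c(tumour = 0.5, cd8t = 0.25,
                                       macrophage = 0.25),
                     marker_sep_sd = 4, marker_sdlog = 0.25,
                     n_regions = 20, concordance_frac = 0.5,
                     background_frac = 0.1, seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 1, n_datasets >= 1,
            is.finite(effect_size), noise_sd > 0, tau >= 0,
            n_up >= 1, n_dn >= 1, n_up + n_dn <= n_genes,
            n_patients >= 2, censor_rate >= 0, censor_rate < 1,
            n_cells >= 1, cell_radius_px >= 2, img_size_px > 4 * cell_radius_px,
            abs(sum(phenotype_mix) - 1) < 1e-8,
            n_regions >= 2, concordance_frac >= 0, concordance_frac <= 1,
            background_frac >= 0, background_frac <= 1)
  spec <- as.list(environment())
  class(spec) <- "SimulationSpec"
  spec
}

# Evaluate expr under a deterministic RNG state without disturbing the
# caller's stream. offset keeps sub-generators on distinct streams.
.with_seed <- function(seed, expr, offset = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

#' Simulate one tumour/non-tumour expression cohort with a planted signature
#'
#' Gaussian log-scale expression: per-gene baselines drawn once, i.i.d.
#' noise with SD `noise_sd`, and in tumour samples the UP genes shifted by
#' `+effect_size * noise_sd` and the DN genes by the negated shift. The
#' planted signature membership is returned as ground truth.
#'
#' @param spec A `SimulationSpec`.
#' @param effect Override of `spec$effect_size` (used by the multi-dataset
#'   generator for heterogeneous true effects).
#' @param seed_offset Internal stream offset.
#' @return list with `expr` (genes x samples matrix), `labels` (character,
#'   `"tumour"`/`"non_tumour"` per sample), `signature` (a `SignaturePair`).
#' @export
gen_expression_cohort <- function(spec, effect = spec$effect_size,
                                  seed_offset = 0L) {
  .with_seed(spec$seed, offset = seed_offset, expr = {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    up <- genes[seq_len(spec$n_up)]
    dn <- genes[spec$n_up + seq_len(spec$n_dn)]
    sig <- signature_pair(up, dn, "planted")
    n <- spec$n_samples_per_group
    samples <- c(sprintf("T%03d", seq_len(n)), sprintf("N%03d", seq_len(n)))
    labels <- rep(c("tumour", "non_tumour"), each = n)
    baseline <- stats::rnorm(spec$n_genes, 0, 1)
    m <- baseline + matrix(stats::rnorm(spec$n_genes * 2 * n, 0, spec$noise_sd),
                           spec$n_genes, 2 * n)
    shift <- effect * spec$noise_sd
    m[seq_len(spec$n_up), labels == "tumour"] <-
      m[seq_len(spec$n_up), labels == "tumour"] + shift
    m[spec$n_up + seq_len(spec$n_dn), labels == "tumour"] <-
      m[spec$n_up + seq_len(spec$n_dn), labels == "tumour"] - shift
    dimnames(m) <- list(genes, samples)
    list(expr = m, labels = stats::setNames(labels, samples), signature = sig)
  })
}

#' Simulate a panel of datasets sharing one true signature effect
#'
#' Each dataset receives an independent per-dataset baseline shift (added
#' to all its values), its own noise draw, and a true effect
#' `effect_size + N(0, tau^2)`; the signature membership is shared.
#'
#' @param spec A `SimulationSpec` with `n_datasets >= 2`.
#' @return list with `cohorts` (list of [gen_expression_cohort()] results),
#'   `true_effects` (numeric vector) and `signature`.
#' @export
gen_multi_dataset <- function(spec) {
  stopifnot(spec$n_datasets >= 2)
  true_effects <- .with_seed(spec$seed, offset = 900000L, {
    spec$effect_size + stats::rnorm(spec$n_datasets, 0, spec$tau)
  })
  shifts <- .with_seed(spec$seed, offset = 910000L, {
    stats::rnorm(spec$n_datasets, 0, 0.5)
  })
  cohorts <- lapply(seq_len(spec$n_datasets), function(i) {
    co <- gen_expression_cohort(spec, effect = true_effects[[i]],
                                seed_offset = i)
    co$expr <- co$expr + shifts[[i]]
    co$dataset <- sprintf("D%02d", i)
    co
  })
  list(cohorts = cohorts, true_effects = true_effects,
       signature = cohorts[[1]]$signature)
}

#' Simulate per-dataset enrichment-score samples with a planted SMD
#'
#' The substrate for testing the meta-analysis machinery on its own scale:
#' for each dataset, control scores are N(0, 1) and tumour scores
#' N(theta_i, 1) with `theta_i = effect_size + N(0, tau^2)`, so the planted
#' standardized mean difference is exactly `effect_size` (expectation over
#' datasets).
#'
#' @param spec A `SimulationSpec`.
#' @return list of datasets, each `list(dataset, tumour, control)`.
#' @export
gen_score_panel <- function(spec) {
  .with_seed(spec$seed, offset = 920000L, {
    n <- spec$n_samples_per_group
    lapply(seq_len(spec$n_datasets), function(i) {
      theta <- spec$effect_size + stats::rnorm(1, 0, spec$tau)
      list(dataset = sprintf("D%02d", i),
           tumour = stats::rnorm(n, theta, 1),
           control = stats::rnorm(n, 0, 1))
    })
  })
}

#' Simulate a survival cohort whose hazard depends on a score
#'
#' Event times are exponential with hazard
#' `h0 * exp(hazard_beta * z(score))`, `z` the standardized score and `h0`
#' set so that median survival at score 0 equals
#' `baseline_median_months`. A `censor_rate` fraction of patients receive
#' an independent uniform censoring time on `(0, follow_up_months)`; times
#' are in months.
#'
#' @param spec A `SimulationSpec`.
#' @param scores Per-patient score vector (non-empty); its length overrides
#'   `spec$n_patients`.
#' @param seed_offset Internal stream offset.
#' @return data.frame with columns `time`, `event`, `score`.
#' @export
gen_survival_cohort <- function(spec, scores, seed_offset = 0L) {
  if (length(scores) == 0L) stop("empty score list")
  stopifnot(is.finite(spec$hazard_beta))
  .with_seed(spec$seed, offset = 930000L + seed_offset, {
    n <- length(scores)
    z <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else
      rep(0, n)
    h0 <- log(2) / spec$baseline_median_months
    t_event <- stats::rexp(n, rate = h0 * exp(spec$hazard_beta * z))
    censored <- stats::runif(n) < spec$censor_rate
    c_time <- ifelse(censored, stats::runif(n, 0, spec$follow_up_months), Inf)
    data.frame(time = pmin(t_event, c_time),
               event = as.integer(t_event <= c_time),
               score = scores)
  })
}

# Pixel offsets of a centred disc of radius r (squared-distance rule).
.disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Simulate a tissue image of non-overlapping cells with nuclei
#'
#' Cells are hard discs of radius `cell_radius_px` placed by rejection
#' sampling (bounded retries; an error suggests lowering `n_cells`), each
#' with a concentric nuclear disc of half radius. Lineages are drawn from
#' `phenotype_mix`; per-pixel marker intensities are lognormal with a
#' lineage-dependent log-mean (`marker_sep_sd * marker_sdlog` above
#' background for the lineage's own marker), and the truth table records
#' each cell's realized mean intensity per marker.
#'
#' @param spec A `SimulationSpec`.
#' @return list with `cells` and `nuclei` (`LabelImage`s), `planes` (named
#'   list of marker intensity matrices, one per lineage marker
#'   `M_<lineage>`), and `truth` (data.frame: `cell_id`, `row`, `col`,
#'   `area`, `phenotype`, realized `cell_M_<lineage>` means).
#' @export
gen_tissue_image <- function(spec) {
  .with_seed(spec$seed, offset = 940000L, {
    r <- spec$cell_radius_px
    size <- spec$img_size_px
    n <- spec$n_cells
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L; max_tries <- 200L * n
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("disc packing failed after ", max_tries,
             " tries; lower n_cells or enlarge img_size_px")
      }
      cand <- c(sample(seq(r + 1L, size - r), 1),
                sample(seq(r + 1L, size - r), 1))
      if (nrow(centers) == 0L ||
          all((centers[, 1] - cand[[1]])^2 + (centers[, 2] - cand[[2]])^2 >
              (2 * r + 1)^2)) {
        centers <- rbind(centers, cand)
      }
    }
    cells <- matrix(0L, size, size)
    nuclei <- matrix(0L, size, size)
    off_c <- .disc_offsets(r)
    off_n <- .disc_offsets(max(1L, floor(r / 2)))
    for (i in seq_len(n)) {
      cells[cbind(centers[i, 1] + off_c$dr, centers[i, 2] + off_c$dc)] <- i
      nuclei[cbind(centers[i, 1] + off_n$dr, centers[i, 2] + off_n$dc)] <- i
    }
    lineages <- names(spec$phenotype_mix)
    phen <- sample(lineages, n, replace = TRUE, prob = spec$phenotype_mix)
    markers <- paste0("M_", lineages)
    mu_hi <- spec$marker_sep_sd * spec$marker_sdlog
    planes <- list()
    truth <- data.frame(cell_id = seq_len(n),
                        row = centers[, 1], col = centers[, 2],
                        area = nrow(off_c), phenotype = phen,
                        stringsAsFactors = FALSE)
    for (k in seq_along(lineages)) {
      plane <- matrix(stats::rlnorm(size * size, 0, spec$marker_sdlog),
                      size, size)
      for (i in seq_len(n)) {
        mu <- if (phen[[i]] == lineages[[k]]) mu_hi else 0
        px <- cbind(centers[i, 1] + off_c$dr, centers[i, 2] + off_c$dc)
        plane[px] <- stats::rlnorm(nrow(px), mu, spec$marker_sdlog)
        truth[i, paste0("cell_", markers[[k]])] <- mean(plane[px])
      }
      planes[[markers[[k]]]] <- plane
    }
    list(cells = as_label_image(cells), nuclei = as_label_image(nuclei),
         planes = planes, truth = truth)
  })
}

#' Simulate mouse/human CNA call sets with planted concordance
#'
#' Mouse regions split evenly into gains and losses, each mapped one-to-one
#' to a human homologue. Per CNA type, the first `round(frac * n_type)`
#' pairs are planted concordant (human same-type carrier frequency drawn
#' strictly above 5%) and the rest discordant (frequency at or below 5%),
#' so the concordant count is deterministic given the fraction. A
#' background pair stratum of the same size is planted at
#' `background_frac`.
#'
#' @param spec A `SimulationSpec`.
#' @return list with `mouse` (`CNARegionSet`), `map` (homology data.frame),
#'   `human` (`CNARegionSet` with `frequency`), `background` (pairs-shaped
#'   data.frame for [concordance_table()]), and `truth` (logical
#'   concordance flags per mouse region).
#' @export
gen_cna_dataset <- function(spec) {
  .with_seed(spec$seed, offset = 950000L, {
    n <- spec$n_regions
    types <- rep(c("gain", "loss"), length.out = n)
    width <- 1e6L
    mouse <- data.frame(
      chrom = paste0("chr", rep(1:19, length.out = n)),
      start = as.integer(seq_len(n)) * 2000000L,
      end = as.integer(seq_len(n)) * 2000000L + width,
      cna_type = types, stringsAsFactors = FALSE)
    human <- data.frame(
      chrom = paste0("chr", rep(1:22, length.out = n)),
      start = as.integer(seq_len(n)) * 3000000L,
      end = as.integer(seq_len(n)) * 3000000L + width,
      cna_type = types, stringsAsFactors = FALSE)
    concordant <- logical(n)
    for (tp in c("gain", "loss")) {
      idx <- which(types == tp)
      k <- round(spec$concordance_frac * length(idx))
      concordant[idx[seq_len(k)]] <- TRUE
    }
    human$frequency <- ifelse(concordant,
                              stats::runif(n, 0.06, 0.5),
                              stats::runif(n, 0, 0.05))
    class(mouse) <- class(human) <- c("CNARegionSet", "data.frame")
    map <- data.frame(mouse_key = region_key(mouse),
                      human_key = region_key(human),
                      stringsAsFactors = FALSE)
    bg_conc <- stats::runif(n) < spec$background_frac
    background <- data.frame(
      mouse_key = paste0("bg", seq_len(n)),
      human_key = paste0("bgh", seq_len(n)),
      cna_type = types, human_cna_type = types,
      human_frequency = ifelse(bg_conc, stats::runif(n, 0.06, 0.5),
                               stats::runif(n, 0, 0.05)),
      stringsAsFactors = FALSE)
    list(mouse = mouse, map = map, human = human, background = background,
         truth = concordant)
  })
}

#' Simulate a MIBI per-cell feature table with planted QC violations
#'
#' Normal cells draw features well inside the QC keep ranges; a configurable
#' count of cells per violation kind is appended, each tripping exactly one
#' rule. The `planted` column records the ground truth.
#'
#' @param spec A `SimulationSpec`.
#' @param violations Named integer vector with any of `area_low`,
#'   `area_high`, `nuclear_dim`, `prop_low`, `prop_high`.
#' @return data.frame with columns `cell_id`, `area_px`, `nuclear_sum_au`,
#'   `nuclear_prop_pct`, `marker1`, `marker2`, `planted`.
#' @export
gen_sc_feature_table <- function(spec,
                                 violations = c(area_low = 0L, area_high = 0L,
                                                nuclear_dim = 0L,
                                                prop_low = 0L,
                                                prop_high = 0L)) {
  .with_seed(spec$seed, offset = 960000L, {
    n <- spec$n_cells
    tbl <- data.frame(
      area_px = round(stats::runif(n, 100, 2000)),
      nuclear_sum_au = stats::runif(n, 20, 200),
      nuclear_prop_pct = stats::runif(n, 20, 80),
      marker1 = stats::rlnorm(n, 0, 0.5),
      marker2 = stats::rlnorm(n, 1, 0.5),
      planted = "none", stringsAsFactors = FALSE)
    plant <- function(kind, n_k, mutate) {
      if (is.na(n_k) || n_k == 0L) return(NULL)
      rows <- tbl[rep(1L, n_k), , drop = FALSE]
      rows$area_px <- round(stats::runif(n_k, 100, 2000))
      rows$nuclear_sum_au <- stats::runif(n_k, 20, 200)
      rows$nuclear_prop_pct <- stats::runif(n_k, 20, 80)
      rows <- mutate(rows)
      rows$planted <- kind
      rows
    }
    extra <- rbind(
      plant("area_low", violations["area_low"],
            function(r) { r$area_px <- 50; r }),
      plant("area_high", violations["area_high"],
            function(r) { r$area_px <- 4000; r }),
      plant("nuclear_dim", violations["nuclear_dim"],
            function(r) { r$nuclear_sum_au <- 5.0; r }),
      plant("prop_low", violations["prop_low"],
            function(r) { r$nuclear_prop_pct <- 0.1; r }),
      plant("prop_high", violations["prop_high"],
            function(r) { r$nuclear_prop_pct <- 99.9; r }))
    tbl <- rbind(tbl, extra)
    tbl <- cbind(cell_id = seq_len(nrow(tbl)), tbl)
    rownames(tbl) <- NULL
    tbl
  })
}
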