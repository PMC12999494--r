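#' Per-object area and centroid of a label image
#'
#' Centroids are arithmetic means of member-pixel (row, col) coordinates,
#' origin top-left.
#'
#' @param img A `LabelImage`.
#' @return data.frame with columns `label`, `area`, `row`, `col`.
#' @export
object_stats <- function(img) {
  idx <- which(img > 0L)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area = integer(),
                      row = numeric(), col = numeric()))
  }
  lab <- as.integer(img[idx])
  r <- (idx - 1L) %% nrow(img) + 1L
  c <- (idx - 1L) %/% nrow(img) + 1L
  area <- tapply(rep(1L, length(lab)), lab, sum)
  rows <- tapply(r, lab, mean)
  cols <- tapply(c, lab, mean)
  data.frame(label = as.integer(names(area)), area = as.integer(area),
             row = as.numeric(rows), col = as.numeric(cols),
             row.names = NULL)
}

#' Derive cytoplasm masks by subtracting nuclei from cells
#'
#' The cytoplasm of each cell is its pixel set minus all nuclear pixels;
#' labels are inherited from the cell image. A cell fully covered by nuclei
#' yields no cytoplasm object.
#'
#' @param cells,nuclei `LabelImage`s of the same shape.
#' @return A `LabelImage` of cytoplasm compartments labelled like `cells`.
#' @export
derive_cytoplasm <- function(cells, nuclei) {
  if (!all(dim(cells) == dim(nuclei))) stop("image shapes differ")
  cyto <- unclass(cells)
  cyto[nuclei > 0L] <- 0L
  as_label_image(cyto)
}

# "Most central xy-coordinate" of each object: the pixel-rounded centroid
# when it lies on the object, else the member pixel nearest the centroid
# (makes the rule total for non-convex objects).
.central_pixels <- function(img) {
  st <- object_stats(img)
  if (nrow(st) == 0L) return(cbind(st, c_row = numeric(), c_col = numeric()))
  c_row <- round(st$row); c_col <- round(st$col)
  for (i in seq_len(nrow(st))) {
    lab <- st$label[[i]]
    if (c_row[[i]] < 1 || c_row[[i]] > nrow(img) ||
        c_col[[i]] < 1 || c_col[[i]] > ncol(img) ||
        img[c_row[[i]], c_col[[i]]] != lab) {
      idx <- which(img == lab)
      pr <- (idx - 1L) %% nrow(img) + 1L
      pc <- (idx - 1L) %/% nrow(img) + 1L
      k <- which.min((pr - st$row[[i]])^2 + (pc - st$col[[i]])^2)
      c_row[[i]] <- pr[[k]]; c_col[[i]] <- pc[[k]]
    }
  }
  cbind(st, c_row = c_row, c_col = c_col)
}

#' Map nuclei and cytoplasm compartments to their parent cells
#'
#' A compartment object is assigned to the cell whose pixel set contains its
#' most central coordinate (pixel-rounded centroid). A cell receives at most
#' one object of each kind: when several centroids fall inside the same
#' cell, the object with the largest pixel overlap with that cell wins and
#' the others remain unassigned. Objects whose central coordinate lies on
#' background remain unassigned. Every cell emits a record even without a
#' nucleus or cytoplasm.
#'
#' @param cells,nuclei,cytoplasm `LabelImage`s of identical shape
#'   (`cytoplasm` defaults to [derive_cytoplasm()] of the other two).
#' @return data.frame (one row per cell) with columns `cell_id`, `row`,
#'   `col`, `area`, `nucleus_id`, `nucleus_area`, `cytoplasm_id`,
#'   `cytoplasm_area` (`NA` where unassigned).
#' @export
map_compartments <- function(cells, nuclei,
                             cytoplasm = derive_cytoplasm(cells, nuclei)) {
  if (!all(dim(cells) == dim(nuclei)) || !all(dim(cells) == dim(cytoplasm))) {
    stop("image shapes differ")
  }
  cs <- object_stats(cells)
  rec <- data.frame(cell_id = cs$label, row = cs$row, col = cs$col,
                    area = cs$area,
                    nucleus_id = NA_integer_, nucleus_area = NA_integer_,
                    cytoplasm_id = NA_integer_, cytoplasm_area = NA_integer_)

  assign_kind <- function(rec, comp, id_col, area_col) {
    st <- .central_pixels(comp)
    if (nrow(st) == 0L) return(rec)
    host <- vapply(seq_len(nrow(st)), function(i) {
      as.integer(cells[st$c_row[[i]], st$c_col[[i]]])
    }, integer(1))
    for (cell in unique(host[host > 0L])) {
      cand <- st$label[host == cell]
      if (length(cand) > 1L) {
        ov <- vapply(cand, function(lab) {
          sum(comp == lab & cells == cell)
        }, numeric(1))
        cand <- cand[[which.max(ov)]]
      }
      k <- match(cell, rec$cell_id)
      rec[[id_col]][[k]] <- cand
      rec[[area_col]][[k]] <- st$area[[match(cand, st$label)]]
    }
    rec
  }
  rec <- assign_kind(rec, nuclei, "nucleus_id", "nucleus_area")
  rec <- assign_kind(rec, cytoplasm, "cytoplasm_id", "cytoplasm_area")
  rec
}

#' Mean marker intensities per compartment
#'
#' For each marker plane, the mean over the member pixels of every assigned
#' compartment is appended to the cell records as columns
#' `<compartment>_<marker>`.
#'
#' @param planes Named list of numeric matrices (one per marker), same shape
#'   as the label images.
#' @param records Cell records from [map_compartments()].
#' @param cells,nuclei,cytoplasm The `LabelImage`s the records were built
#'   from (`cytoplasm` may be `NULL` to skip that compartment).
#' @return `records` with intensity columns appended.
#' @export
extract_intensities <- function(planes, records, cells, nuclei,
                                cytoplasm = NULL) {
  stopifnot(is.list(planes), !is.null(names(planes)))
  comp_imgs <- list(cell = cells, nucleus = nuclei)
  id_cols <- c(cell = "cell_id", nucleus = "nucleus_id")
  if (!is.null(cytoplasm)) {
    comp_imgs$cytoplasm <- cytoplasm
    id_cols <- c(id_cols, cytoplasm = "cytoplasm_id")
  }
  for (marker in names(planes)) {
    plane <- planes[[marker]]
    if (!all(dim(plane) == dim(cells))) stop("plane shape mismatch: ", marker)
    for (comp in names(comp_imgs)) {
      img <- comp_imgs[[comp]]
      idx <- which(img > 0L)
      means <- tapply(plane[idx], as.integer(img[idx]), mean)
      ids <- records[[id_cols[[comp]]]]
      records[[paste0(comp, "_", marker)]] <-
        as.numeric(means[match(ids, as.integer(names(means)))])
    }
  }
  records
}

#' Gate marker positivity and assign lineages
#'
#' A compartment is positive for a marker when its mean intensity is at or
#' above the gate threshold (inclusive). Lineages are derived from a
#' caller-supplied rule list: each rule names the flag columns that must all
#' be `TRUE`; rules are evaluated in order and the first match wins;
#' unmatched cells are labelled `"unassigned"`.
#'
#' @param records Cell records with intensity columns from
#'   [extract_intensities()].
#' @param gates data.frame with columns `marker`, `compartment`, `threshold`.
#' @param lineage_rules Optional named list: lineage name -> character vector
#'   of required positivity columns (`<compartment>_<marker>_pos`).
#' @return `records` with `<compartment>_<marker>_pos` logical columns and,
#'   when rules are given, a `lineage` column.
#' @export
gate_markers <- function(records, gates, lineage_rules = NULL) {
  stopifnot(all(c("marker", "compartment", "threshold") %in% names(gates)))
  if (anyNA(gates$threshold)) stop("missing gate threshold")
  for (i in seq_len(nrow(gates))) {
    col <- paste0(gates$compartment[[i]], "_", gates$marker[[i]])
    if (!col %in% names(records)) {
      stop("gate references unknown marker/compartment: ", col)
    }
    records[[paste0(col, "_pos")]] <-
      !is.na(records[[col]]) & records[[col]] >= gates$threshold[[i]]
  }
  if (!is.null(lineage_rules)) {
    lin <- rep("unassigned", nrow(records))
    for (nm in names(lineage_rules)) {
      need <- lineage_rules[[nm]]
      if (!all(need %in% names(records))) {
        stop("lineage rule '", nm, "' references unknown flag column")
      }
      hit <- Reduce(`&`, records[need])
      lin[lin == "unassigned" & hit] <- nm
    }
    records$lineage <- lin
  }
  records
}

#' Classify tissue regions as ATF6-hi or ATF6-low
#'
#' Per region the fraction of positive cells is computed; regions strictly
#' above the across-region median fraction are `hi`, the rest `low` (ties at
#' the median go to `low`, consistent with [median_split()]). An absolute
#' fraction cutoff can override the median rule.
#'
#' @param records Cell records with a region column and a logical positivity
#'   column.
#' @param flag_col Name of the logical positivity column.
#' @param region_col Name of the region column (default `"region"`).
#' @param abs_cutoff Optional absolute positive-fraction cutoff; regions
#'   with fraction > `abs_cutoff` are `hi`.
#' @return data.frame with columns `region`, `n_cells`, `frac_positive`,
#'   `class`.
#' @export
classify_tissue_atf6 <- function(records, flag_col, region_col = "region",
                                 abs_cutoff = NULL) {
  stopifnot(flag_col %in% names(records), region_col %in% names(records))
  counts <- table(records[[region_col]])
  if (any(counts == 0L)) stop("region with zero cells")
  frac <- tapply(records[[flag_col]], records[[region_col]], mean)
  if (is.null(abs_cutoff)) {
    if (length(frac) < 2L) stop("median rule needs >= 2 regions")
    cutoff <- stats::median(frac)
  } else {
    cutoff <- abs_cutoff
  }
  data.frame(region = names(frac), n_cells = as.integer(counts[names(frac)]),
             frac_positive = as.numeric(frac),
             class = ifelse(frac > cutoff, "hi", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Radius-based neighborhood lineage profiles
#'
#' The neighborhood radius is `radius_factor` times the mean
#' equivalent-circle cell diameter of the image (`2 sqrt(area / pi)`).
#' Neighbors of a cell are all other cells whose centroid lies within the
#' radius (boundary inclusive); the profile is the lineage frequency among
#' its neighbors. `aggregate_neighborhoods()` averages profiles per index
#' lineage.
#'
#' @param records Cell records with `row`, `col`, `area` and `lineage`.
#' @param radius_factor Multiplier of the mean cell diameter (default 1.5).
#' @param radius Optional absolute radius in pixels, overriding the factor.
#' @return list with `radius`, `neighbors` (list of neighbor cell ids per
#'   cell) and `profile` (cells x lineages frequency matrix; all-`NA` row
#'   for cells without neighbors).
#' @export
neighborhood_profile <- function(records, radius_factor = 1.5, radius = NULL) {
  stopifnot(all(c("row", "col", "area", "lineage") %in% names(records)))
  n <- nrow(records)
  if (n == 0L) stop("no labelled cells")
  if (is.null(radius)) {
    diam <- 2 * sqrt(records$area / pi)
    radius <- radius_factor * mean(diam)
  }
  d <- as.matrix(stats::dist(records[, c("row", "col")]))
  lineages <- sort(unique(records$lineage))
  profile <- matrix(NA_real_, n, length(lineages),
                    dimnames = list(records$cell_id, lineages))
  neighbors <- vector("list", n)
  names(neighbors) <- as.character(records$cell_id)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= radius & seq_len(n) != i)
    neighbors[[i]] <- records$cell_id[nb]
    if (length(nb)) {
      tab <- table(factor(records$lineage[nb], levels = lineages))
      profile[i, ] <- as.numeric(tab) / length(nb)
    }
  }
  list(radius = radius, neighbors = neighbors, profile = profile)
}

#' Mean neighborhood composition per index lineage
#'
#' @param records Cell records used for [neighborhood_profile()].
#' @param prof Result of [neighborhood_profile()].
#' @return Matrix: index lineages x neighbor lineages, mean frequency over
#'   index cells that have at least one neighbor.
#' @export
aggregate_neighborhoods <- function(records, prof) {
  keep <- rowSums(is.na(prof$profile)) == 0
  idx_lin <- records$lineage[keep]
  out <- apply(prof$profile[keep, , drop = FALSE], 2, function(col) {
    tapply(col, idx_lin, mean)
  })
  if (is.null(dim(out))) out <- t(as.matrix(out))
  out
}
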