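#' Read a GMT gene-set file
#'
#' Parses the tab-separated gene-set exchange format used by MSigDB: one set
#' per line, fields are set name, description, then gene identifiers. Gene
#' order is preserved; duplicate genes within a set are collapsed keeping the
#' first occurrence.
#'
#' @param path Path to a GMT file.
#' @return An object of class `GeneSetCollection`: a list with elements
#'   `name` (the file basename) and `sets` (named list of character vectors).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("malformed GMT line %d: set '%s' has no genes", i, fields[[1]]))
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- genes[!duplicated(genes)]
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(list(name = basename(path), sets = sets),
            class = "GeneSetCollection")
}

#' Write a GeneSetCollection to GMT
#'
#' @param gsc A `GeneSetCollection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, "na", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Gene identifiers must be unique and all cells numeric and non-missing.
#'
#' @param path Path to a TSV/CSV matrix.
#' @param sep Field separator (default tab).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("matrix file has no data: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in matrix: ", path)
  if (anyNA(m)) stop("missing values in matrix: ", path)
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix
#'
#' @param m Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like CNA region file
#'
#' Columns: chrom, start, end, cna_type, optional carrier frequency.
#' Coordinates are 0-based half-open (BED convention); `start < end` and
#' `cna_type` must be `gain` or `loss`.
#'
#' @param path Path to a tab-separated region file (no header).
#' @return A data.frame of class `CNARegionSet` with columns `chrom`,
#'   `start`, `end`, `cna_type` and, when present, `frequency`.
#' @export
read_regions <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("region file needs >= 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "cna_type")
  if (ncol(df) >= 5L) names(df)[5] <- "frequency"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("start >= end at line(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(df$cna_type), c("gain", "loss"))
  if (length(unknown)) stop("unknown cna_type: ", paste(unknown, collapse = ", "))
  if ("frequency" %in% names(df)) {
    f <- df$frequency
    if (any(!is.na(f) & (f < 0 | f > 1))) stop("frequency outside [0, 1]")
  }
  class(df) <- c("CNARegionSet", "data.frame")
  df
}

#' Write a CNARegionSet to a BED-like file
#'
#' @param regions A `CNARegionSet` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a single-plane integer label image
#'
#' Accepts either a TIFF (via the tiff package; integer labels are recovered
#' from the [0, 1] sample scale by multiplying with the bit-depth maximum) or
#' a plain whitespace/tab-delimited integer matrix. Zero is background;
#' labels must be non-negative integers.
#'
#' @param path Path to a `.tif`/`.tiff` file or a delimited integer matrix.
#' @return Integer matrix of class `LabelImage`.
#' @export
read_label_image <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] != 1L) stop("label image must be single-plane: ", path)
      img <- img[, , 1]
    }
    m <- img
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE))
  }
  if (any(m != round(m))) stop("non-integer pixels in label image: ", path)
  m <- matrix(as.integer(round(m)), nrow = nrow(m))
  if (any(m < 0L)) stop("negative labels in label image: ", path)
  as_label_image(m)
}

#' Construct a LabelImage from an integer matrix
#'
#' @param m Integer matrix, 0 = background, positive values = object labels.
#' @return `m` with class `LabelImage`.
#' @export
as_label_image <- function(m) {
  stopifnot(is.matrix(m))
  if (any(m != round(m))) stop("non-integer labels")
  if (any(m < 0)) stop("negative labels")
  storage.mode(m) <- "integer"
  class(m) <- c("LabelImage", class(m))
  m
}

#' Labels present in a LabelImage
#'
#' @param img A `LabelImage`.
#' @return Sorted integer vector of distinct non-zero labels.
#' @export
label_ids <- function(img) {
  sort(unique(as.integer(img[img > 0L])))
}

#' Write a label image as a delimited integer matrix
#'
#' @param img A `LabelImage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  utils::write.table(unclass(img), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
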