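#' Construct a spot-level spatial expression dataset
#'
#' A `spot_dataset` bundles a spots x genes expression matrix with the 2-D
#' spatial coordinates of each spot, plus optional ground-truth domain
#' labels. It is the common input container for graph construction, model
#' fitting and evaluation.
#'
#' @param X numeric matrix, spots in rows, genes in columns. Raw counts or
#'   already-normalized values (see `normalized`).
#' @param coords numeric matrix or data.frame with one row per spot and two
#'   columns (x, y), in the same length units used for neighbor radii.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   rownames of `X` or `spot_1..spot_n`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   colnames of `X` or `gene_1..gene_g`.
#' @param truth_labels optional integer vector of reference domain labels
#'   (0-based), used only for evaluation.
#' @param normalized logical flag: has library-size normalization and
#'   log1p transformation been applied?
#' @param hvg_mask optional logical vector per gene marking the highly
#'   variable genes selected by [select_hvg()].
#' @return An object of class `spot_dataset`.
#' @seealso [load_spot_dataset()], [normalize_log1p()], [select_hvg()]
#' @export
spot_dataset <- function(X, coords, spot_ids = NULL, gene_ids = NULL,
                         truth_labels = NULL, normalized = FALSE,
                         hvg_mask = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("coords must have exactly 2 columns (x, y)")
  if (nrow(X) != nrow(coords))
    stop("X has ", nrow(X), " rows but coords has ", nrow(coords))
  if (is.null(spot_ids)) spot_ids <- rownames(X) %||% paste0("spot_", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- colnames(X) %||% paste0("gene_", seq_len(ncol(X)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (length(spot_ids) != nrow(X)) stop("spot_ids length mismatch")
  if (length(gene_ids) != ncol(X)) stop("gene_ids length mismatch")
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids: ", paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  if (!all(is.finite(coords))) stop("coords contain non-finite entries")
  if (!normalized && any(X < 0)) stop("raw counts must be non-negative")
  if (!is.null(truth_labels)) {
    if (length(truth_labels) != nrow(X)) stop("truth_labels length mismatch")
    truth_labels <- as.integer(truth_labels)
  }
  if (!is.null(hvg_mask)) {
    if (length(hvg_mask) != ncol(X)) stop("hvg_mask length mismatch")
    hvg_mask <- as.logical(hvg_mask)
  }
  dimnames(X) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(X = X, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, truth_labels = truth_labels,
                 normalized = isTRUE(normalized), hvg_mask = hvg_mask),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$normalized) "normalized" else "raw counts"))
  if (!is.null(x$truth_labels))
    cat(sprintf("  truth labels: %d domains\n", length(unique(x$truth_labels))))
  if (!is.null(x$hvg_mask))
    cat(sprintf("  HVG mask: %d genes selected\n", sum(x$hvg_mask)))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$X)

#' Load a spot dataset from an expression matrix and a coordinate table
#'
#' Reads either a dense delimited matrix (header row = gene ids, first
#' column = spot ids) or a MatrixMarket triplet file, together with a
#' coordinate table whose first three columns are spot id, x and y.
#' Matrix rows and coordinates are aligned by spot id for the dense
#' dialect; spots present in only one of the two files are dropped with a
#' message reporting the count. For the MatrixMarket dialect, spot ids are
#' either read from `spots_path` (one barcode per line, aligned by id) or
#' taken positionally from the coordinate table.
#'
#' @param matrix_path path to the expression matrix file.
#' @param coords_path path to the coordinate table (same `sep`).
#' @param dialect `"dense"` (delimited, default) or `"mtx"` (MatrixMarket
#'   triplet; duplicate (spot, gene) entries are summed).
#' @param spots_as for `"mtx"`: are spots the `"rows"` or `"cols"` of the
#'   stored matrix?
#' @param spots_path,genes_path optional id sidecar files (one id per
#'   line) for the `"mtx"` dialect.
#' @param sep field separator for delimited files; `","` by default.
#' @return A [spot_dataset()] with `normalized = FALSE`.
#' @export
load_spot_dataset <- function(matrix_path, coords_path,
                              dialect = c("dense", "mtx"),
                              spots_as = c("rows", "cols"),
                              spots_path = NULL, genes_path = NULL,
                              sep = ",") {
  dialect <- match.arg(dialect)
  spots_as <- match.arg(spots_as)
  for (p in c(matrix_path, coords_path))
    if (!file.exists(p)) stop("file not found: ", p)

  coords_tab <- utils::read.table(coords_path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(coords_tab) < 3L)
    stop("coordinate table needs at least 3 columns (spot id, x, y)")
  cid <- as.character(coords_tab[[1L]])
  cx <- suppressWarnings(as.numeric(coords_tab[[2L]]))
  cy <- suppressWarnings(as.numeric(coords_tab[[3L]]))
  bad <- which(!is.finite(cx) | !is.finite(cy))
  if (length(bad))
    stop("non-numeric coordinates for spot(s): ", paste(cid[bad], collapse = ", "))
  if (anyDuplicated(cid))
    stop("duplicate spot ids in coordinate table: ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))

  if (dialect == "dense") {
    tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE)
    X <- as.matrix(tab)
    storage.mode(X) <- "double"
    mid <- rownames(X)
  } else {
    M <- Matrix::readMM(matrix_path)
    M <- methods::as(M, "CsparseMatrix")   # sums duplicate triplet entries
    X <- as.matrix(M)
    if (spots_as == "cols") X <- t(X)
    if (!is.null(spots_path)) {
      mid <- readLines(spots_path)
      if (length(mid) != nrow(X))
        stop("spots_path has ", length(mid), " ids for ", nrow(X), " matrix spots")
    } else {
      if (nrow(X) != length(cid))
        stop("MatrixMarket matrix has ", nrow(X), " spots but coordinate table has ",
             length(cid), "; supply spots_path for id-based alignment")
      mid <- cid
    }
    gid <- if (!is.null(genes_path)) readLines(genes_path)
           else paste0("gene_", seq_len(ncol(X)))
    dimnames(X) <- list(mid, gid)
  }
  if (anyDuplicated(mid))
    stop("duplicate spot ids in matrix: ",
         paste(unique(mid[duplicated(mid)]), collapse = ", "))

  keep <- intersect(mid, cid)
  n_drop <- (length(mid) - length(keep)) + (length(cid) - length(keep))
  if (length(keep) == 0L) stop("no spot ids shared between matrix and coordinates")
  if (n_drop > 0L)
    message("load_spot_dataset: dropped ", n_drop,
            " spot(s) unmatched between matrix and coordinate table")
  ord <- mid[mid %in% keep]
  X <- X[ord, , drop = FALSE]
  co <- cbind(cx, cy)[match(ord, cid), , drop = FALSE]
  spot_dataset(X, co, spot_ids = ord, gene_ids = colnames(X))
}

#' Write a spot dataset as a plain-text archive directory
#'
#' Writes `matrix.csv` (dense, spot ids in the first column, gene ids in
#' the header), `coords.csv`, optional `labels.csv`, and `meta.json`
#' (normalization flag and HVG mask). The archive round-trips through
#' [read_spot_dataset()].
#'
#' @param ds a [spot_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spot_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mt <- data.frame(spot = ds$spot_ids, ds$X, check.names = FALSE)
  utils::write.table(mt, file.path(dir, "matrix.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  co <- data.frame(spot = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2])
  utils::write.table(co, file.path(dir, "coords.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(ds$truth_labels)) {
    lb <- data.frame(spot = ds$spot_ids, domain = ds$truth_labels)
    utils::write.table(lb, file.path(dir, "labels.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  meta <- list(normalized = ds$normalized,
               hvg_mask = ds$hvg_mask, gene_ids = ds$gene_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a spot dataset archive written by [write_spot_dataset()]
#'
#' @param dir archive directory.
#' @return A [spot_dataset()].
#' @export
read_spot_dataset <- function(dir) {
  ds <- load_spot_dataset(file.path(dir, "matrix.csv"),
                          file.path(dir, "coords.csv"))
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    ds$normalized <- isTRUE(meta$normalized)
    if (!is.null(meta$hvg_mask) && length(meta$hvg_mask))
      ds$hvg_mask <- as.logical(meta$hvg_mask)
  }
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    lb <- utils::read.table(lab_path, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE)
    ds$truth_labels <- as.integer(lb$domain[match(ds$spot_ids, as.character(lb$spot))])
  }
  ds
}

#' Subset spots with a logical mask
#'
#' Rows of the expression matrix, coordinates, spot ids and (when present)
#' truth labels are subset consistently; spot order is preserved.
#'
#' @param ds a [spot_dataset()].
#' @param in_tissue_mask logical vector of length `n`; `TRUE` keeps a spot.
#' @return The filtered [spot_dataset()].
#' @export
filter_spots <- function(ds, in_tissue_mask) {
  stopifnot(inherits(ds, "spot_dataset"))
  in_tissue_mask <- as.logical(in_tissue_mask)
  if (length(in_tissue_mask) != nrow(ds$X))
    stop("mask length ", length(in_tissue_mask), " != number of spots ", nrow(ds$X))
  if (anyNA(in_tissue_mask)) stop("mask contains NA")
  if (!any(in_tissue_mask)) stop("no spots remain after filtering")
  spot_dataset(ds$X[in_tissue_mask, , drop = FALSE],
               ds$coords[in_tissue_mask, , drop = FALSE],
               spot_ids = ds$spot_ids[in_tissue_mask],
               gene_ids = ds$gene_ids,
               truth_labels = if (!is.null(ds$truth_labels)) ds$truth_labels[in_tissue_mask],
               normalized = ds$normalized, hvg_mask = ds$hvg_mask)
}

#' Drop spots with zero total counts
#'
#' Library-size normalization is undefined for spots with an empty library;
#' this pre-filter removes them and reports how many were dropped.
#'
#' @param ds a raw-count [spot_dataset()].
#' @return The filtered [spot_dataset()].
#' @export
drop_empty_spots <- function(ds) {
  stopifnot(inherits(ds, "spot_dataset"))
  lib <- rowSums(ds$X)
  if (all(lib > 0)) return(ds)
  message("drop_empty_spots: removing ", sum(lib == 0), " zero-count spot(s)")
  filter_spots(ds, lib > 0)
}

#' Library-size normalization followed by log1p
#'
#' Each spot's counts are scaled so the library sums to `target_sum`, then
#' transformed elementwise with `log(1 + x)`. The standard preprocessing
#' for sequencing-based spatial data before embedding.
#'
#' @param ds a raw [spot_dataset()] (`normalized = FALSE`).
#' @param target_sum per-spot total after scaling; default `1e4`.
#' @return The normalized [spot_dataset()] with `normalized = TRUE`.
#' @export
normalize_log1p <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (ds$normalized) stop("dataset is already normalized")
  stopifnot(target_sum > 0)
  lib <- rowSums(ds$X)
  if (any(lib == 0))
    stop("zero library size for spot(s): ",
         paste(ds$spot_ids[lib == 0], collapse = ", "),
         "; run drop_empty_spots() first")
  Xn <- log1p(ds$X * (target_sum / lib))
  spot_dataset(Xn, ds$coords, spot_ids = ds$spot_ids, gene_ids = ds$gene_ids,
               truth_labels = ds$truth_labels, normalized = TRUE,
               hvg_mask = ds$hvg_mask)
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by dispersion (variance / mean of the normalized values;
#' genes with zero mean get dispersion 0) and keeps the top `n_top`.
#' Gene order is preserved; ties are broken by gene id. The selection is
#' recorded in `hvg_mask`.
#'
#' @param ds a normalized [spot_dataset()].
#' @param n_top number of genes to keep (default 3000, a Visium-scale
#'   convention; capped at the number of genes by the caller if needed).
#' @return A [spot_dataset()] restricted to the selected genes.
#' @export
select_hvg <- function(ds, n_top = 3000) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (!ds$normalized) stop("select_hvg expects a normalized dataset")
  g <- ncol(ds$X)
  if (n_top < 1 || n_top > g)
    stop("n_top must be in [1, ", g, "], got ", n_top)
  mu <- colMeans(ds$X)
  v <- apply(ds$X, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, ds$gene_ids)
  keep_idx <- sort(ord[seq_len(n_top)])
  mask <- logical(g)
  mask[keep_idx] <- TRUE
  spot_dataset(ds$X[, keep_idx, drop = FALSE], ds$coords,
               spot_ids = ds$spot_ids, gene_ids = ds$gene_ids[keep_idx],
               truth_labels = ds$truth_labels, normalized = TRUE,
               hvg_mask = rep(TRUE, n_top))
}
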