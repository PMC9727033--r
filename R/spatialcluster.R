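#' DBSCAN parameters for localization clustering
#'
#' The defaults are the deliberately "loose" setting used to propose
#' receptor clusters from localization maps: neighbourhood length-scale
#' 120 nm and minimum neighbourhood size 4. `n_min` counts the point itself
#' (minPts-inclusive convention — implementations differ, so the convention
#' is pinned here: 4 points pairwise within 120 nm always form a cluster).
#'
#' @param length_scale neighbourhood radius, nm (default 120).
#' @param n_min minimum points (self-inclusive) for a core point (default 4).
#' @param min_detections optional curation filter: drop clusters with fewer
#'   detections (default `NULL`, off).
#' @param max_r_gyration optional curation filter: drop clusters with larger
#'   radius of gyration in nm (default `NULL`, off).
#' @return a list of class `clustering_params`.
#' @export
clustering_params <- function(length_scale = 120, n_min = 4L,
                              min_detections = NULL, max_r_gyration = NULL) {
  check_that(is_number(length_scale, 0, strict = TRUE),
             "length_scale must be > 0")
  check_that(is_count(n_min, 1L), "n_min must be an integer >= 1")
  structure(list(length_scale = length_scale, n_min = as.integer(n_min),
                 min_detections = min_detections,
                 max_r_gyration = max_r_gyration),
            class = "clustering_params")
}

#' Cluster localizations with DBSCAN
#'
#' Standard DBSCAN semantics with the conventions documented in
#' [clustering_params()]: a point is core if at least `n_min` points
#' (including itself) lie within `length_scale`; clusters are maximal
#' density-connected sets; remaining points are noise. Cluster memberships
#' are invariant to input ordering (labels may permute); border points are
#' attached to the first core cluster that reaches them in deterministic
#' scan order.
#'
#' @param locs data.frame with `x_nm` and `y_nm` columns (extra columns are
#'   kept), or a two-column matrix.
#' @param params a [clustering_params()].
#' @return a list with `clusters` (data.frame: cluster_id, centroid_x_nm,
#'   centroid_y_nm, n_detections, r_gyration_nm), `labels` (integer per
#'   localization, 0 = noise) and `locs` (the input with a `cluster_id`
#'   column).
#' @export
dbscan_cluster <- function(locs, params = clustering_params()) {
  if (is.matrix(locs)) {
    locs <- data.frame(x_nm = locs[, 1], y_nm = locs[, 2])
  }
  check_that(all(c("x_nm", "y_nm") %in% names(locs)),
             "locs must have x_nm and y_nm columns")
  empty_clusters <- data.frame(cluster_id = integer(0),
                               centroid_x_nm = numeric(0),
                               centroid_y_nm = numeric(0),
                               n_detections = integer(0),
                               r_gyration_nm = numeric(0))
  if (nrow(locs) == 0) {
    locs$cluster_id <- integer(0)
    return(list(clusters = empty_clusters, labels = integer(0), locs = locs))
  }
  check_that(all(is.finite(locs$x_nm)) && all(is.finite(locs$y_nm)),
             "positions must be finite")
  labels <- .dbscan_grid(locs$x_nm, locs$y_nm, params$length_scale,
                         params$n_min)
  locs$cluster_id <- labels
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(list(clusters = empty_clusters, labels = labels, locs = locs))
  }
  dt <- data.table::as.data.table(locs[labels > 0, c("x_nm", "y_nm",
                                                     "cluster_id")])
  agg <- dt[, list(centroid_x_nm = mean(x_nm), centroid_y_nm = mean(y_nm),
                   n_detections = .N,
                   r_gyration_nm = sqrt(mean((x_nm - mean(x_nm))^2 +
                                               (y_nm - mean(y_nm))^2))),
            by = "cluster_id"]
  data.table::setorderv(agg, "cluster_id")
  clusters <- as.data.frame(agg)
  # optional automated curation (replaces the interactive selection step)
  drop <- rep(FALSE, nrow(clusters))
  if (!is.null(params$min_detections)) {
    drop <- drop | clusters$n_detections < params$min_detections
  }
  if (!is.null(params$max_r_gyration)) {
    drop <- drop | clusters$r_gyration_nm > params$max_r_gyration
  }
  if (any(drop)) {
    dropped <- clusters$cluster_id[drop]
    labels[labels %in% dropped] <- 0L
    locs$cluster_id <- labels
    clusters <- clusters[!drop, , drop = FALSE]
  }
  list(clusters = clusters, labels = labels, locs = locs)
}

#' Build a subcellular region mask
#'
#' Combines a cell mask and a nucleus mask into a label image:
#' 0 = outside the cell, 1 = plasma-membrane band (the cell-boundary
#' neighbourhood of width `pm_band_px`), 2 = cytoplasm, 3 = nucleus.
#'
#' @param nucleus_mask,cell_mask logical matrices of equal size; the nucleus
#'   must be contained in the cell.
#' @param pm_band_px width of the membrane band in pixels (default 2).
#' @param pixel_size_nm pixel pitch of the masks, nm.
#' @return a list of class `region_mask`: `labels` (integer matrix) and
#'   `pixel_size_nm`.
#' @export
build_region_mask <- function(nucleus_mask, cell_mask, pm_band_px = 2L,
                              pixel_size_nm) {
  check_that(is.matrix(nucleus_mask) && is.matrix(cell_mask) &&
               all(dim(nucleus_mask) == dim(cell_mask)),
             "masks must be matrices of equal size")
  check_that(is_count(pm_band_px, 1L), "pm_band_px must be >= 1")
  check_that(is_number(pixel_size_nm, 0, strict = TRUE),
             "pixel_size_nm must be > 0")
  nucleus_mask <- nucleus_mask != 0
  cell_mask <- cell_mask != 0
  check_that(!any(nucleus_mask & !cell_mask),
             "nucleus mask must be contained in the cell mask")
  se <- matrix(TRUE, 3L, 3L)
  eroded <- cell_mask
  for (k in seq_len(pm_band_px)) eroded <- .binary_erode(eroded, se)
  labels <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  labels[cell_mask & !eroded] <- 1L              # plasma-membrane band
  labels[eroded] <- 2L                           # cytoplasm
  labels[nucleus_mask] <- 3L                     # nucleus wins
  structure(list(labels = labels, pixel_size_nm = pixel_size_nm),
            class = "region_mask")
}

REGION_NAMES <- c("outside", "plasma_membrane", "cytoplasm", "nucleus")

#' Assign clusters to subcellular regions
#'
#' Each cluster takes the mask label at its centroid pixel (the
#' cluster-level convention; a majority vote over members is available as
#' an option). Centroids outside the mask frame are labelled `outside`;
#' such clusters should be excluded from region statistics.
#'
#' @param clusters data.frame from [dbscan_cluster()] (needs
#'   `centroid_x_nm`, `centroid_y_nm`; for `method = "majority"` pass the
#'   full [dbscan_cluster()] result instead).
#' @param mask a [build_region_mask()] result.
#' @param method `"centroid"` (default) or `"majority"`.
#' @return the cluster data.frame with a `region` factor column.
#' @export
assign_regions <- function(clusters, mask, method = c("centroid",
                                                      "majority")) {
  method <- match.arg(method)
  check_that(inherits(mask, "region_mask"), "mask must be a region_mask")
  full <- NULL
  if (is.list(clusters) && !is.data.frame(clusters) &&
      !is.null(clusters$clusters)) {
    full <- clusters
    clusters <- clusters$clusters
  }
  label_at <- function(x_nm, y_nm) {
    j <- floor(x_nm / mask$pixel_size_nm) + 1L
    i <- floor(y_nm / mask$pixel_size_nm) + 1L
    ok <- i >= 1 & i <= nrow(mask$labels) & j >= 1 & j <= ncol(mask$labels)
    out <- rep(0L, length(x_nm))
    out[ok] <- mask$labels[cbind(i[ok], j[ok])]
    out
  }
  if (method == "centroid" || is.null(full)) {
    lab <- label_at(clusters$centroid_x_nm, clusters$centroid_y_nm)
  } else {
    member_lab <- label_at(full$locs$x_nm, full$locs$y_nm)
    lab <- vapply(clusters$cluster_id, function(id) {
      tab <- table(member_lab[full$locs$cluster_id == id])
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
  }
  clusters$region <- factor(REGION_NAMES[lab + 1L], levels = REGION_NAMES)
  n_out <- sum(clusters$region == "outside")
  if (n_out > 0) {
    message(n_out, " cluster(s) fell outside the cell mask")
  }
  clusters
}
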