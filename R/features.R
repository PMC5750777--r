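#' Morphometric and intensity features of a segmented cell
#'
#' The feature extractor targets 17 features of the nucleus, cytoplasm and
#' whole cell: geometry (areas, axes, aspect ratio, perimeter, roundness,
#' compactness, nucleus/cytoplasm ratio), intensity (mean brightness, counts
#' of local extrema, GLCM homogeneity) and texture (a 38-entry LBP
#' histogram-Fourier descriptor), for a total feature vector of 54 named
#' entries.
#'
#' @name features
NULL

# ---- geometry ---------------------------------------------------------------

# Moments-equivalent ellipse axis lengths of a pixel region: the ellipse with
# the same second central moments as the pixel set (the regionprops
# convention). Returns c(major, minor). For a filled ellipse with semi-axes
# (a, b) this converges to (2a, 2b).
ellipse_axes <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(c(major = 0, minor = 0))
  cr <- coords[, 1] - mean(coords[, 1])
  cc <- coords[, 2] - mean(coords[, 2])
  m20 <- sum(cr * cr) / n
  m02 <- sum(cc * cc) / n
  m11 <- sum(cr * cc) / n
  tr <- m20 + m02
  det <- m20 * m02 - m11 * m11
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Region perimeter by boundary-pixel count
#'
#' Counts the region pixels that touch the background through at least one
#' 4-neighbour (pixels on the image border count as touching background).
#' Because a staircase boundary under-measures Euclidean length by a factor
#' of \eqn{2\sqrt2/\pi \approx 0.90} on isotropic shapes, the count is by
#' default multiplied by the isotropic correction \eqn{\pi/(2\sqrt2)}, which
#' brings the compactness of rasterized disks within a few percent of the
#' ideal \eqn{4\pi}. Set `correct = FALSE` for the raw pixel count.
#'
#' @param region Logical matrix marking the region.
#' @param correct Apply the isotropic staircase correction (default TRUE).
#' @return Perimeter estimate in pixel units.
#' @export
region_perimeter <- function(region, correct = TRUE) {
  if (!any(region)) stopf("empty region has no perimeter")
  interior <- shift_mat(region, 1, 0, FALSE) & shift_mat(region, -1, 0, FALSE) &
    shift_mat(region, 0, 1, FALSE) & shift_mat(region, 0, -1, FALSE)
  n <- sum(region & !interior)
  if (correct) n * pi / (2 * sqrt(2)) else as.numeric(n)
}

#' Geometric features of a segmented cell
#'
#' Computes the shape features: nucleus area `A_n` (pixel count), major and
#' minor axis lengths `L_n`, `D_n` of the moments-equivalent ellipse of the
#' nucleus, bounding-box aspect ratio `R_n = W_n / H_n`, nucleus perimeter
#' `P_n`, nucleus roundness `A_n / (pi/4 * L_n^2)`, whole-cell area
#' `A_cell`, whole-cell compactness `C_cell = P_cell^2 / A_cell` and the
#' nucleus/cytoplasm area ratio `R_cell`.
#'
#' @param cell A [segmented_cell()].
#' @param perimeter_correct Passed to [region_perimeter()].
#' @return Named list with entries `A_n, L_n, D_n, W_n, H_n, R_n, P_n,
#'   N_roundness, A_cell, P_cell, C_cell, R_cell`.
#' @export
region_geometry <- function(cell, perimeter_correct = TRUE) {
  stopifnot(inherits(cell, "segmented_cell"))
  nuc <- cell$mask == 2L
  cyto <- cell$mask == 1L
  whole <- cell$mask >= 1L
  coords <- which(nuc, arr.ind = TRUE)
  A_n <- nrow(coords)
  ax <- ellipse_axes(coords)
  W_n <- diff(range(coords[, 2])) + 1
  H_n <- diff(range(coords[, 1])) + 1
  P_n <- region_perimeter(nuc, correct = perimeter_correct)
  N_circle <- pi / 4 * ax[["major"]]^2
  A_cell <- sum(whole)
  P_cell <- region_perimeter(whole, correct = perimeter_correct)
  list(
    A_n = A_n,
    L_n = ax[["major"]],
    D_n = ax[["minor"]],
    W_n = W_n,
    H_n = H_n,
    R_n = W_n / H_n,
    P_n = P_n,
    N_roundness = if (N_circle > 0) A_n / N_circle else 0,
    A_cell = A_cell,
    P_cell = P_cell,
    C_cell = P_cell^2 / A_cell,
    R_cell = A_n / sum(cyto)
  )
}

# ---- intensity --------------------------------------------------------------

#' Count strict local extrema within a region
#'
#' A pixel counts as a local maximum (minimum) when it is strictly greater
#' (smaller) than every available 8-neighbour, where "available" means the
#' neighbour lies inside both the image and the region. Pixels with no
#' available neighbour never count, and plateaus contribute nothing because
#' the comparison is strict.
#'
#' @param intensity Numeric intensity matrix.
#' @param region Logical matrix, same shape, marking the region.
#' @param mode `"max"` or `"min"`.
#' @return Integer count.
#' @export
local_extrema_count <- function(intensity, region, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (!any(region)) stopf("empty region")
  stopifnot(all(dim(intensity) == dim(region)))
  masked <- ifelse(region, intensity, NA_real_)
  n_avail <- matrix(0L, nrow(region), ncol(region))
  n_pass <- matrix(0L, nrow(region), ncol(region))
  for (i in seq_len(nrow(NEIGH8))) {
    nb <- shift_mat(masked, NEIGH8[i, 1], NEIGH8[i, 2], NA_real_)
    avail <- !is.na(nb)
    cmp <- if (mode == "max") intensity > nb else intensity < nb
    cmp[!avail] <- FALSE
    n_avail <- n_avail + avail
    n_pass <- n_pass + cmp
  }
  sum(region & n_avail > 0L & n_pass == n_avail)
}

#' GLCM homogeneity of a region
#'
#' Quantizes intensities uniformly into `levels` gray levels, accumulates
#' the symmetric gray-level co-occurrence matrix over pixel pairs at the
#' given `offset` with both pixels inside the region, normalizes it to a
#' joint probability `p(i, j)`, and returns
#' \deqn{H = \sum_i \sum_j \frac{p(i,j)}{1 + |i - j|},}
#' which is 1 exactly when the quantized region is constant and decreases
#' with local gray-level contrast.
#'
#' @param intensity Numeric matrix with values in \[0, 255\].
#' @param region Logical matrix marking the region.
#' @param levels Number of gray levels for uniform quantization (default 8).
#' @param offset Integer `c(dr, dc)` pixel displacement (default `c(0, 1)`,
#'   i.e. horizontal neighbours).
#' @return Homogeneity in \[0, 1\].
#' @export
glcm_homogeneity <- function(intensity, region, levels = 8L,
                             offset = c(0L, 1L)) {
  stopifnot(all(dim(intensity) == dim(region)), levels >= 2L)
  q <- matrix(pmin(floor(intensity * levels / 256), levels - 1L),
              nrow(intensity), ncol(intensity))
  a_ok <- region & shift_mat(region, -offset[1], -offset[2], FALSE)
  if (!any(a_ok))
    stopf("region contains no co-occurring pixel pair for offset (%d, %d)",
          offset[1], offset[2])
  qb <- shift_mat(q, -offset[1], -offset[2], NA_real_)
  i <- q[a_ok]
  j <- qb[a_ok]
  counts <- matrix(0, levels, levels)
  for (idx in seq_along(i))
    counts[i[idx] + 1L, j[idx] + 1L] <- counts[i[idx] + 1L, j[idx] + 1L] + 1
  counts <- counts + t(counts)   # symmetric accumulation
  p <- counts / sum(counts)
  lev <- seq_len(levels)
  w <- 1 / (1 + abs(outer(lev, lev, "-")))
  sum(p * w)
}

#' Mean brightness of a region
#'
#' @param intensity Numeric intensity matrix.
#' @param region Logical matrix marking the region.
#' @return Arithmetic mean intensity over the region.
#' @export
mean_brightness <- function(intensity, region) {
  if (!any(region)) stopf("empty region")
  stopifnot(all(dim(intensity) == dim(region)))
  mean(intensity[region])
}

# ---- assembly ---------------------------------------------------------------

#' Names of the 54 feature-vector entries
#'
#' 16 scalar features followed by the 38 LBP histogram-Fourier entries.
#' The order is fixed: it is the column schema of every feature table the
#' package reads or writes.
#'
#' @return Character vector of length 54.
#' @export
feature_names <- function() {
  c("A_n", "L_n", "D_n", "R_n", "P_n", "N_roundness",
    "Max_n", "Min_n", "H_n", "B_n",
    "Max_c", "Min_c", "B_c",
    "A_cell", "C_cell", "R_cell",
    lbp_hf_names())
}

#' Extract the full 54-entry feature vector from a segmented cell
#'
#' Computes all geometric, intensity and texture features: nucleus area,
#' axis lengths, aspect ratio, perimeter, roundness, local maxima/minima
#' counts and GLCM homogeneity and brightness of the nucleus; maxima/minima
#' counts and brightness of the cytoplasm; whole-cell area, compactness and
#' nucleus/cytoplasm ratio; and the 38-entry LBP histogram-Fourier texture
#' descriptor of the whole-cell region.
#'
#' @param cell A [segmented_cell()].
#' @param glcm_levels Gray levels for the homogeneity feature (default 8).
#' @param glcm_offset Co-occurrence displacement (default `c(0, 1)`).
#' @param perimeter_correct Passed to [region_perimeter()].
#' @return Named numeric vector of length 54 (see [feature_names()]).
#'
#' @examples
#' cell <- generate_cell(cell_class_specs()[["carcinoma_in_situ"]])
#' fv <- extract_features(cell)
#' length(fv)  # 54
#' fv[c("A_n", "R_cell", "H_n")]
#' @export
extract_features <- function(cell, glcm_levels = 8L, glcm_offset = c(0L, 1L),
                             perimeter_correct = TRUE) {
  stopifnot(inherits(cell, "segmented_cell"))
  nuc <- cell$mask == 2L
  cyto <- cell$mask == 1L
  whole <- cell$mask >= 1L
  g <- region_geometry(cell, perimeter_correct = perimeter_correct)
  v <- c(
    A_n = g$A_n, L_n = g$L_n, D_n = g$D_n, R_n = g$R_n, P_n = g$P_n,
    N_roundness = g$N_roundness,
    Max_n = local_extrema_count(cell$intensity, nuc, "max"),
    Min_n = local_extrema_count(cell$intensity, nuc, "min"),
    H_n = glcm_homogeneity(cell$intensity, nuc, levels = glcm_levels,
                           offset = glcm_offset),
    B_n = mean_brightness(cell$intensity, nuc),
    Max_c = local_extrema_count(cell$intensity, cyto, "max"),
    Min_c = local_extrema_count(cell$intensity, cyto, "min"),
    B_c = mean_brightness(cell$intensity, cyto),
    A_cell = g$A_cell, C_cell = g$C_cell, R_cell = g$R_cell
  )
  c(v, lbp_hf(cell$intensity, whole))
}

#' Extract a feature table from a list of cells
#'
#' @param cells List of `segmented_cell` objects.
#' @param labels Optional class labels (factor or character), one per cell.
#' @param ids Optional cell identifiers; defaults to `cell_1 ... cell_n`.
#' @param ... Passed to [extract_features()].
#' @return Data frame with columns `cell_id`, `class` (if labels given) and
#'   the 54 feature columns in [feature_names()] order.
#' @export
extract_feature_table <- function(cells, labels = NULL, ids = NULL, ...) {
  stopifnot(length(cells) >= 1L)
  if (is.null(ids)) ids <- sprintf("cell_%d", seq_along(cells))
  m <- t(vapply(cells, extract_features, numeric(54), ...))
  out <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(cells))
    out$class <- as.character(labels)
  }
  cbind(out, as.data.frame(m))
}

#' Read / write feature tables
#'
#' CSV round-trip helpers for the fixed 54-column feature schema plus
#' `cell_id` and optional `class` columns.
#'
#' @param x Feature table (data frame) as produced by
#'   [extract_feature_table()].
#' @param path CSV path.
#' @return `read_feature_table` returns the data frame;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(feature_names(), names(x))
  if (length(miss))
    stopf("feature table is missing %d schema columns (first: %s)",
          length(miss), miss[1])
  x
}
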