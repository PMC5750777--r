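#' Class specifications for synthetic Pap-smear cells
#'
#' Seven cell classes ordered along the normal-to-malignant axis: three
#' normal types (superficial squamous, intermediate squamous, columnar)
#' and four abnormal grades (light, moderate and severe dysplastic,
#' carcinoma in situ). Along that axis the generator's defaults encode the
#' morphological progression of dysplasia: the nucleus enlarges, the
#' nucleus/cytoplasm area ratio rises, nuclear chromatin darkens, the
#' boundary grows more irregular and the texture coarsens.
#'
#' @return Named list of `cell_class_spec` lists with fields
#'   `name`, `nucleus_radius` (range, px), `cytoplasm_radius` (range, px),
#'   `nucleus_brightness`, `cytoplasm_brightness` (mean gray values),
#'   `noise_sd`, `irregularity` (relative boundary perturbation amplitude)
#'   and `grain` (texture correlation scale, px).
#' @export
cell_class_specs <- function() {
  spec <- function(name, nr, cr, bn, bc, sd, irr, grain) {
    structure(list(name = name, nucleus_radius = nr, cytoplasm_radius = cr,
                   nucleus_brightness = bn, cytoplasm_brightness = bc,
                   noise_sd = sd, irregularity = irr, grain = grain),
              class = "cell_class_spec")
  }
  list(
    superficial        = spec("superficial",        c(3, 5),   c(28, 34), 180, 205, 8, 0.04, 1),
    intermediate       = spec("intermediate",       c(4, 6),   c(26, 32), 170, 200, 8, 0.05, 1),
    columnar           = spec("columnar",           c(6, 8),   c(20, 26), 160, 195, 9, 0.06, 2),
    light_dysplastic   = spec("light_dysplastic",   c(8, 11),  c(22, 28), 150, 190, 10, 0.10, 2),
    moderate_dysplastic= spec("moderate_dysplastic",c(10, 13), c(20, 26), 135, 180, 11, 0.15, 3),
    severe_dysplastic  = spec("severe_dysplastic",  c(12, 15), c(18, 24), 115, 170, 12, 0.22, 3),
    carcinoma_in_situ  = spec("carcinoma_in_situ",  c(14, 17), c(19, 24), 95,  165, 13, 0.28, 4)
  )
}

#' Reference per-class cell counts
#'
#' The class distribution of the Herlev single-cell benchmark (917 cells),
#' used as the default class proportions for synthetic datasets.
#'
#' @return Named integer vector over the seven classes in
#'   [cell_class_specs()] order.
#' @export
herlev_counts <- function() {
  c(superficial = 74L, intermediate = 70L, columnar = 98L,
    light_dysplastic = 182L, moderate_dysplastic = 146L,
    severe_dysplastic = 197L, carcinoma_in_situ = 150L)
}

# Smooth positive-scale noise field: white Gaussian noise box-blurred at
# `grain` pixels, then restandardized, so the marginal sd stays ~1 while
# the spatial correlation length grows with grain.
textured_noise <- function(nr, nc, grain) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (grain > 1) {
    k <- rep(1 / grain, grain)
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
    z <- (z - mean(z)) / stats::sd(z)
  }
  z
}

#' Generate one synthetic segmented cell
#'
#' Draws a cell of the given class: a cytoplasm blob and, fully inside it,
#' a nucleus whose boundary is an ellipse-like shape with a sinusoidal
#' radial perturbation (amplitude = the class's irregularity). Intensities
#' are class-specific means plus spatially correlated Gaussian texture,
#' rounded and clamped to 0-255. Uses the current RNG stream: seed the
#' stream (or use [generate_cells()]) for reproducibility.
#'
#' @param spec A `cell_class_spec` from [cell_class_specs()].
#' @param size Image side length in pixels (default 100).
#' @return A [segmented_cell()].
#' @export
generate_cell <- function(spec, size = 100L) {
  stopifnot(inherits(spec, "cell_class_spec"))
  ctr <- (size + 1) / 2
  r_c <- stats::runif(1, spec$cytoplasm_radius[1], spec$cytoplasm_radius[2])
  r_n <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
  ecc <- stats::runif(1, 0.75, 1)            # mild elongation
  theta0 <- stats::runif(1, 0, 2 * pi)
  lobes <- sample(2:5, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- spec$irregularity
  amp_c <- 0.05
  # nucleus centre jitter, capped so the perturbed nucleus stays inside
  max_off <- max(r_c * (1 - amp_c) - r_n * (1 + amp) - 2, 0)
  off_r <- stats::runif(1, 0, max_off * 0.5)
  off_a <- stats::runif(1, 0, 2 * pi)
  ncr <- ctr + off_r * sin(off_a)
  ncc <- ctr + off_r * cos(off_a)

  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)

  ang_c <- atan2(rows - ctr, cols - ctr)
  rad_c <- r_c * (1 + amp_c * sin(3 * ang_c + phase))
  d_c <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  in_cyto <- d_c <= rad_c

  ang_n <- atan2(rows - ncr, cols - ncc)
  # elliptical base radius plus perturbation
  base <- r_n / sqrt((cos(ang_n - theta0))^2 + (sin(ang_n - theta0) / ecc)^2)
  rad_n <- base * (1 + amp * sin(lobes * ang_n + phase))
  d_n <- sqrt((rows - ncr)^2 + (cols - ncc)^2)
  in_nuc <- d_n <= rad_n & in_cyto

  mask <- matrix(0L, size, size)
  mask[in_cyto] <- 1L
  mask[in_nuc] <- 2L

  tex <- textured_noise(size, size, spec$grain)
  img <- matrix(230, size, size) + 2 * matrix(stats::rnorm(size * size), size, size)
  img[in_cyto] <- spec$cytoplasm_brightness + spec$noise_sd * tex[in_cyto]
  img[in_nuc] <- spec$nucleus_brightness + spec$noise_sd * tex[in_nuc]
  img <- matrix(pmin(pmax(round(img), 0), 255), size, size)
  segmented_cell(img, mask)
}

#' Generate a labelled set of synthetic cells
#'
#' @param counts Named integer vector of per-class cell counts over (a
#'   subset of) the classes in [cell_class_specs()]; default
#'   [herlev_counts()].
#' @param size Image side length in pixels.
#' @param seed Integer seed; the full set is reproducible from it.
#' @return List with `cells` (list of `segmented_cell`), `labels` (factor)
#'   and `ids` (character).
#' @export
generate_cells <- function(counts = herlev_counts(), size = 100L, seed = 1L) {
  specs <- cell_class_specs()
  bad <- setdiff(names(counts), names(specs))
  if (length(bad)) stopf("unknown cell class '%s'", bad[1])
  with_seed(seed, {
    cells <- list(); labels <- character(); ids <- character()
    for (cl in names(counts)) {
      for (i in seq_len(counts[[cl]])) {
        cells[[length(cells) + 1L]] <- generate_cell(specs[[cl]], size = size)
        labels <- c(labels, cl)
        ids <- c(ids, sprintf("%s_%03d", cl, i))
      }
    }
    list(cells = cells, labels = factor(labels, levels = names(specs)),
         ids = ids)
  })
}

#' Write a synthetic cell set as image pairs plus a manifest
#'
#' Creates one directory per class containing `<id>.png` /
#' `<id>_mask.png` pairs, and a `manifest.csv` with columns `cell_id`,
#' `class`, `image`, `mask` (paths relative to `dir`).
#'
#' @param cellset Output of [generate_cells()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cells <- function(cellset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cellset$cells)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- as.character(cellset$labels[i])
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    img <- file.path(cl, sprintf("%s.png", cellset$ids[i]))
    msk <- file.path(cl, sprintf("%s_mask.png", cellset$ids[i]))
    write_cell(cellset$cells[[i]], file.path(dir, img), file.path(dir, msk))
    rows[[i]] <- data.frame(cell_id = cellset$ids[i], class = cl,
                            image = img, mask = msk,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell set written by [write_cells()]
#'
#' @param dir Directory holding `manifest.csv` and the image pairs.
#' @return List with `cells`, `labels`, `ids` as in [generate_cells()].
#' @export
read_cells <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(manifest)), function(i)
    read_cell(file.path(dir, manifest$image[i]),
              file.path(dir, manifest$mask[i])))
  list(cells = cells, labels = factor(manifest$class), ids = manifest$cell_id)
}

#' Generate a feature table with planted informative columns
#'
#' Oracle fixture for the wrapper: `d_informative` columns carry a class
#' signal on top of unit-variance Gaussian noise, while `d_noise` columns
#' are pure standard Gaussian noise. `effect_size` is the separation of
#' adjacent class centroids across the whole informative block, in
#' noise-sd units: each informative column assigns the classes means
#' `effect_size / sqrt(d_informative)` times a random permutation of
#' `0 .. n_classes - 1`, so the per-column signal is deliberately partial
#' and the full planted set is needed to realise the nominal separation.
#' Informative columns are scattered among the noise columns at random
#' positions; the ground-truth index set is returned. With
#' `effect_size = 0` every column is noise and any classifier can only
#' reach chance level.
#'
#' @param n Number of rows; must be at least `10 * n_classes`.
#' @param d_informative,d_noise Column counts.
#' @param effect_size Class-mean separation in noise-sd units.
#' @param n_classes Number of classes (balanced up to remainders).
#' @param seed Integer seed.
#' @return List with `x` (data frame, columns `f1 ... f(d)`), `y` (factor
#'   `c1 ... c<n_classes>`) and `informative` (integer column indices).
#' @export
generate_feature_table <- function(n, d_informative = 5L, d_noise = 25L,
                                   effect_size = 3, n_classes = 7L,
                                   seed = 1L) {
  if (n < 10L * n_classes)
    stopf("need n >= 10 * n_classes (n = %d, classes = %d)", n, n_classes)
  d <- d_informative + d_noise
  with_seed(seed, {
    y <- factor(sprintf("c%d", rep_len(seq_len(n_classes), n)),
                levels = sprintf("c%d", seq_len(n_classes)))
    x <- matrix(stats::rnorm(n * d), n, d)
    pos <- sort(sample.int(d, d_informative))
    per_col <- effect_size / sqrt(d_informative)
    for (j in pos) {
      mu <- per_col * sample(seq_len(n_classes) - 1L)
      x[, j] <- x[, j] + mu[as.integer(y)]
    }
    colnames(x) <- sprintf("f%d", seq_len(d))
    list(x = as.data.frame(x), y = y, informative = pos)
  })
}
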