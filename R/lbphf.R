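#' Rotation-invariant LBP histogram-Fourier texture descriptor
#'
#' Local binary patterns with 8 neighbours at radius 1 assign each pixel an
#' 8-bit code: bit k is 1 when the k-th neighbour (counter-clockwise from
#' east) is greater than or equal to the centre. Uniform codes (at most two
#' 0/1 transitions around the circle) fall into 7 rotation orbits indexed by
#' the number of set bits n = 1..7, each orbit holding the 8 rotations of a
#' single run of ones. Rotating the image permutes codes cyclically within
#' each orbit, so the magnitudes of the discrete Fourier transform of each
#' orbit's 8-bin histogram are rotation invariant; for a real histogram only
#' frequencies 0..4 carry distinct magnitudes. The descriptor concatenates
#' the 7 x 5 = 35 DFT magnitudes with the all-zeros, all-ones and
#' non-uniform histogram bins: 38 entries. The histogram is normalized by
#' the number of coded pixels before the transform.
#'
#' @param intensity Numeric intensity matrix.
#' @param region Logical matrix marking the region over which codes are
#'   accumulated. Codes are computed at region pixels whose full 3x3
#'   neighbourhood lies inside the image; neighbour intensities are taken
#'   from the image regardless of their own region label.
#' @return Named numeric vector of length 38 (see `lbp_hf_names()`).
#' @export
lbp_hf <- function(intensity, region) {
  stopifnot(all(dim(intensity) == dim(region)))
  n <- nrow(intensity); p <- ncol(intensity)
  if (n < 3L || p < 3L) stopf("image too small for 8-neighbour LBP")
  interior <- matrix(FALSE, n, p)
  interior[2:(n - 1), 2:(p - 1)] <- TRUE
  at <- region & interior
  if (!any(at)) stopf("region has no pixel with a full 8-neighbourhood")

  code <- matrix(0L, n, p)
  for (k in seq_len(8L)) {
    nb <- shift_mat(intensity, NEIGH8[k, 1], NEIGH8[k, 2], NA_real_)
    bit <- !is.na(nb) & nb >= intensity
    code <- code + bit * 2L^(k - 1L)
  }
  codes <- code[at]

  lut <- lbp_code_table()
  hist_total <- length(codes)
  cnt <- tabulate(codes + 1L, nbins = 256L) / hist_total

  h_all0 <- cnt[1L]           # code 0
  h_all1 <- cnt[256L]         # code 255
  h_nonu <- sum(cnt[lut$orbit == -1L])

  mags <- numeric(35L)
  for (orb in 1:7) {
    h <- numeric(8L)
    sel <- which(lut$orbit == orb)
    h[lut$rot[sel] + 1L] <- cnt[sel]
    f <- stats::fft(h)
    mags[(orb - 1L) * 5L + 1:5] <- Mod(f[1:5])
  }
  stats::setNames(c(mags, h_all0, h_all1, h_nonu), lbp_hf_names())
}

lbp_hf_names <- function() {
  c(sprintf("lbphf_o%d_f%d", rep(1:7, each = 5), rep(0:4, times = 7)),
    "lbphf_all0", "lbphf_all1", "lbphf_nonuniform")
}

# Classify all 256 LBP codes: orbit = number of ones for uniform codes with
# 1..7 ones, -1 for non-uniform, 0 for the two constant codes (0 and 255);
# rot = start position (0-based bit index) of the circular run of ones.
lbp_code_table <- function() {
  if (!is.null(.lbp_cache$tab)) return(.lbp_cache$tab)
  orbit <- integer(256L)
  rot <- integer(256L)
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != bits[c(2:8, 1)])
    ones <- sum(bits)
    if (ones %in% c(0L, 8L)) {
      orbit[code + 1L] <- 0L
    } else if (trans <= 2L) {
      orbit[code + 1L] <- ones
      # run start: bit k set while predecessor (k-1 mod 8) clear
      prev <- bits[c(8, 1:7)]
      rot[code + 1L] <- which(bits == 1L & prev == 0L) - 1L
    } else {
      orbit[code + 1L] <- -1L
    }
  }
  .lbp_cache$tab <- list(orbit = orbit, rot = rot)
  .lbp_cache$tab
}

.lbp_cache <- new.env(parent = emptyenv())
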