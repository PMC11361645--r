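#' Generate a two-channel punctate image pair with known colocalization
#'
#' Synthesizes the kind of two-channel fluorescence data that object-based
#' colocalization is applied to: isotropic Gaussian spots (width `psf_sigma`)
#' on Gaussian background noise, with a controllable true fraction of
#' co-placed objects. Exactly `round(coloc_fraction * n_objects)` object
#' centers are shared between the channels (offset by at most `jitter_px` per
#' axis); all remaining centers are placed at least `min_separation` pixels
#' from every object of the other channel, and objects within a channel are
#' also kept `min_separation` apart so that segmentation can recover them.
#' Coordinates are (row, col) in pixels, origin at the top-left pixel center.
#'
#' @param n_objects Objects per channel (>= 1).
#' @param coloc_fraction True colocalized fraction in \[0, 1\].
#' @param grid_shape Image dimensions `c(rows, cols)` (default 128 x 128).
#' @param psf_sigma Gaussian spot width, px.
#' @param min_separation Minimum center-to-center distance between
#'   non-co-placed objects, px. When `coloc_fraction = 0` this must exceed
#'   the matching tolerance used downstream or recovered colocalization will
#'   not be zero.
#' @param background_sd Gaussian background noise sd (intensity units; spot
#'   peak amplitude is ~1).
#' @param jitter_px Per-axis uniform jitter applied to the second channel's
#'   copy of each co-placed center, px (<= 0.5; default 0 so co-placed
#'   centroids coincide exactly).
#' @param amplitude_range Spot peak amplitudes drawn uniformly from this
#'   range.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per object before giving up with a
#'   placement error.
#' @return An `image_pair` list: `channel_a`, `channel_b` (matrices),
#'   `truth_centroids_a`, `truth_centroids_b` (tibbles `row`, `col`; the
#'   first `n_coloc` rows of each are the co-placed pairs, in order),
#'   `true_coloc_fraction`, `n_coloc`.
#' @export
generate_image_pair <- function(n_objects, coloc_fraction,
                                grid_shape = c(128, 128), psf_sigma = 2,
                                min_separation = 12, background_sd = 0.01,
                                jitter_px = 0, amplitude_range = c(0.8, 1.2),
                                seed = NULL, max_tries = 2000) {
  n_objects <- check_count(n_objects, "n_objects", min = 1L)
  check_number(coloc_fraction, "coloc_fraction", min = 0, max = 1)
  check_number(psf_sigma, "psf_sigma", min = 0, strict_min = TRUE)
  check_number(min_separation, "min_separation", min = 0)
  check_number(background_sd, "background_sd", min = 0)
  check_number(jitter_px, "jitter_px", min = 0, max = 0.5)
  if (length(grid_shape) != 2L || any(grid_shape < 16)) {
    abort_input("`grid_shape` must be two dimensions of at least 16 px.")
  }
  n_coloc <- round(coloc_fraction * n_objects)

  with_seed_scope(seed, {
    margin <- ceiling(4 * psf_sigma) + 1
    lo <- c(margin, margin)
    hi <- grid_shape - margin
    if (any(hi <= lo)) abort_input("Grid too small for the spot size.")

    draw_point <- function() c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    far_enough <- function(pt, others) {
      if (nrow(others) == 0L) return(TRUE)
      all(sqrt((others[, 1] - pt[1])^2 + (others[, 2] - pt[2])^2) >=
            min_separation)
    }
    place <- function(n, avoid) {
      placed <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          pt <- draw_point()
          if (far_enough(pt, rbind(avoid, placed))) { ok <- TRUE; break }
        }
        if (!ok) {
          abort_placement(sprintf(
            "Could not place %d objects at min_separation %g px in a %dx%d grid.",
            n, min_separation, grid_shape[1], grid_shape[2]))
        }
        placed <- rbind(placed, pt)
      }
      placed
    }

    shared <- place(n_coloc, matrix(numeric(0), ncol = 2))
    uniq_a <- place(n_objects - n_coloc, shared)
    uniq_b <- place(n_objects - n_coloc, rbind(shared, uniq_a))

    shared_b <- shared
    if (n_coloc > 0 && jitter_px > 0) {
      shared_b <- shared + matrix(runif(2 * n_coloc, -jitter_px, jitter_px),
                                  ncol = 2)
    }
    cents_a <- rbind(shared, uniq_a)
    cents_b <- rbind(shared_b, uniq_b)

    render <- function(cents) {
      img <- matrix(0, grid_shape[1], grid_shape[2])
      if (nrow(cents) > 0) {
        amps <- runif(nrow(cents), amplitude_range[1], amplitude_range[2])
        w <- ceiling(4 * psf_sigma)
        for (i in seq_len(nrow(cents))) {
          r0 <- cents[i, 1]; c0 <- cents[i, 2]
          rr <- max(1, floor(r0 - w)):min(grid_shape[1], ceiling(r0 + w))
          cc <- max(1, floor(c0 - w)):min(grid_shape[2], ceiling(c0 + w))
          spot <- amps[i] *
            exp(-(outer((rr - r0)^2, (cc - c0)^2, `+`)) / (2 * psf_sigma^2))
          img[rr, cc] <- img[rr, cc] + spot
        }
      }
      if (background_sd > 0) {
        img <- img + matrix(rnorm(prod(grid_shape), sd = background_sd),
                            grid_shape[1], grid_shape[2])
      }
      pmax(img, 0)
    }

    structure(list(
      channel_a = render(cents_a),
      channel_b = render(cents_b),
      truth_centroids_a = tibble(row = cents_a[, 1], col = cents_a[, 2]),
      truth_centroids_b = tibble(row = cents_b[, 1], col = cents_b[, 2]),
      true_coloc_fraction = coloc_fraction,
      n_coloc = n_coloc
    ), class = "image_pair")
  })
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf(
    "<image_pair: %dx%d px, %d objects/channel, %d co-placed (true fraction %.2f)>\n",
    nrow(x$channel_a), ncol(x$channel_a), nrow(x$truth_centroids_a),
    x$n_coloc, x$true_coloc_fraction))
  invisible(x)
}
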