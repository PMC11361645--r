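check_image_pair_args <- function(img_a, img_b) {
  if (!is.matrix(img_a) || !is.matrix(img_b)) {
    abort_input("Images must be numeric matrices.")
  }
  if (!all(dim(img_a) == dim(img_b))) {
    abort_input("Images must have identical dimensions.")
  }
}

#' Pearson correlation of two intensity images
#'
#' Standard pixel-wise product-moment correlation between two channels,
#' optionally restricted to a logical mask. Invariant to positive affine
#' rescaling of either channel.
#'
#' @param img_a,img_b Numeric matrices of equal dimensions.
#' @param mask Optional logical matrix of the same dimensions; only `TRUE`
#'   pixels are used.
#' @return Correlation in \[-1, 1\]. A channel with zero variance over the
#'   evaluated pixels raises an error (the correlation is undefined).
#' @export
pearson_coefficient <- function(img_a, img_b, mask = NULL) {
  check_image_pair_args(img_a, img_b)
  a <- as.vector(img_a); b <- as.vector(img_b)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(img_a))) {
      abort_input("`mask` must be a logical matrix matching the images.")
    }
    a <- a[as.vector(mask)]; b <- b[as.vector(mask)]
  }
  if (length(a) < 2L) abort_input("Need at least 2 pixels.")
  if (var(a) == 0 || var(b) == 0) {
    abort_input("Pearson correlation undefined: a channel has zero variance.")
  }
  cor(a, b)
}

#' Manders-type overlap coefficient of two intensity images
#'
#' \deqn{O = \frac{\sum_i a_i b_i}{\sqrt{\sum_i a_i^2 \sum_i b_i^2}}}
#' over all pixels. Lies in \[0, 1\] for nonnegative images, equals 1 iff the
#' channels are proportional, 0 for disjoint supports, and is invariant to
#' positive scalar rescaling of either channel.
#'
#' @inheritParams pearson_coefficient
#' @return Overlap coefficient in \[0, 1\].
#' @export
overlap_coefficient <- function(img_a, img_b, mask = NULL) {
  check_image_pair_args(img_a, img_b)
  a <- as.vector(img_a); b <- as.vector(img_b)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(img_a))) {
      abort_input("`mask` must be a logical matrix matching the images.")
    }
    a <- a[as.vector(mask)]; b <- b[as.vector(mask)]
  }
  sa2 <- sum(a^2); sb2 <- sum(b^2)
  if (sa2 == 0 || sb2 == 0) {
    abort_input("Overlap coefficient undefined: a channel is all zero.")
  }
  sum(a * b) / sqrt(sa2 * sb2)
}

# 8-connectivity component labels for a logical matrix. Foreground pixels are
# nodes; edges join each pixel to its E, S, SE and SW neighbours (forward
# half of the 8-neighbourhood); components come from igraph.
label_components_8 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  idx <- which(binary)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  node <- integer(nr * nc)
  node[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + off[1]; cn <- cl + off[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- node[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(node[idx[ok]][hit], node[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  labels[idx] <- igraph::components(g)$membership
  labels
}

#' Segment punctate objects from an intensity image
#'
#' Thresholds the image at `mean + rel_threshold * sd` of its intensities,
#' groups above-threshold pixels by 8-connectivity, drops components smaller
#' than `min_area` pixels, and returns the intensity-weighted centroid and
#' area of each remaining object. An image with no objects above threshold
#' returns an empty set, not an error.
#'
#' @param img Numeric matrix.
#' @param rel_threshold Threshold in units of the image sd above the mean
#'   (default 2).
#' @param min_area Minimum object area, px (default 4).
#' @param source_channel Optional label recorded in the result.
#' @return An `object_set` tibble with columns `label`, `row`, `col`
#'   (sub-pixel centroid), `area`; attributes `threshold_used`, `dims`,
#'   `source_channel`.
#' @export
segment_objects <- function(img, rel_threshold = 2, min_area = 4,
                            source_channel = NA_character_) {
  if (!is.matrix(img)) abort_input("`img` must be a numeric matrix.")
  check_number(rel_threshold, "rel_threshold")
  min_area <- check_count(min_area, "min_area", min = 1L)
  thr <- mean(img) + rel_threshold * sd(img)
  labels <- label_components_8(img > thr)
  out <- empty <- tibble(label = integer(), row = double(), col = double(),
                         area = integer())
  if (max(labels) > 0L) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    w <- img[idx]
    r <- ((idx - 1L) %% nrow(img)) + 1L
    cl <- ((idx - 1L) %/% nrow(img)) + 1L
    out <- tibble(lab = lab, r = r, cl = cl, w = w) |>
      dplyr::summarise(
        row = sum(.data$r * .data$w) / sum(.data$w),
        col = sum(.data$cl * .data$w) / sum(.data$w),
        area = dplyr::n(), .by = "lab") |>
      dplyr::filter(.data$area >= min_area) |>
      dplyr::arrange(.data$row, .data$col) |>
      dplyr::mutate(label = dplyr::row_number()) |>
      dplyr::select("label", "row", "col", "area")
  }
  if (nrow(out) == 0L) out <- empty
  class(out) <- c("object_set", class(out))
  attr(out, "threshold_used") <- thr
  attr(out, "dims") <- dim(img)
  attr(out, "source_channel") <- source_channel
  out
}

#' Object-based colocalization by centroid distance
#'
#' Matches segmented objects of two channels by greedy nearest-neighbor
#' pairing of geometric centers: candidate pairs are sorted by distance and
#' accepted one-to-one while the distance is at most `max_dist`. Reports the
#' colocalized percentage in both directions (share of channel-A objects with
#' a matched partner in B, and vice versa), as object-based analyses report
#' YFP/mCherry and mCherry/YFP percentages.
#'
#' @param a,b `object_set`s from [segment_objects()] (or tibbles with `row`,
#'   `col`).
#' @param max_dist Matching tolerance, px (default 3).
#' @return A one-row `coloc_result` tibble: `n_a`, `n_b`, `n_matched`,
#'   `pct_a_in_b`, `pct_b_in_a`. Percentages are 0 when the corresponding
#'   channel has no objects.
#' @export
object_based_colocalization <- function(a, b, max_dist = 3) {
  check_number(max_dist, "max_dist", min = 0)
  for (s in list(a, b)) {
    if (!all(c("row", "col") %in% names(s))) {
      abort_input("Object sets need `row` and `col` columns.")
    }
  }
  da <- attr(a, "dims"); db <- attr(b, "dims")
  if (!is.null(da) && !is.null(db) && !all(da == db)) {
    abort_input("Object sets come from images of different dimensions.")
  }
  n_a <- nrow(a); n_b <- nrow(b)
  n_matched <- 0L
  if (n_a > 0L && n_b > 0L) {
    d <- sqrt(outer(a$row, b$row, `-`)^2 + outer(a$col, b$col, `-`)^2)
    cand <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_a <- logical(n_a); used_b <- logical(n_b)
      for (i in seq_len(nrow(cand))) {
        ia <- cand[i, 1]; ib <- cand[i, 2]
        if (!used_a[ia] && !used_b[ib]) {
          used_a[ia] <- TRUE; used_b[ib] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  out <- tibble(
    n_a = n_a, n_b = n_b, n_matched = n_matched,
    pct_a_in_b = if (n_a > 0) 100 * n_matched / n_a else 0,
    pct_b_in_a = if (n_b > 0) 100 * n_matched / n_b else 0)
  class(out) <- c("coloc_result", class(out))
  out
}

#' Full colocalization report for an image pair
#'
#' Convenience pipeline: Pearson and overlap coefficients on the raw
#' intensities plus object-based bidirectional percentages after
#' segmentation.
#'
#' @inheritParams pearson_coefficient
#' @inheritParams segment_objects
#' @inheritParams object_based_colocalization
#' @return A one-row `coloc_result` tibble: `pearson`, `overlap`, `n_a`,
#'   `n_b`, `n_matched`, `pct_a_in_b`, `pct_b_in_a`.
#' @export
#' @examples
#' pair <- generate_image_pair(20, 0.5, seed = 1)
#' coloc_analyze(pair$channel_a, pair$channel_b)
coloc_analyze <- function(img_a, img_b, rel_threshold = 2, min_area = 4,
                          max_dist = 3) {
  check_image_pair_args(img_a, img_b)
  obj <- object_based_colocalization(
    segment_objects(img_a, rel_threshold, min_area, "a"),
    segment_objects(img_b, rel_threshold, min_area, "b"),
    max_dist = max_dist)
  out <- dplyr::bind_cols(
    tibble(pearson = pearson_coefficient(img_a, img_b),
           overlap = overlap_coefficient(img_a, img_b)),
    obj)
  class(out) <- c("coloc_result", class(out))
  out
}
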