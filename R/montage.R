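#' Synthetic high-density electrode montage
#'
#' Builds a quasi-uniform layout of `n_channels` sensors on the upper part
#' of a unit sphere (spherical Fibonacci lattice over the cap above
#' z = `z_min`), emulating a high-density geodesic net. Channel labels are
#' E1..En. The montage is synthetic: it reproduces the channel count and
#' rough geometry of a 128-channel (adult) or 124-channel (infant) net,
#' not the true electrode coordinates of any commercial product.
#'
#' @param n_channels Number of sensors (128 adult, 124 infant).
#' @param z_min Lower z bound of the cap covered by sensors.
#' @return An object of class `montage_spec` with elements `labels`,
#'   `positions` (n x 3 matrix of unit vectors) and `neighbors` (list of
#'   integer vectors, the 6 nearest channels of each channel).
#' @export
make_montage <- function(n_channels = 128, z_min = -0.3) {
  stopifnot(n_channels >= 8)
  i <- seq_len(n_channels) - 0.5
  # golden-angle spiral over z in (z_min, 1)
  z <- 1 - (1 - z_min) * i / n_channels
  theta <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  rownames(pos) <- paste0("E", seq_len(n_channels))
  nb <- nearest_neighbors(pos, k = 6)
  structure(list(labels = rownames(pos), positions = pos, neighbors = nb),
            class = "montage_spec")
}

# k nearest channels per channel, Euclidean distance in 3-D, ties broken
# by channel index (order() is stable on the index tiebreak)
nearest_neighbors <- function(positions, k = 6) {
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  lapply(seq_len(nrow(d)), function(i) {
    order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
  })
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec>", length(x$labels), "channels\n")
  invisible(x)
}

#' Read/write a montage as CSV
#'
#' Plain CSV with columns `label, x, y, z`. Neighbor lists are recomputed
#' on read.
#'
#' @param montage A `montage_spec`.
#' @param path File path.
#' @return `read_montage_csv` returns a `montage_spec`.
#' @export
write_montage_csv <- function(montage, path) {
  df <- data.frame(label = montage$labels, montage$positions,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$label
  structure(list(labels = df$label, positions = pos,
                 neighbors = nearest_neighbors(pos, k = 6)),
            class = "montage_spec")
}

#' Smooth scalp topography centred on a montage location
#'
#' Gaussian-on-the-sphere sensor weighting used as a planted component
#' topography: w_c = exp(-angle(c, center)^2 / (2 * width^2)), normalised
#' to unit Euclidean norm.
#'
#' @param montage A `montage_spec`.
#' @param center Unit 3-vector; channels closest to it get largest weight.
#' @param width Angular width in radians.
#' @return Numeric weight vector over channels, unit norm.
#' @export
smooth_topography <- function(montage, center = c(0, -0.6, 0.8),
                              width = 0.6) {
  center <- center / sqrt(sum(center^2))
  cosang <- pmin(1, pmax(-1, montage$positions %*% center))
  ang <- acos(cosang)
  w <- exp(-ang^2 / (2 * width^2))
  as.numeric(w / sqrt(sum(w^2)))
}
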