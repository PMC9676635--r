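#' Build a synthetic scalp sensor layout
#'
#' Places `n_channels` sensors inside the unit disc (a schematic top view of
#' the head, nose up) and tags each with a coarse scalp region. Channels in
#' the lower third of the disc (y <= -1/3) are tagged `"occipital"`, the
#' upper third (y >= 1/3) `"frontal"`, the rest `"other"`. The first two
#' channels are pinned at the occipital and frontal poles so that every
#' layout carries at least one channel of each tagged region.
#'
#' @param n_channels Number of sensors (>= 4). The study montage the
#'   simulator emulates used 102 scalp electrodes.
#' @param seed Integer seed; layouts are deterministic given the seed.
#' @return An object of class `sensor_layout`: a list with `channel_ids`
#'   (unique labels), `positions` (n x 2 matrix, columns `x`, `y`, inside the
#'   unit disc) and `region_tags` (`"occipital"`, `"frontal"` or `"other"`).
#' @export
#' @examples
#' lay <- make_scalp_layout(32, seed = 7)
#' table(lay$region_tags)
make_scalp_layout <- function(n_channels, seed = 1L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 4) {
    stop_config("n_channels must be a single number >= 4")
  }
  n_channels <- as.integer(n_channels)
  pos <- with_seed(child_seed(seed, 104729L), {
    r <- sqrt(stats::runif(n_channels)) * 0.95
    th <- stats::runif(n_channels, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  })
  # anchor the poles so both tagged regions are always represented
  pos[1, ] <- c(0, -0.8)
  pos[2, ] <- c(0, 0.8)
  tags <- ifelse(pos[, "y"] <= -1 / 3, "occipital",
                 ifelse(pos[, "y"] >= 1 / 3, "frontal", "other"))
  structure(list(channel_ids = sprintf("E%03d", seq_len(n_channels)),
                 positions = pos,
                 region_tags = tags),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d channels (%s)\n", length(x$channel_ids),
              paste(sprintf("%s: %d", names(table(x$region_tags)),
                            table(x$region_tags)), collapse = ", ")))
  invisible(x)
}

# Gaussian spatial weight map centred on a scalp location; used to project
# simulated components onto the montage.
spatial_pattern <- function(layout, center, width = 0.35) {
  d2 <- (layout$positions[, "x"] - center[1])^2 +
    (layout$positions[, "y"] - center[2])^2
  exp(-d2 / (2 * width^2))
}
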