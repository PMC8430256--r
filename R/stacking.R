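#' Dimensional-stacking axis layout
#'
#' An ordered split of the swept channels between the two axes of the
#' stacked map. Each axis nests its channels outermost to innermost: the
#' first channel of `x_order` is the most significant (longest-label)
#' digit of the x coordinate, and likewise for y. For the full ten-channel
#' sweep each axis carries five channels, giving a 1024 x 1024 map.
#'
#' @param x_order,y_order Character vectors of channel names,
#'   outermost first; disjoint, jointly covering the swept channels.
#' @return A `stack_layout` object.
#' @export
#' @examples
#' stackLayout(c("bNa", "to", "pK", "bCa", "CaL"),
#'             c("pCa", "K1", "Ks", "Na", "Kr"))
stackLayout <- function(x_order, y_order) {
  all <- c(x_order, y_order)
  if (anyDuplicated(all)) stop("x_order and y_order must be disjoint")
  if (!all(all %in% channelIds()))
    stop("unknown channel names in layout")
  structure(list(x_order = x_order, y_order = y_order),
            class = "stack_layout")
}

#' @export
print.stack_layout <- function(x, ...) {
  cat("<stack_layout> x:", paste(x$x_order, collapse = " > "),
      "| y:", paste(x$y_order, collapse = " > "), "\n")
  invisible(x)
}

#' Map coordinates of a level vector under a stacking layout
#'
#' The x coordinate is sum over the x-axis channels of
#' level(channel) * n_levels^(position from innermost); the outermost
#' channel is the most significant digit. Bijective over the full
#' factorial.
#'
#' @param levels Named integer level vector (codes `0:(n_levels-1)`), or
#'   a matrix with named columns for many cases at once.
#' @param layout A `stack_layout`.
#' @param n_levels Radix (default 4).
#' @return List with 0-based `x` and `y` (vectors if `levels` is a
#'   matrix).
#' @export
stackCoordinates <- function(levels, layout, n_levels = 4L) {
  axis <- function(ord) {
    w <- n_levels^(rev(seq_along(ord)) - 1)  # outermost most significant
    if (is.matrix(levels)) as.numeric(levels[, ord, drop = FALSE] %*% w)
    else sum(levels[ord] * w)
  }
  list(x = axis(layout$x_order), y = axis(layout$y_order))
}

#' Build a stacked biomarker map from a results table
#'
#' Embeds the factorial results for one basic cycle length into a 2-D
#' grid: the cell for each case sits at its [stackCoordinates()]. Cells
#' of no-contraction or diverged cases (or any missing biomarker value)
#' carry the missing sentinel `NA`.
#'
#' @param table Results table from [runSweep()] or
#'   [generateSurrogateSweep()] (attributes `channels`/`factors`
#'   required).
#' @param biomarker Column name, e.g. `"emd_ms"` or `"apd90_ms"`.
#' @param layout A `stack_layout` over the table's channels.
#' @param bcl Basic cycle length selecting the table rows.
#' @return A `stacked_map`: numeric matrix (rows = y, columns = x) with
#'   attributes `biomarker`, `layout`, `bcl`.
#' @export
buildMap <- function(table, biomarker, layout, bcl) {
  channels <- attr(table, "channels")
  if (is.null(channels)) stop("results table lacks 'channels' metadata")
  if (!setequal(c(layout$x_order, layout$y_order), channels))
    stop("layout channels must match the table's swept channels")
  if (!biomarker %in% names(table)) stop("unknown biomarker: ", biomarker)
  rows <- table[table$bcl_ms == bcl, , drop = FALSE]
  if (!nrow(rows)) stop("no rows at bcl = ", bcl)
  nl <- 4L
  lev <- t(vapply(rows$case_id, decodeIndex, integer(length(channels)),
                  channels = channels, n_levels = nl))
  colnames(lev) <- channels
  nx <- nl^length(layout$x_order)
  ny <- nl^length(layout$y_order)
  need <- nx * ny
  if (nrow(rows) < need) {
    missing_idx <- setdiff(seq_len(need) - 1, rows$case_id)
    stop("incomplete factorial: missing case indices ",
         paste(head(missing_idx, 10), collapse = ", "),
         if (length(missing_idx) > 10) " ...")
  }
  co <- stackCoordinates(lev, layout, nl)
  m <- matrix(NA_real_, nrow = ny, ncol = nx)
  m[cbind(co$y + 1, co$x + 1)] <- rows[[biomarker]]
  structure(m, biomarker = biomarker, layout = layout, bcl = bcl,
            class = c("stacked_map", "matrix", "array"))
}

#' Roughness cost of a stacked map
#'
#' Sum over all horizontally and vertically adjacent cell pairs of the
#' absolute value difference, each unordered pair counted once. Pairs
#' involving a missing-sentinel cell contribute zero; borders are
#' truncated (no wrap-around). Minimizing this cost over axis layouts
#' smooths the map so that low-influence channels receive the short
#' (innermost) labels.
#'
#' @param map A `stacked_map` (any numeric matrix works).
#' @return Non-negative scalar cost.
#' @export
roughnessCost <- function(map) {
  m <- unclass(map)
  h <- abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  v <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  sum(h, na.rm = TRUE) + sum(v, na.rm = TRUE)
}

# cost of a candidate layout without building the S3 object
layoutCost <- function(values, lev, x_order, y_order, nl = 4L) {
  wx <- nl^(rev(seq_along(x_order)) - 1)
  wy <- nl^(rev(seq_along(y_order)) - 1)
  x <- as.numeric(lev[, x_order, drop = FALSE] %*% wx)
  y <- as.numeric(lev[, y_order, drop = FALSE] %*% wy)
  m <- matrix(NA_real_, nrow = nl^length(y_order),
              ncol = nl^length(x_order))
  m[cbind(y + 1, x + 1)] <- values
  h <- abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  v <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  sum(h, na.rm = TRUE) + sum(v, na.rm = TRUE)
}

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

layoutKey <- function(x_order, y_order) {
  paste(paste(x_order, collapse = ","), paste(y_order, collapse = ","),
        sep = " | ")
}

#' Optimize the stacking axis layout
#'
#' Searches for the axis configuration minimizing the summed absolute
#' neighbor difference of the stacked map. Exhaustive mode enumerates
#' every ordered split of the channels between the axes (modulo the
#' x/y-swap symmetry, which leaves the cost unchanged) and is provably
#' global; it refuses when the count exceeds `cap`. Heuristic mode runs
#' seeded pairwise-swap hill climbing with restarts. Ties are broken by
#' the lexicographically smallest (x_order, y_order).
#'
#' @inheritParams buildMap
#' @param mode "exhaustive" or "heuristic".
#' @param seed RNG seed for the heuristic restarts.
#' @param cap Maximum number of layouts exhaustive mode will enumerate.
#' @param restarts Hill-climbing restarts in heuristic mode.
#' @return List with `layout` (a `stack_layout`), `cost`, and `n_evaluated`.
#' @export
optimizeLayout <- function(table, biomarker, bcl,
                           mode = c("heuristic", "exhaustive"),
                           seed = 1, cap = 10080, restarts = 5) {
  mode <- match.arg(mode)
  channels <- attr(table, "channels")
  if (is.null(channels)) stop("results table lacks 'channels' metadata")
  rows <- table[table$bcl_ms == bcl, , drop = FALSE]
  nl <- 4L
  lev <- t(vapply(rows$case_id, decodeIndex, integer(length(channels)),
                  channels = channels, n_levels = nl))
  colnames(lev) <- channels
  values <- rows[[biomarker]]
  n <- length(channels)
  nx <- ceiling(n / 2)

  best <- NULL
  neval <- 0L
  consider <- function(x_order, y_order) {
    cost <- layoutCost(values, lev, x_order, y_order, nl)
    neval <<- neval + 1L
    if (is.null(best) || cost < best$cost - 1e-12 ||
        (abs(cost - best$cost) <= 1e-12 &&
         layoutKey(x_order, y_order) < best$key)) {
      best <<- list(x_order = x_order, y_order = y_order, cost = cost,
                    key = layoutKey(x_order, y_order))
    }
    cost
  }

  if (mode == "exhaustive") {
    xsets <- combn(channels, nx, simplify = FALSE)
    total <- 0
    cands <- list()
    for (xs in xsets) {
      ys <- setdiff(channels, xs)
      for (px in permutations(xs)) for (py in permutations(ys)) {
        if (length(px) == length(py) &&
            layoutKey(py, px) < layoutKey(px, py)) next # x/y-swap class
        cands[[length(cands) + 1L]] <- list(px, py)
        total <- total + 1
        if (total > cap)
          stop(sprintf(
            "exhaustive search refused: more than %d layouts (cap)", cap))
      }
    }
    for (cd in cands) consider(cd[[1]], cd[[2]])
  } else {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      ord <- sample(channels)
      cur_x <- ord[seq_len(nx)]
      cur_y <- ord[-seq_len(nx)]
      cur_cost <- consider(cur_x, cur_y)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        pos <- c(cur_x, cur_y)
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          cand <- pos
          cand[c(i, j)] <- cand[c(j, i)]
          cc <- consider(cand[seq_len(nx)], cand[-seq_len(nx)])
          if (cc < cur_cost - 1e-12) {
            cur_cost <- cc
            pos <- cand
            improved <- TRUE
          }
        }
        cur_x <- pos[seq_len(nx)]
        cur_y <- pos[-seq_len(nx)]
      }
    }
  }
  list(layout = stackLayout(best$x_order, best$y_order), cost = best$cost,
       n_evaluated = neval)
}

#' Render a stacked map to an image and a delimited grid
#'
#' Writes the raw grid as tab-separated text (missing sentinel as NA) and,
#' optionally, a PNG figure with nested axis labels (outermost channel's
#' blocks are 1/4 of the axis, each inner channel 1/4 of its parent) where
#' sentinel cells are drawn in a reserved color. With `file_raster`, also
#' writes a pixel-exact raster (one pixel per cell) through the `png`
#' package when available.
#'
#' @param map A `stacked_map` from [buildMap()].
#' @param file_grid Path of the TSV grid.
#' @param file_image Optional path of the labeled PNG figure.
#' @param file_raster Optional path of the one-pixel-per-cell PNG.
#' @param sentinel_color Reserved color for missing cells.
#' @param palette_n Number of ramp colors.
#' @return Invisible list of the files written.
#' @export
renderMap <- function(map, file_grid, file_image = NULL,
                      file_raster = NULL, sentinel_color = "#00008B",
                      palette_n = 64) {
  m <- unclass(map)
  utils::write.table(m, file_grid, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  ramp <- grDevices::hcl.colors(palette_n, "viridis")
  rng <- range(m, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  idx <- if (rng[2] > rng[1])
    pmin(palette_n, 1 + floor((m - rng[1]) / (rng[2] - rng[1]) *
                                (palette_n - 1)))
  else matrix(1L, nrow(m), ncol(m))
  cols <- matrix(ramp[idx], nrow(m), ncol(m))
  cols[is.na(m)] <- sentinel_color

  if (!is.null(file_raster)) {
    if (requireNamespace("png", quietly = TRUE)) {
      arr <- grDevices::col2rgb(cols) / 255
      img <- array(0, dim = c(nrow(m), ncol(m), 3))
      img[, , 1] <- matrix(arr[1, ], nrow(m))
      img[, , 2] <- matrix(arr[2, ], nrow(m))
      img[, , 3] <- matrix(arr[3, ], nrow(m))
      png::writePNG(img, file_raster)
    } else warning("png package unavailable; raster not written")
  }

  if (!is.null(file_image)) {
    lay <- attr(map, "layout")
    grDevices::png(file_image, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(6, 6, 3, 1))
    graphics::image(x = seq_len(ncol(m)) - 0.5, y = seq_len(nrow(m)) - 0.5,
                    z = t(m), col = ramp, useRaster = FALSE,
                    xlab = "", ylab = "", axes = FALSE,
                    main = attr(map, "biomarker"))
    sent <- which(is.na(m), arr.ind = TRUE)
    if (nrow(sent))
      graphics::points(sent[, 2] - 0.5, sent[, 1] - 0.5, pch = 15,
                       cex = 0.4, col = sentinel_color)
    # nested tick labels: one line per axis channel, outermost closest
    nestedLabels <- function(ord, len, side) {
      for (k in seq_along(ord)) {
        blocks <- 4^k
        at <- (seq_len(blocks) - 0.5) * len / blocks
        lab <- rep(c("25", "50", "75", "100"), length.out = blocks)
        if (blocks <= 64)
          graphics::mtext(lab, side = side, at = at,
                          line = length(ord) - k + 0.5, cex = 0.5)
        graphics::mtext(ord[k], side = side,
                        at = if (side == 1) -0.02 * len else -0.02 * len,
                        line = length(ord) - k + 0.5, cex = 0.6, adj = 1)
      }
    }
    nestedLabels(lay$x_order, ncol(m), side = 1)
    nestedLabels(lay$y_order, nrow(m), side = 2)
    graphics::box()
  }
  invisible(list(grid = file_grid, image = file_image,
                 raster = file_raster))
}
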