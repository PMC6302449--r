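snapshot_columns <- c("id", "kind", "x", "y", "z", "volume", "radius",
                      "state", "oncoprotein", "attached_to")

#' Write a snapshot to disk
#'
#' The cell table is written as CSV with the exact column contract
#' `id, kind, x, y, z, volume, radius, state, oncoprotein, attached_to`
#' (empty `attached_to` when unattached); the substrate field arrays are
#' persisted alongside in a binary array container (RDS) keyed by substrate
#' name and save time, at `<path>_fields.rds`.
#'
#' @param snapshot A `tissue_snapshot`.
#' @param path CSV path for the cell table.
#' @param fields Logical; also write the field container (default TRUE when
#'   the snapshot carries fields).
#' @return (Invisibly) `path`.
#' @export
write_snapshot <- function(snapshot, path, fields = TRUE) {
  cells <- snapshot$cells[, snapshot_columns, drop = FALSE]
  # 17 significant digits: doubles survive the text round trip exactly
  for (col in c("x", "y", "z", "volume", "radius", "oncoprotein"))
    cells[[col]] <- sprintf("%.17g", cells[[col]])
  utils::write.csv(cells, path, row.names = FALSE, na = "", quote = FALSE)
  if (fields && !is.null(snapshot$fields)) {
    saveRDS(list(time = snapshot$time,
                 fields = snapshot$fields,
                 mesh = snapshot$mesh,
                 substrates = snapshot$substrates),
            field_container_path(path))
  }
  invisible(path)
}

field_container_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_fields.rds")
}

#' Read a snapshot from disk
#'
#' Strict inverse of [write_snapshot()]: the CSV must carry exactly the
#' contract columns, and every `state` must be one of `live`, `apoptotic`,
#' `necrotic` -- anything else raises a parse error naming the offending
#' row. The field container is loaded when present.
#'
#' @param path CSV path written by [write_snapshot()].
#' @return A `tissue_snapshot`.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("parse error: no such file: ", path)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(cells), snapshot_columns))
    stop("parse error: expected columns ",
         paste(snapshot_columns, collapse = ", "),
         " but found ", paste(names(cells), collapse = ", "))
  bad <- which(!cells$state %in% state_names)
  if (length(bad) > 0)
    stop("parse error: unknown state '", cells$state[bad[1]],
         "' in row ", bad[1])
  bad_kind <- which(!cells$kind %in% c("tumor", "immune"))
  if (length(bad_kind) > 0)
    stop("parse error: unknown kind '", cells$kind[bad_kind[1]],
         "' in row ", bad_kind[1])
  if (nrow(cells) > 0) cells$attached_to <- as.integer(cells$attached_to)
  fp <- field_container_path(path)
  time <- NA_real_; flds <- NULL; mesh <- NULL; subs <- NULL
  if (file.exists(fp)) {
    fc <- readRDS(fp)
    time <- fc$time; flds <- fc$fields; mesh <- fc$mesh; subs <- fc$substrates
  }
  structure(list(time = time, cells = cells, fields = flds,
                 mesh = mesh, substrates = subs),
            class = "tissue_snapshot")
}

#' Cell display color
#'
#' The cross-section color semantics: live tumor cells are shaded
#' continuously from blue (`p <= 0.5`, low proliferation and
#' immunogenicity) to yellow (`p >= 1.5`) by linear interpolation in the
#' oncoprotein expression; immune cells are red, apoptotic cells cyan, and
#' necrotic cells brown.
#'
#' @param state Cell state(s): `live`, `apoptotic`, `necrotic`.
#' @param kind Cell kind(s): `tumor` or `immune`.
#' @param p Oncoprotein expression(s).
#' @return Hex color string(s).
#' @examples
#' cell_color("live", "tumor", 1.0)  # midpoint blend of blue and yellow
#' @export
cell_color <- function(state, kind, p) {
  n <- max(length(state), length(kind), length(p))
  state <- rep_len(state, n); kind <- rep_len(kind, n); p <- rep_len(p, n)
  tt <- pmin(pmax((p - 0.5) / 1.0, 0), 1)
  out <- grDevices::rgb(tt, tt, 1 - tt) # blue -> yellow
  out[kind == "immune"] <- "#FF0000"
  out[kind == "tumor" & state == "apoptotic"] <- "#00FFFF"
  out[kind == "tumor" & state == "necrotic"] <- "#8B4513"
  out
}

#' Render an SVG cross-section
#'
#' Draws one circle per cell whose sphere intersects the plane
#' `z = z_plane` (`|z - z_plane| < radius`), with the in-plane section
#' radius `sqrt(radius^2 - (z - z_plane)^2)` and the [cell_color()]
#' semantics. Elements are emitted in ascending cell-id order with fixed
#' number formatting, so identical snapshots produce byte-identical SVG.
#'
#' @param snapshot A `tissue_snapshot`.
#' @param z_plane Cross-section plane, um (default 0).
#' @param path Optional output file; when `NULL` the SVG text is returned.
#' @param scale Pixels per micrometre.
#' @return The SVG document as a character scalar (invisibly when written
#'   to `path`).
#' @export
render_cross_section <- function(snapshot, z_plane = 0, path = NULL,
                                 scale = 1) {
  cells <- snapshot$cells
  mesh <- snapshot$mesh
  if (!is.null(mesh)) {
    x0 <- mesh$origin[1]; y0 <- mesh$origin[2]
    w <- mesh$nx * mesh$dx; h <- mesh$ny * mesh$dy
  } else if (nrow(cells) > 0) {
    x0 <- min(cells$x) - 50; y0 <- min(cells$y) - 50
    w <- diff(range(cells$x)) + 100; h <- diff(range(cells$y)) + 100
  } else {
    x0 <- 0; y0 <- 0; w <- 100; h <- 100
  }
  cells <- cells[order(cells$id), , drop = FALSE]
  dzs <- abs(cells$z - z_plane)
  keep <- dzs < cells$radius
  cells <- cells[keep, , drop = FALSE]
  rsec <- sqrt(cells$radius^2 - (cells$z[seq_len(nrow(cells))] - z_plane)^2)
  cols <- cell_color(cells$state, cells$kind, cells$oncoprotein)
  head_ <- sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%.1f" height="%.1f" viewBox="%.3f %.3f %.3f %.3f">'),
    w * scale, h * scale, x0, y0, w, h)
  body <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    body[i] <- sprintf(
      '<circle cx="%.3f" cy="%.3f" r="%.3f" fill="%s" stroke="black" stroke-width="0.2"/>',
      cells$x[i], cells$y[i], rsec[i], cols[i])
  }
  svg <- paste(c(head_, body, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Plot a sweep heatmap
#'
#' Renders a [heatmap_table()] grid as a PNG: cells shaded from deep blue
#' (lowest mean; the most effective response when the metric is a live
#' tumor count) to bright yellow (highest), annotated with the mean and the
#' completed replicate count `n`. Empty cells (no completed replicates) are
#' hatched and excluded from the color scale.
#'
#' @param grid A `sweep_heatmap` matrix.
#' @param path PNG output path.
#' @param main Plot title.
#' @param width,height Device size in pixels.
#' @return (Invisibly) `path`.
#' @export
plot_heatmap <- function(grid, path, main = "", width = 640, height = 560) {
  if (length(grid) == 0 || all(is.na(grid)))
    stop("empty-result error: nothing to plot")
  nmat <- attr(grid, "n")
  pal <- grDevices::colorRampPalette(c("#00008B", "#3B6FB6", "#7FB2B8",
                                       "#D9D26A", "#FFFF00"))(100)
  rng <- range(grid, na.rm = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  nx <- ncol(grid); ny <- nrow(grid)
  graphics::plot(NA, xlim = c(0.5, nx + 0.5), ylim = c(0.5, ny + 0.5),
                 xaxt = "n", yaxt = "n",
                 xlab = attr(grid, "x_param"), ylab = attr(grid, "y_param"),
                 main = main)
  graphics::axis(1, at = seq_len(nx), labels = colnames(grid))
  graphics::axis(2, at = seq_len(ny), labels = rownames(grid))
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    v <- grid[i, j]
    if (is.na(v)) {
      graphics::rect(j - 0.5, i - 0.5, j + 0.5, i + 0.5, col = "grey90",
                     density = 12)
    } else {
      ci <- 1 + floor(99 * (v - rng[1]) / diff(rng))
      graphics::rect(j - 0.5, i - 0.5, j + 0.5, i + 0.5, col = pal[ci])
      graphics::text(j, i, sprintf("%.3g\nn=%d", v,
                                   if (is.null(nmat)) NA_integer_
                                   else nmat[i, j]),
                     col = if (ci > 55) "black" else "white", cex = 0.9)
    }
  }
  invisible(path)
}
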