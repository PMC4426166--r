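#' Render configuration
#'
#' Visual defaults follow the field's convention for expression-overlaid TF
#' networks: up-regulated targets solid red, down-regulated solid blue,
#' everything else grey; filtered-out ("blurred") nodes are drawn at low
#' alpha rather than with a raster blur, which is resolution-independent and
#' visually equivalent. TFs draw as squares at twice the target size.
#'
#' @param width,height image dimensions in pixels.
#' @param format `"png"`, `"gif"` or `"svg"`.
#' @param up_colour,down_colour,neutral_colour,tf_colour node fill colours.
#' @param blur_alpha alpha of blurred nodes (default 0.15; visible nodes draw
#'   at alpha 1).
#' @param label_policy which labels to draw: `"tfs_only"`,
#'   `"tfs_and_visible"` (default), `"all"` or `"none"`.
#' @param font_size label size in points.
#' @param edge_alpha alpha of edge strokes.
#' @param node_size target-gene glyph size in points (TFs get 2x).
#' @return object of class `render_config`.
#' @export
render_config <- function(width = 1200, height = 900,
                          format = c("png", "gif", "svg"),
                          up_colour = "#DC1414", down_colour = "#1414DC",
                          neutral_colour = "#808080", tf_colour = "#222222",
                          blur_alpha = 0.15,
                          label_policy = c("tfs_and_visible", "tfs_only",
                                           "all", "none"),
                          font_size = 12, edge_alpha = 0.3, node_size = 4) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("png", "gif", "svg"))
    stop2("unsupported format '", format, "'; supported: png, gif, svg")
  format <- match.arg(format)
  label_policy <- match.arg(label_policy)
  if (width <= 0 || height <= 0) stop2("image dimensions must be positive")
  if (blur_alpha < 0 || blur_alpha > 1) stop2("blur_alpha must be in [0, 1]")
  for (col in c(up_colour, down_colour, neutral_colour, tf_colour))
    grDevices::col2rgb(col)  # validates
  structure(list(width = width, height = height, format = format,
                 up_colour = up_colour, down_colour = down_colour,
                 neutral_colour = neutral_colour, tf_colour = tf_colour,
                 blur_alpha = blur_alpha, label_policy = label_policy,
                 font_size = font_size, edge_alpha = edge_alpha,
                 node_size = node_size),
            class = "render_config")
}

#' Build per-node styles from a visual state
#'
#' Maps the up/down/neutral/tf classification and visible/blurred/hidden
#' state to concrete glyphs: class `up` -> up colour at alpha 1, `down` ->
#' down colour at alpha 1, blurred or neutral -> neutral colour at the blur
#' alpha (neutral-but-visible nodes draw opaque grey), `tf` -> square at
#' double size. Hidden nodes are excluded from the style map entirely. TFs
#' are labelled under every policy except `"none"`; visible targets are
#' labelled under `"tfs_and_visible"` and `"all"`.
#'
#' @param net a [tf_network()].
#' @param state a `visual_state` from [apply_filter()] (carries both state
#'   and class per node).
#' @param config a [render_config()].
#' @return data frame with columns `node`, `shape` (`square`/`circle`),
#'   `fill`, `alpha`, `size`, `label` (NA when unlabelled), one row per
#'   non-hidden node.
#' @export
build_style <- function(net, state, config = render_config()) {
  nodes <- network_nodes(net)
  missing_state <- setdiff(nodes, names(state$state))
  if (length(missing_state))
    stop2("node missing from visual state: ", missing_state[1L])
  st <- state$state[nodes]
  cls <- state$class[nodes]
  keep <- st != "hidden"
  nodes <- nodes[keep]; st <- st[keep]; cls <- cls[keep]

  fill <- character(length(nodes))
  alpha <- numeric(length(nodes))
  fill[cls == "up"] <- config$up_colour
  fill[cls == "down"] <- config$down_colour
  fill[cls == "neutral"] <- config$neutral_colour
  fill[cls == "tf"] <- config$tf_colour
  alpha[] <- 1
  alpha[st == "blurred"] <- config$blur_alpha
  # a blurred up/down gene still reads as filtered out: grey it
  fill[st == "blurred"] <- config$neutral_colour

  size <- ifelse(cls == "tf", 2 * config$node_size, config$node_size)
  shape <- ifelse(cls == "tf", "square", "circle")
  labelled <- switch(config$label_policy,
    none = rep(FALSE, length(nodes)),
    tfs_only = cls == "tf",
    tfs_and_visible = cls == "tf" | st == "visible",
    all = rep(TRUE, length(nodes)))
  data.frame(node = nodes, shape = shape, fill = fill, alpha = alpha,
             size = size, label = ifelse(labelled, nodes, NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Render a styled network to an image file
#'
#' Draws edges beneath nodes; edges incident to a hidden node (absent from
#' the style map) are not drawn. Output is PNG, GIF or SVG at the configured
#' pixel dimensions; the drawing is deterministic given identical inputs.
#'
#' @param net a [tf_network()].
#' @param layout a `tf_layout` covering all styled nodes.
#' @param style style data frame from [build_style()].
#' @param config a [render_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_image <- function(net, layout, style, config = render_config(), path) {
  missing_pos <- setdiff(style$node, layout$positions$node)
  if (length(missing_pos))
    stop2("styled node missing from layout: ", missing_pos[1L])
  dir <- dirname(path)
  if (!dir.exists(dir)) stop2("output directory does not exist: ", dir)

  target <- path
  tmp_png <- NULL
  if (config$format == "gif") {
    tmp_png <- tempfile(fileext = ".png")
    target <- tmp_png
  }
  open_dev <- switch(config$format,
    png = , gif = function(p) grDevices::png(p, width = config$width,
                                             height = config$height,
                                             type = "cairo"),
    svg = function(p) grDevices::svg(p, width = config$width / 96,
                                     height = config$height / 96))
  open_dev(target)
  ok <- FALSE
  tryCatch({
    draw_network(net, layout, style, config)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop2("rendering failed")
  if (config$format == "gif") {
    rgba <- png::readPNG(tmp_png)
    write_gif(rgba, path)
    unlink(tmp_png)
  }
  invisible(path)
}

draw_network <- function(net, layout, style, config) {
  pos <- layout$positions
  px <- stats::setNames(pos$x, pos$node)
  py <- stats::setNames(pos$y, pos$node)
  graphics::par(mar = c(0, 0, 0, 0), bg = "white")
  pad <- 0.08 * (max(px) - min(px) + 1)
  graphics::plot.new()
  graphics::plot.window(xlim = range(px) + c(-pad, pad),
                        ylim = range(py) + c(-pad, pad), asp = 1)
  styled <- style$node
  ed <- net$edges[net$edges$tf %in% styled & net$edges$target %in% styled, ,
                  drop = FALSE]
  if (nrow(ed))
    graphics::segments(px[ed$tf], py[ed$tf], px[ed$target], py[ed$target],
                       col = grDevices::adjustcolor("#999999",
                                                    alpha.f = config$edge_alpha),
                       lwd = 0.5)
  # blurred first so opaque visible nodes draw on top; one vectorised call
  # per (shape, fill, alpha, size) batch
  sty <- style[order(style$alpha), , drop = FALSE]
  grp <- paste(sty$shape, sty$fill, sty$alpha, sty$size)
  for (g in unique(grp)) {
    rows <- sty[grp == g, , drop = FALSE]
    graphics::points(px[rows$node], py[rows$node],
                     pch = if (rows$shape[1L] == "square") 15 else 16,
                     col = grDevices::adjustcolor(rows$fill[1L],
                                                  alpha.f = rows$alpha[1L]),
                     cex = rows$size[1L] / 4)
  }
  lab <- style[!is.na(style$label), , drop = FALSE]
  if (nrow(lab))
    graphics::text(px[lab$node], py[lab$node], labels = lab$label, pos = 3,
                   cex = config$font_size / 12,
                   col = "#000000")
  invisible(NULL)
}

## ---- GIF writer ------------------------------------------------------------
## Minimal GIF87a encoder. The LZW stream uses the fixed-code-width idiom:
## a CLEAR code is emitted before the decoder's table would force a width
## increase, so every pixel is written as a literal palette code. Valid LZW,
## no compression; adequate for the small flat-colour network figures.

#' Write an RGB(A) raster as a GIF file
#'
#' Quantises to at most 256 colours (successive per-channel bit reduction)
#' and encodes a single-frame GIF87a image.
#'
#' @param rgba numeric array h x w x 3 or 4 with values in \[0, 1\] (as from
#'   [png::readPNG()]); any alpha channel is composited over white.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gif <- function(rgba, path) {
  if (length(dim(rgba)) == 2L)
    rgba <- array(rep(rgba, 3L), c(dim(rgba), 3L))
  h <- dim(rgba)[1L]; w <- dim(rgba)[2L]
  if (dim(rgba)[3L] >= 4L) {
    a <- rgba[, , 4L]
    for (ch in 1:3) rgba[, , ch] <- rgba[, , ch] * a + (1 - a)
  }
  rgb255 <- round(255 * rgba[, , 1:3])

  bits <- 8L
  repeat {
    q <- (rgb255 %/% bitwShiftL(1L, 8L - bits)) * bitwShiftL(1L, 8L - bits)
    packed <- q[, , 1L] * 65536 + q[, , 2L] * 256 + q[, , 3L]
    pal <- sort(unique(as.vector(packed)))
    if (length(pal) <= 256L) break
    bits <- bits - 1L
  }
  idx <- matrix(match(packed, pal) - 1L, h, w)  # 0-based palette indices
  npal <- length(pal)
  m <- max(2L, ceiling(log2(npal)))            # LZW minimum code size
  pal_size <- bitwShiftL(1L, m)
  pal_r <- pal %/% 65536; pal_g <- (pal %/% 256) %% 256; pal_b <- pal %% 256
  table_bytes <- as.raw(rbind(c(pal_r, rep(0L, pal_size - npal)),
                              c(pal_g, rep(0L, pal_size - npal)),
                              c(pal_b, rep(0L, pal_size - npal))))

  clear <- bitwShiftL(1L, m)
  eoi <- clear + 1L
  width <- m + 1L
  run_len <- bitwShiftL(1L, width) - clear - 2L  # literals per CLEAR block
  pix <- as.vector(t(idx))                       # row-major scan order
  nblocks <- ceiling(length(pix) / run_len)
  codes <- integer(length(pix) + nblocks + 1L)
  ci <- 1L
  for (b in seq_len(nblocks)) {
    codes[ci] <- clear; ci <- ci + 1L
    seg <- pix[((b - 1L) * run_len + 1L):min(b * run_len, length(pix))]
    codes[ci:(ci + length(seg) - 1L)] <- seg
    ci <- ci + length(seg)
  }
  codes[ci] <- eoi

  bitmat <- vapply(0:(width - 1L),
                   function(b) bitwAnd(bitwShiftR(codes, b), 1L),
                   integer(length(codes)))
  bitstream <- as.vector(t(bitmat))              # LSB-first per code
  pad <- (-length(bitstream)) %% 8L
  bitstream <- c(bitstream, integer(pad))
  bytes <- as.integer(matrix(bitstream, nrow = 8L) |>
                        crossprod(bitwShiftL(1L, 0:7)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("GIF87a", con, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w16(w); w16(h)
  writeBin(as.raw(c(0xF0 + (m - 1L), 0x00, 0x00)), con)  # GCT flag + size
  writeBin(table_bytes, con)
  writeBin(as.raw(0x2C), con)                    # image descriptor
  w16(0L); w16(0L); w16(w); w16(h)
  writeBin(as.raw(c(0x00, m)), con)              # no LCT; LZW min code size
  i <- 1L
  while (i <= length(bytes)) {
    j <- min(i + 254L, length(bytes))
    writeBin(as.raw(c(j - i + 1L, bytes[i:j])), con)
    i <- j + 1L
  }
  writeBin(as.raw(c(0x00, 0x3B)), con)           # terminator, trailer
  invisible(path)
}

#' Read back the dimensions of a GIF file
#'
#' Lightweight header inspection used in tests and sanity checks.
#'
#' @param path GIF file path.
#' @return integer vector `c(width, height)`.
#' @export
gif_dimensions <- function(path) {
  hdr <- readBin(path, "raw", n = 10L)
  if (rawToChar(hdr[1:3]) != "GIF") stop2("not a GIF file: ", path)
  le16 <- function(lo, hi) as.integer(lo) + 256L * as.integer(hi)
  c(width = le16(hdr[7L], hdr[8L]), height = le16(hdr[9L], hdr[10L]))
}
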