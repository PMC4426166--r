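#' Layout parameters
#'
#' Tunables of the TF-circle / region-box layout. Units are abstract drawing
#' units; only ratios matter for the final image.
#'
#' @param radius circle radius R on which TF anchors sit (default 100).
#' @param box_width,box_height dimensions of each Venn-region box (defaults
#'   `0.5 * radius` and `0.35 * radius`).
#' @param shrink alpha in (0, 1] scaling each region's anchor centroid toward
#'   the centre (default 0.6), so multi-TF regions sit between their hubs.
#' @param collision_offset radial nudge applied to colliding box centres
#'   (default `0.15 * radius`).
#' @param seed integer RNG seed for the random placement inside boxes.
#' @return object of class `layout_params`.
#' @export
layout_params <- function(radius = 100, box_width = 0.5 * radius,
                          box_height = 0.35 * radius, shrink = 0.6,
                          collision_offset = 0.15 * radius, seed = 1L) {
  if (!is_finite_number(radius) || radius <= 0) stop2("radius must be > 0")
  if (box_width <= 0 || box_height <= 0) stop2("box dimensions must be > 0")
  if (shrink <= 0 || shrink > 1) stop2("shrink must be in (0, 1]")
  if (collision_offset <= 0) stop2("collision_offset must be > 0")
  structure(list(radius = radius, box_width = box_width,
                 box_height = box_height, shrink = shrink,
                 collision_offset = collision_offset,
                 seed = as.integer(seed)),
            class = "layout_params")
}

#' TF anchor positions on a circle
#'
#' TF `i` (0-based, in network TF order) sits at angle
#' `pi/2 - 2*pi*i/k` on a circle of radius R: the first TF at the top,
#' subsequent TFs clockwise, all equidistant.
#'
#' @param k number of TFs (>= 1).
#' @param params a [layout_params()].
#' @return k x 2 numeric matrix of (x, y) anchor coordinates.
#' @export
compute_tf_anchors <- function(k, params = layout_params()) {
  if (!is_finite_number(k) || k < 1) stop2("k must be >= 1")
  i <- seq_len(k) - 1L
  theta <- pi / 2 - 2 * pi * i / k
  cbind(x = params$radius * cos(theta), y = params$radius * sin(theta))
}

## Canonical ordering of signatures: by member count, then by member indices
## in network TF order. Deterministic given the TF order.
canonical_signature_order <- function(signatures, tfs) {
  idx <- lapply(signatures, function(m) match(m, tfs))
  key <- vapply(idx, function(v) paste(sprintf("%04d", sort(v)), collapse = ","),
                character(1))
  order(lengths(signatures), key)
}

#' Fixed-location boxes for every Venn region
#'
#' The box centre for a signature S is `shrink` times the centroid of the
#' anchors of S's member TFs, so exclusive regions sit near their TF and
#' fuller signatures sit toward the centre. If two centres fall within
#' `0.05 * radius` of each other, each colliding box after the first (in
#' canonical signature order: fewer members first, then TF-order indices) is
#' nudged radially outward by successive multiples of `collision_offset`;
#' a centre at the origin is nudged along its first member's anchor
#' direction. Box placement is a deterministic function of the TF order and
#' the parameters.
#'
#' @param signatures list of character vectors, every distinct non-empty
#'   membership signature present in the network (members in TF order).
#' @param anchors anchor matrix from [compute_tf_anchors()].
#' @param tfs TF labels in network order (rows of `anchors`).
#' @param params a [layout_params()].
#' @return named list (by signature key) of `region_box` objects: lists with
#'   `cx`, `cy`, `width`, `height`, `members`.
#' @export
compute_region_boxes <- function(signatures, anchors, tfs,
                                 params = layout_params()) {
  if (!length(signatures)) stop2("at least one signature is required")
  ord <- canonical_signature_order(signatures, tfs)
  sigs <- signatures[ord]
  delta <- 0.05 * params$radius
  centres <- matrix(NA_real_, length(sigs), 2L)
  for (i in seq_along(sigs)) {
    rows <- match(sigs[[i]], tfs)
    if (anyNA(rows)) stop2("signature member not among TFs")
    ctr <- params$shrink * colMeans(anchors[rows, , drop = FALSE])
    if (i > 1L) {
      dir <- ctr
      if (sqrt(sum(dir^2)) < 1e-12) dir <- anchors[rows[1L], ]
      dir <- dir / sqrt(sum(dir^2))
      m <- 0L
      repeat {
        cand <- ctr + m * params$collision_offset * dir
        d <- sqrt(rowSums((centres[seq_len(i - 1L), , drop = FALSE] -
                             matrix(cand, i - 1L, 2L, byrow = TRUE))^2))
        if (all(d >= delta)) break
        m <- m + 1L
      }
      ctr <- ctr + m * params$collision_offset * dir
    }
    centres[i, ] <- ctr
  }
  boxes <- lapply(seq_along(sigs), function(i)
    structure(list(cx = centres[i, 1L], cy = centres[i, 2L],
                   width = params$box_width, height = params$box_height,
                   members = sigs[[i]]),
              class = "region_box"))
  stats::setNames(boxes, vapply(sigs, signature_key, character(1)))
}

#' Place all nodes of a network
#'
#' TFs go to their circle anchors; each target gene is drawn uniformly at
#' random inside its signature's box. Targets are processed in lexicographic
#' gene order through one RNG stream seeded from `params$seed`, so the layout
#' is bit-reproducible given (network, params) and independent of input
#' order. Node overlaps are permitted.
#'
#' @param net a [tf_network()].
#' @param boxes region boxes from [compute_region_boxes()].
#' @param anchors anchor matrix from [compute_tf_anchors()].
#' @param params a [layout_params()].
#' @return object of class `tf_layout`: list with `positions` (data frame
#'   `node`, `x`, `y`) and `boxes`.
#' @export
place_nodes <- function(net, boxes, anchors, params = layout_params()) {
  sigs <- target_signatures(net)
  missing_box <- setdiff(unique(sigs), names(boxes))
  if (length(missing_box))
    stop2("internal error: no box for signature ", missing_box[1L])
  genes <- sort(net$targets)
  gx <- numeric(length(genes))
  gy <- numeric(length(genes))
  withr::with_seed(params$seed, {
    for (i in seq_along(genes)) {
      b <- boxes[[sigs[[genes[i]]]]]
      gx[i] <- b$cx + (stats::runif(1) - 0.5) * b$width
      gy[i] <- b$cy + (stats::runif(1) - 0.5) * b$height
    }
  })
  pos <- data.frame(
    node = c(net$tfs, genes),
    x = c(anchors[, 1L], gx),
    y = c(anchors[, 2L], gy),
    stringsAsFactors = FALSE)
  structure(list(positions = pos, boxes = boxes), class = "tf_layout")
}

#' @export
print.tf_layout <- function(x, ...) {
  cat(sprintf("tf_layout: %d nodes, %d region boxes\n",
              nrow(x$positions), length(x$boxes)))
  invisible(x)
}

#' One-call layout of a network
#'
#' Convenience wrapper running [compute_tf_anchors()],
#' [compute_region_boxes()] and [place_nodes()].
#'
#' @param net a [tf_network()].
#' @param params a [layout_params()].
#' @return a `tf_layout`.
#' @export
layout_network <- function(net, params = layout_params()) {
  anchors <- compute_tf_anchors(length(net$tfs), params)
  sig_keys <- unique(target_signatures(net))
  signatures <- lapply(sig_keys, split_signature_key)
  boxes <- compute_region_boxes(signatures, anchors, net$tfs, params)
  place_nodes(net, boxes, anchors, params)
}

#' Force-directed alternative layout
#'
#' Optional hook laying the same network out with Fruchterman-Reingold via
#' the igraph package (if installed), behind the same `tf_layout` interface.
#' No region boxes are produced.
#'
#' @param net a [tf_network()].
#' @param seed RNG seed.
#' @return a `tf_layout` with an empty `boxes` list.
#' @export
layout_force <- function(net, seed = 1L) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop2("layout_force requires the igraph package")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = network_nodes(net)))
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  structure(list(positions = data.frame(node = network_nodes(net),
                                        x = xy[, 1L], y = xy[, 2L],
                                        stringsAsFactors = FALSE),
                 boxes = list()),
            class = "tf_layout")
}

#' Write a layout as a three-column TSV
#' @param layout a `tf_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  p <- layout$positions
  writeLines(c("node\tx\ty",
               paste(p$node, sprintf("%.17g", p$x), sprintf("%.17g", p$y),
                     sep = "\t")), path)
  invisible(path)
}
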