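#' Arena polygon specification
#'
#' A convex polygon (in cm, origin at the arena centroid) describing the
#' test arena. Stores the vertex ring together with precomputed inward edge
#' normals and the narrowest width (the minimum distance between two
#' parallel supporting lines, i.e. wall-to-wall for a regular polygon).
#'
#' @param vertices Two-column matrix (x, y) of polygon vertices in cm, in
#'   ring order (either orientation; stored counter-clockwise).
#' @return An object of class `arena_spec` with fields `vertices`,
#'   `normals`, `offsets`, `narrowest_width` and `centroid`.
#' @export
arena_spec <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    stop("arena vertices must be an n x 2 matrix with n >= 3")
  }
  storage.mode(v) <- "double"
  # orient counter-clockwise (shoelace)
  area2 <- sum(v[, 1] * c(v[-1, 2], v[1, 2]) - c(v[-1, 1], v[1, 1]) * v[, 2])
  if (area2 < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  e <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  cross <- e[, 1] * c(e[-1, 2], e[1, 2]) - e[, 2] * c(e[-1, 1], e[1, 1])
  if (any(cross <= 0)) stop("arena polygon must be convex")
  len <- sqrt(rowSums(e^2))
  nrm <- cbind(-e[, 2], e[, 1]) / len  # inward unit normals for a CCW ring
  b <- rowSums(nrm * v)
  # polygon width in each edge-normal direction; narrowest over all edges
  proj <- v %*% t(nrm)
  widths <- apply(proj, 2, function(p) max(p) - min(p))
  structure(
    list(
      vertices = v,
      normals = nrm,
      offsets = b,
      narrowest_width = min(widths),
      centroid = colMeans(v)
    ),
    class = "arena_spec"
  )
}

#' Regular octagonal arena
#'
#' The default experimental arena: a regular octagon centred on the origin,
#' specified by its narrowest width (distance between opposite walls).
#'
#' @param narrowest_width Wall-to-wall distance in cm (default 105).
#' @return An `arena_spec`.
#' @export
octagon_arena <- function(narrowest_width = 105) {
  stopifnot(narrowest_width > 0)
  apothem <- narrowest_width / 2
  circum <- apothem / cos(pi / 8)
  ang <- pi / 8 + (0:7) * (pi / 4)
  a <- arena_spec(cbind(circum * cos(ang), circum * sin(ang)))
  stopifnot(abs(a$narrowest_width - narrowest_width) < 1e-6)
  a
}

#' Test whether points lie inside an arena
#'
#' @param arena An `arena_spec`.
#' @param x,y Coordinate vectors in cm.
#' @param tol Slack in cm applied to each wall half-plane.
#' @return Logical vector; `NA` where a coordinate is `NA`.
#' @export
in_arena <- function(arena, x, y, tol = 1e-9) {
  stopifnot(inherits(arena, "arena_spec"))
  p <- cbind(x, y) %*% t(arena$normals)
  d <- sweep(p, 2, arena$offsets)
  rowSums(d >= -tol) == ncol(d)
}

# signed distance to the nearest wall (positive inside)
arena_depth <- function(arena, x, y) {
  p <- cbind(x, y) %*% t(arena$normals)
  d <- sweep(p, 2, arena$offsets)
  apply(d, 1, min)
}

scale_arena <- function(arena, factor) {
  arena_spec(arena$vertices * factor)
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %d-gon, narrowest width %.2f cm\n",
              nrow(x$vertices), x$narrowest_width))
  invisible(x)
}
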