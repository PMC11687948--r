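#' Minimum-area enclosing rectangle of a 2D point set
#'
#' Rotating-calipers construction: the minimum-area rectangle has one edge
#' collinear with a convex-hull edge, so it suffices to evaluate the
#' axis-aligned bounding box after rotating by each hull-edge angle.
#' Degenerate inputs (single or collinear points) yield a degenerate
#' rectangle whose short extent is zero; [assignPixels()] pads it before
#' mapping.
#'
#' @param points n x 2 numeric matrix.
#' @return list with `theta` (minimizing rotation angle, radians, in
#'   [0, pi/2)), `corners` (4 x 2 matrix, original coordinates), `area`,
#'   `width`, `height`.
#' @examples
#' minAreaRectangle(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))$area  # 1
#' @export
minAreaRectangle <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 1L)
  rot <- function(theta) matrix(c(cos(theta), -sin(theta),
                                  sin(theta), cos(theta)), 2, 2)
  uniq <- unique(points)
  if (nrow(uniq) == 1L) {
    corners <- matrix(rep(uniq[1, ], 4), 4, 2, byrow = TRUE)
    return(list(theta = 0, corners = corners, area = 0, width = 0,
                height = 0))
  }
  hullIdx <- grDevices::chull(points)
  hull <- points[hullIdx, , drop = FALSE]
  if (nrow(hull) < 2L) hull <- uniq
  nh <- nrow(hull)
  edges <- hull[c(seq_len(nh)[-1], 1L), , drop = FALSE] - hull
  angles <- atan2(edges[, 2], edges[, 1]) %% (pi / 2)
  angles <- unique(c(angles, 0))
  best <- NULL
  for (th in angles) {
    r <- points %*% rot(-th)  # rotate points by -th
    w <- diff(range(r[, 1])); h <- diff(range(r[, 2]))
    area <- w * h
    if (is.null(best) || area < best$area - 1e-15)
      best <- list(theta = th %% (pi / 2), area = area, width = w,
                   height = h,
                   xr = range(r[, 1]), yr = range(r[, 2]))
  }
  cornersRot <- rbind(c(best$xr[1], best$yr[1]), c(best$xr[2], best$yr[1]),
                      c(best$xr[2], best$yr[2]), c(best$xr[1], best$yr[2]))
  corners <- cornersRot %*% t(rot(-best$theta))
  list(theta = best$theta, corners = corners, area = best$area,
       width = best$width, height = best$height)
}

#' Assign every taxon to one pixel of a fixed grid
#'
#' Rotates the embedding into its minimum-area rectangle frame, affinely
#' maps the rectangle onto the `H` x `W` grid, and bins each taxon by floor
#' of its mapped coordinate (points on the far edge clamp into the last
#' pixel, i.e. bins are half-open except the final one). Taxa with close or
#' identical coordinates may share a pixel; the collision count is logged
#' and recorded. A degenerate rectangle axis is padded to 1e-6 of the long
#' axis before mapping.
#'
#' @param emb n x 2 embedding from [embedTaxa()] (rownames = taxa).
#' @param H,W image height and width in pixels (>= 2).
#' @return a \linkS4class{PixelMap}.
#' @export
assignPixels <- function(emb, H = 32L, W = 32L) {
  H <- as.integer(H); W <- as.integer(W)
  stopifnot(H >= 2L, W >= 2L)
  emb <- as.matrix(emb)
  taxa <- rownames(emb)
  if (is.null(taxa)) taxa <- sprintf("taxon_%03d", seq_len(nrow(emb)))
  rect <- minAreaRectangle(emb)
  th <- rect$theta
  r <- emb %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pad <- function(rg, other) {
    if (diff(rg) < 1e-12) {
      eps <- max(1e-6 * max(diff(other), 1), 1e-12)
      rg + c(-eps, eps) / 2
    } else rg
  }
  xr <- pad(range(r[, 1]), range(r[, 2]))
  yr <- pad(range(r[, 2]), range(r[, 1]))
  col <- pmin(pmax(floor((r[, 1] - xr[1]) / diff(xr) * W) + 1L, 1L), W)
  row <- pmin(pmax(floor((r[, 2] - yr[1]) / diff(yr) * H) + 1L, 1L), H)
  nCollide <- sum(duplicated(paste(row, col)))
  if (nCollide > 0)
    stageLog(nCollide, " taxa share a pixel with another taxon (grid ",
             H, "x", W, ")")
  embAttrs <- attributes(emb)
  new("PixelMap", taxa = taxa, pixelRow = as.integer(row),
      pixelCol = as.integer(col), height = H, width = W,
      theta = rect$theta, corners = rect$corners,
      embedding = emb,
      method = embAttrs$method %||% "unknown",
      params = c(embAttrs$params %||% list(),
                 list(seed = embAttrs$seed, collisions = nCollide)))
}
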