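#' Delaunay triangulation and piecewise-linear scattered interpolation
#'
#' Minimal Bowyer-Watson incremental Delaunay triangulation plus barycentric
#' interpolation over the triangulation, used to turn a handful of fitted
#' patch centres into dense retinotopic maps. Written for tens of sites, not
#' thousands.
#'
#' @name delaunay
#' @keywords internal
NULL

## circumcircle (centre + squared radius) of triangle p1 p2 p3
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(c = c(ux, uy), r2 = (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation (Bowyer-Watson)
#'
#' @param x,y site coordinates (length >= 3, not all collinear).
#' @return integer matrix, one row per triangle, columns the site indices.
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("insufficient retinotopy: need at least 3 sites")
  ## super-triangle comfortably containing all sites
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1) * 20
  pts <- rbind(cbind(x, y),
               c(cx - 2 * span, cy - span),
               c(cx + 2 * span, cy - span),
               c(cx, cy + 2 * span))
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    bad <- vapply(tris, function(t) {
      cc <- circumcircle(pts[t[1], ], pts[t[2], ], pts[t[3], ])
      if (is.null(cc)) return(FALSE)
      (p[1] - cc$c[1])^2 + (p[2] - cc$c[2])^2 <= cc$r2 * (1 + 1e-12)
    }, logical(1))
    ## boundary = edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(t) {
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))
    }))
    if (is.null(edges)) stop("triangulation failure: point outside super-triangle")
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- c(tris[!bad],
              lapply(seq_len(nrow(boundary)),
                     function(j) c(boundary[j, 1], boundary[j, 2], i)))
  }
  out <- do.call(rbind, tris)
  out <- out[apply(out, 1, function(t) all(t <= n)), , drop = FALSE]
  if (nrow(out) == 0L) stop("insufficient retinotopy: sites are collinear")
  out
}

#' Piecewise-linear interpolation over a Delaunay triangulation
#'
#' Linearly interpolates one or more site-value columns at query points via
#' barycentric coordinates; queries outside the convex hull get NA.
#'
#' @param x,y site coordinates.
#' @param values numeric vector or matrix (one row per site).
#' @param qx,qy query coordinates.
#' @return matrix of interpolated values (one row per query, NA outside the
#'   hull), with attribute `inside` the logical hull membership.
#' @export
interp_barycentric <- function(x, y, values, qx, qy) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x), length(qx) == length(qy))
  tris <- delaunay_triangulate(x, y)
  out <- matrix(NA_real_, length(qx), ncol(values))
  inside <- logical(length(qx))
  for (r in seq_len(nrow(tris))) {
    t <- tris[r, ]
    x1 <- x[t[1]]; y1 <- y[t[1]]; x2 <- x[t[2]]; y2 <- y[t[2]]
    x3 <- x[t[3]]; y3 <- y[t[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
    l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
    l3 <- 1 - l1 - l2
    eps <- 1e-9
    hit <- !inside & l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(hit)) next
    out[hit, ] <- l1[hit] %o% values[t[1], ] + l2[hit] %o% values[t[2], ] +
      l3[hit] %o% values[t[3], ]
    inside[hit] <- TRUE
  }
  attr(out, "inside") <- inside
  out
}
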