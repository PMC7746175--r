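# NFHAS: a single mobility percentage built from the normalized main
# cervical ranges of motion. The three axis values (flexion-extension,
# lateral bending, rotation) are placed as vertices on mutually orthogonal
# axes; the polygon they span is measured with Heron's formula and compared
# against the ideal polygon where every normalized ROM is 100%.

#' Euclidean distance between two polygon vertices
#'
#' @param p,q numeric 3-vectors (percent units on the three ROM axes).
#' @return non-negative distance; zero iff `p == q`.
#' @examples
#' vertexDistance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
vertexDistance <- function(p, q) {
  if (length(p) != 3L || length(q) != 3L ||
      any(!is.finite(p)) || any(!is.finite(q))) {
    stop("vertexDistance expects two finite 3-D points")
  }
  sqrt(sum((p - q)^2))
}

#' Triangle area by Heron's formula
#'
#' \eqn{A = \sqrt{s(s-a)(s-b)(s-c)}} with semiperimeter
#' \eqn{s = (a+b+c)/2}. Degenerate (collinear) triangles return 0; a tiny
#' negative radicand from floating-point cancellation is clamped to 0, but
#' a genuine triangle-inequality violation is an error.
#'
#' @param a,b,c side lengths, each `>= 0`.
#' @param tol relative tolerance for the triangle-inequality check.
#' @return the area (percent squared when sides are percent units).
#' @examples
#' heronArea(3, 4, 5) # 6
#' @export
heronArea <- function(a, b, c, tol = 1e-9) {
  sides <- c(a, b, c)
  if (any(!is.finite(sides)) || any(sides < 0)) {
    stop("sides must be finite and non-negative")
  }
  s <- (a + b + c) / 2
  slack <- tol * max(1, a + b + c)
  if (max(sides) > (a + b + c) - max(sides) + slack) {
    stop("invalid geometry: sides violate the triangle inequality")
  }
  rad <- s * (s - a) * (s - b) * (s - c)
  if (rad < 0) rad <- 0
  sqrt(rad)
}

# Area of the triangle with vertices (x,0,0), (0,y,0), (0,0,z).
.axisTriangleArea <- function(x, y, z) {
  a <- vertexDistance(c(x, 0, 0), c(0, y, 0))
  b <- vertexDistance(c(0, y, 0), c(0, 0, z))
  c <- vertexDistance(c(0, 0, z), c(x, 0, 0))
  heronArea(a, b, c)
}

# Sum of the eight octant faces spanned by directional vertices on +/- axes.
.octantArea <- function(xp, xm, yp, ym, zp, zm) {
  total <- 0
  for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    total <- total + .axisTriangleArea(
      if (sx > 0) xp else xm,
      if (sy > 0) yp else ym,
      if (sz > 0) zp else zm
    )
  }
  total
}

#' NFHAS score from six normalized ROM values
#'
#' Combines the six directional normalized ROMs (percent of normative) into
#' one mobility percentage. Opposing directions are combined per axis
#' (mean by default); the default geometry is a single triangle whose
#' vertices sit on three orthogonal axes at the flexion-extension, lateral
#' bending and rotation values. The score is 100 times the ratio of this
#' polygon's area to the ideal polygon with every ROM at 100%. Scores above
#' 100 are possible (hypermobility) and are not clipped.
#'
#' @param roms numeric vector of 6 non-negative percentages in the order
#'   `F, E, Llb, Rlb, Lrt, Rrt` (names, if present, are checked).
#' @param geometry `"triangle"` (default; one face on the three orthogonal
#'   axes) or `"octant"` (six directional vertices on +/- axes, eight faces
#'   summed).
#' @param combine how opposing directions form an axis value: `"mean"`
#'   (default) or `"sum"`. Ignored by the octant geometry, which uses the
#'   directions individually.
#' @return the NFHAS score (percent, `>= 0`).
#' @examples
#' nfhasScore(rep(100, 6)) # 100
#' nfhasScore(rep(50, 6))  # 25: area scales with the square of ROM
#' @export
nfhasScore <- function(roms, geometry = c("triangle", "octant"),
                       combine = c("mean", "sum")) {
  geometry <- match.arg(geometry)
  combine <- match.arg(combine)
  if (length(roms) != 6L || any(!is.finite(roms))) {
    stop("six finite normalized ROM values are required (F, E, Llb, Rlb, Lrt, Rrt)")
  }
  if (any(roms < 0)) stop("normalized ROM values must be non-negative")
  if (!is.null(names(roms)) && !identical(names(roms), MOVEMENTS)) {
    roms <- roms[MOVEMENTS]
    if (anyNA(roms)) stop("named input must use movement names F, E, Llb, Rlb, Lrt, Rrt")
  }
  if (geometry == "triangle") {
    comb <- if (combine == "mean") {
      function(a, b) (a + b) / 2
    } else {
      function(a, b) a + b
    }
    fe <- comb(roms[1], roms[2])
    lb <- comb(roms[3], roms[4])
    rt <- comb(roms[5], roms[6])
    ideal <- comb(100, 100)
    area <- .axisTriangleArea(fe, lb, rt)
    areaIdeal <- .axisTriangleArea(ideal, ideal, ideal)
  } else {
    area <- .octantArea(roms[1], roms[2], roms[3], roms[4], roms[5], roms[6])
    areaIdeal <- .octantArea(100, 100, 100, 100, 100, 100)
  }
  unname(100 * area / areaIdeal)
}

#' NFHAS scores for every column of a cohort time point
#'
#' @param se a [NeckCohort-class] (or subset) holding `rom_norm` rows.
#' @param ... passed to [nfhasScore()].
#' @return named numeric vector, one score per column.
#' @export
nfhasScores <- function(se, ...) {
  rn <- metricMatrix(se, "rom_norm")
  out <- apply(rn, 2, nfhasScore, ...)
  stats::setNames(out, SummarizedExperiment::colData(se)$patient_id)
}

#' Stage NFHAS scores into 5 severity types
#'
#' Type 1 denotes complete ROM, type 5 severe limitation. The default mode
#' applies fixed score thresholds (a score above the first threshold is
#' type 1, and so on; scores above 100 are type 1). The `"kmeans"` mode
#' clusters the scores into 5 one-dimensional groups (fixed seed, centroids
#' sorted descending) and falls back to thresholds with a warning when
#' fewer than 5 distinct scores are supplied.
#'
#' @param scores numeric vector of NFHAS scores.
#' @param method `"threshold"` (default) or `"kmeans"`.
#' @param thresholds decreasing numeric vector of 4 cut points; the default
#'   `c(80, 60, 40, 20)` slices the score range into five equal-width bands.
#' @param seed RNG seed for the k-means mode.
#' @return integer vector of severity types in `1:5`.
#' @examples
#' stageSeverity(c(95, 75, 55, 35, 15)) # 1 2 3 4 5
#' @export
stageSeverity <- function(scores, method = c("threshold", "kmeans"),
                          thresholds = c(80, 60, 40, 20), seed = 1L) {
  method <- match.arg(method)
  if (!length(scores) || any(!is.finite(scores))) {
    stop("scores must be finite and non-empty")
  }
  if (method == "kmeans") {
    if (length(unique(scores)) < 5L) {
      warning("fewer than 5 distinct scores; falling back to threshold staging")
      method <- "threshold"
    } else {
      km <- withSeed(seed, stats::kmeans(scores, centers = 5L, nstart = 10L))
      ord <- order(km$centers, decreasing = TRUE) # highest score -> type 1
      rank <- integer(5L)
      rank[ord] <- seq_len(5L)
      return(rank[km$cluster])
    }
  }
  if (length(thresholds) != 4L || is.unsorted(rev(thresholds))) {
    stop("thresholds must be 4 decreasing cut points")
  }
  vapply(scores, function(s) 1L + sum(s <= thresholds), integer(1))
}
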