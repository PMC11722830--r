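#' ACGIH TLV lifting-zone boundaries
#'
#' Band edges of the 4 vertical x 3 horizontal zone grid.  Defaults are
#' the published ranges: V1 1.45--1.70 m (shoulder height and above), V2
#' 1--1.45 m, V3 0.5--1 m, V4 0--0.5 m; H1 0--0.25 m (near), H2
#' 0.25--0.457 m, H3 0.457--0.712 m (far).  Edges are configurable to
#' support subject-height-scaled zones.
#'
#' @param v_edges 5 strictly ascending non-negative heights (m).
#' @param h_edges 4 strictly ascending non-negative distances (m).
#' @return A list of class `"zone_boundaries"`.
#' @export
zone_boundaries <- function(v_edges = c(0, 0.5, 1, 1.45, 1.70),
                            h_edges = c(0, 0.25, 0.457, 0.712)) {
  if (length(v_edges) != 5L || length(h_edges) != 4L)
    stop_invalid("need 5 vertical and 4 horizontal edges")
  if (any(!is.finite(c(v_edges, h_edges))) || any(c(v_edges, h_edges) < 0))
    stop_invalid("edges must be finite and non-negative")
  if (any(diff(v_edges) <= 0) || any(diff(h_edges) <= 0))
    stop_invalid("edges must be strictly ascending")
  structure(list(v_edges = v_edges, h_edges = h_edges),
            class = "zone_boundaries")
}

# shared band classifier: lower-closed, upper-open intervals, top band
# closed; values outside the range are clamped to the nearest band and
# flagged out-of-range
classify_band <- function(x, edges, what) {
  if (any(is.na(x)) || any(!is.finite(x)))
    stop_invalid("non-finite ", what, " value")
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  out <- idx < 1L | idx > length(edges) - 1L
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  structure(idx, out_of_range = out)
}

#' Classify V into a vertical band
#'
#' Bands are numbered from the top: band 1 = V1 (highest, closed at the
#' top edge), band 4 = V4 (floor).  Intervals are lower-closed and
#' upper-open, so a V exactly on a shared edge belongs to the band above
#' it numerically (e.g. V = 0.5 is V3, not V4).  Out-of-range values are
#' clamped to the nearest band and flagged.
#'
#' @param v vertical height(s), m; must be finite.
#' @param boundaries a [zone_boundaries()] object.
#' @return Integer band(s) 1--4 with a logical `"out_of_range"` attribute.
#' @export
classify_v <- function(v, boundaries = zone_boundaries()) {
  b <- classify_band(v, boundaries$v_edges, "V")
  structure(length(boundaries$v_edges) - as.integer(b),
            out_of_range = attr(b, "out_of_range"))
}

#' Classify H into a horizontal band
#'
#' Band 1 = H1 (nearest), band 3 = H3 (farthest, closed at the top edge);
#' same interval-closure and clamping rules as [classify_v()].
#'
#' @param h horizontal distance(s), m; must be finite.
#' @inheritParams classify_v
#' @return Integer band(s) 1--3 with a logical `"out_of_range"` attribute.
#' @export
classify_h <- function(h, boundaries = zone_boundaries()) {
  classify_band(h, boundaries$h_edges, "H")
}

#' Zone index from a hand location
#'
#' The 12 zones are laid out row-major from the top vertical band and the
#' nearest horizontal band: `zone = 3 * (v_band - 1) + h_band`, so zone 1
#' is V1/H1 (above-shoulder, close) and zone 12 is V4/H3 (floor, far).
#'
#' @param v,h hand location in metres (equal-length vectors allowed).
#' @inheritParams classify_v
#' @return Data frame with columns `zone`, `v_band`, `h_band`,
#'   `out_of_range`.
#' @examples
#' zone_from_vh(1.50, 0.20)  # zone 1
#' zone_from_vh(1.20, 0.30)  # zone 5
#' @export
zone_from_vh <- function(v, h, boundaries = zone_boundaries()) {
  if (length(v) != length(h)) stop_invalid("v and h lengths differ")
  vb <- classify_v(v, boundaries)
  hb <- classify_h(h, boundaries)
  data.frame(zone = 3L * (as.integer(vb) - 1L) + as.integer(hb),
             v_band = as.integer(vb), h_band = as.integer(hb),
             out_of_range = attr(vb, "out_of_range") | attr(hb, "out_of_range"))
}

#' Grouped risk levels for the 12 lifting zones
#'
#' `zone_group_map()` returns the zone-to-risk lookup.  The default
#' (`"acgih_simplified"`) groups zones 4 and 5 as low risk, 6--9 as medium
#' and 1, 2, 3, 10, 11, 12 as high.  The alternate `"los_alamos"` mapping
#' (the original simplification this grouping was adapted from) has zone 4
#' alone as low; 1, 5, 7, 8, 10 medium; the rest high.
#'
#' @param mapping `"acgih_simplified"` (default) or `"los_alamos"`.
#' @return `zone_group_map()`: a length-12 factor (levels low, medium,
#'   high) indexed by zone.
#' @export
zone_group_map <- function(mapping = c("acgih_simplified", "los_alamos")) {
  mapping <- match.arg(mapping)
  g <- switch(mapping,
    acgih_simplified = c("high", "high", "high", "low", "low", "medium",
                         "medium", "medium", "medium", "high", "high", "high"),
    los_alamos = c("medium", "high", "high", "low", "medium", "high",
                   "medium", "medium", "high", "medium", "high", "high"))
  factor(g, levels = RISK_LEVELS)
}

RISK_LEVELS <- c("low", "medium", "high")

#' @rdname zone_group_map
#' @param zone integer zone index or indices in 1--12.
#' @return `group_from_zone()`: factor of risk levels, one per zone.
#' @examples
#' group_from_zone(4)   # low
#' group_from_zone(8)   # medium
#' group_from_zone(12)  # high
#' @export
group_from_zone <- function(zone, mapping = c("acgih_simplified", "los_alamos")) {
  if (any(is.na(zone)) || any(zone != as.integer(zone)) ||
      any(zone < 1L) || any(zone > 12L))
    stop_invalid("zone index must be an integer in 1..12")
  zone_group_map(mapping)[as.integer(zone)]
}
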