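#' Genetic map
#'
#' Ordered marker positions: linkage group, genetic position in
#' centimorgan, optional 1-based physical position in bp. Markers are
#' stored sorted by (linkage group, cM, bp, marker id); the lexicographic
#' tie-break makes marker order total, which phasing and haploblock
#' border placement rely on.
#'
#' @param marker character vector of marker ids.
#' @param linkage_group character/integer vector.
#' @param cm numeric, nonnegative centimorgan positions.
#' @param bp optional integer physical positions (1-based, positive).
#' @return data frame of class \code{genetic_map}.
#' @export
genetic_map <- function(marker, linkage_group, cm, bp = NA) {
  if (anyDuplicated(marker)) stop("duplicated markers in map")
  if (any(cm < 0, na.rm = TRUE)) stop("cM positions must be nonnegative")
  df <- data.frame(marker = as.character(marker),
                   linkage_group = as.character(linkage_group),
                   cm = as.numeric(cm), bp = as.numeric(rep_len(bp, length(marker))),
                   stringsAsFactors = FALSE)
  o <- order(df$linkage_group, df$cm, df$bp, df$marker, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read / write a map CSV (columns marker, linkage_group, cm[, bp])
#' @param path file path.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  genetic_map(df$marker, df$linkage_group, df$cm,
              bp = if ("bp" %in% names(df)) df$bp else NA)
}

#' @rdname read_genetic_map
#' @param map a \code{genetic_map}.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate genetic positions from physical positions
#'
#' Places markers that have only a physical position onto the genetic map
#' by comparing their bp to those of flanking anchor markers carrying
#' both coordinates: linear interpolation between the two flanking
#' anchors, linear extrapolation beyond terminal anchors using the
#' nearest anchor pair's local cM/bp slope. Extrapolated placements are
#' flagged, and an optional cap on extrapolation distance marks distant
#' targets unplaceable instead.
#'
#' @param anchors \code{genetic_map} whose rows all carry cm and bp.
#' @param targets data frame with columns \code{marker},
#'   \code{linkage_group}, \code{bp}.
#' @param max_extrapolate_cm cap (in cM beyond the terminal anchor) past
#'   which a target is declared unplaceable; \code{Inf} disables the cap.
#' @return a \code{genetic_map} of the placed targets with extra columns
#'   \code{extrapolated} (logical) and \code{placeable}; unplaceable
#'   markers (linkage group with < 2 anchors, or beyond the cap) have
#'   \code{placeable = FALSE} and NA cm. These are candidates for
#'   exclusion as unmappable (classification type 5).
#' @export
interpolate_map <- function(anchors, targets, max_extrapolate_cm = Inf) {
  stopifnot(all(!is.na(anchors$cm)), all(!is.na(anchors$bp)))
  out <- data.frame(marker = as.character(targets$marker),
                    linkage_group = as.character(targets$linkage_group),
                    cm = NA_real_, bp = as.numeric(targets$bp),
                    extrapolated = FALSE, placeable = FALSE,
                    stringsAsFactors = FALSE)
  for (lg in unique(out$linkage_group)) {
    a <- anchors[anchors$linkage_group == lg, , drop = FALSE]
    ti <- which(out$linkage_group == lg)
    if (nrow(a) < 2) next
    a <- a[order(a$bp), , drop = FALSE]
    x <- out$bp[ti]
    # exact anchor hit keeps the anchor's cM
    hit <- match(x, a$bp)
    cm <- ifelse(!is.na(hit), a$cm[hit], NA_real_)
    inside <- is.na(cm) & x >= min(a$bp) & x <= max(a$bp)
    if (any(inside))
      cm[inside] <- stats::approx(a$bp, a$cm, xout = x[inside], ties = "ordered")$y
    lo <- is.na(cm) & x < min(a$bp)
    hi <- is.na(cm) & x > max(a$bp)
    n <- nrow(a)
    slope_lo <- (a$cm[2] - a$cm[1]) / (a$bp[2] - a$bp[1])
    slope_hi <- (a$cm[n] - a$cm[n - 1]) / (a$bp[n] - a$bp[n - 1])
    cm[lo] <- a$cm[1] + slope_lo * (x[lo] - a$bp[1])
    cm[hi] <- a$cm[n] + slope_hi * (x[hi] - a$bp[n])
    extrap <- lo | hi
    dist_out <- rep(0, length(x))
    dist_out[lo] <- a$cm[1] - cm[lo]
    dist_out[hi] <- cm[hi] - a$cm[n]
    ok <- !is.na(cm) & dist_out <= max_extrapolate_cm
    out$cm[ti] <- ifelse(ok, pmax(cm, 0), NA_real_)
    out$extrapolated[ti] <- extrap & ok
    out$placeable[ti] <- ok
  }
  out
}

#' Scale a physical map to an approximate genetic map
#'
#' Applies a constant conversion factor; the default of 4 cM per Mb is
#' the scaling used for the peach physical map.
#' @param bp_map data frame with columns \code{marker},
#'   \code{linkage_group}, \code{bp} (positive).
#' @param cm_per_mb conversion factor, default 4.
#' @return a \code{genetic_map} with cm = bp / 1e6 * cm_per_mb.
#' @export
physical_to_genetic <- function(bp_map, cm_per_mb = 4.0) {
  if (any(bp_map$bp <= 0)) stop("physical positions must be positive")
  genetic_map(bp_map$marker, bp_map$linkage_group,
              cm = bp_map$bp / 1e6 * cm_per_mb, bp = bp_map$bp)
}
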