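# Tumor-core ROI and 5/10/15-pixel peritumoral margin bands.

# Offsets of the Euclidean disc of radius w: (dr, dc) with dr^2+dc^2 <= w^2.
disc_offsets <- function(width) {
  w <- floor(width)
  g <- expand.grid(dr = -w:w, dc = -w:w)
  g[g$dr^2 + g$dc^2 <= width^2, , drop = FALSE]
}

# Binary dilation of a 2D mask by the Euclidean disc (pixel included iff its
# center lies within `width` of some mask pixel center). Shift-OR over the
# disc offsets: exact by construction.
dilate_disc <- function(mask, width) {
  off <- disc_offsets(width)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    sr <- max(1L, 1L + dr):min(nr, nr + dr)     # destination rows
    sc <- max(1L, 1L + dc):min(nc, nc + dc)
    out[sr, sc] <- out[sr, sc] | mask[sr - dr, sc - dc]
  }
  out
}

#' Build a peritumoral margin band
#'
#' Per slice, the band is the tumor core dilated by a Euclidean disc of
#' radius \code{width} pixels ("expanded in all directions"), minus the core,
#' intersected with the breast-tissue mask. Dilation is 2D per slice, never
#' through-slice. The band is therefore disjoint from the core, confined to
#' breast tissue, and nested across widths: band(5) is a subset of band(15).
#'
#' @param core,breast Lists of per-slice logical masks (or single matrices),
#'   core within breast.
#' @param width Band width in pixels (>= 1; the study grid uses 5, 10, 15).
#' @return A list with \code{kind} (e.g. \code{"margin10"}) and \code{mask},
#'   the per-slice band rasters; class \code{roi_selection}.
#' @export
build_margin <- function(core, breast, width) {
  if (is.matrix(core)) core <- list(core)
  if (is.matrix(breast)) breast <- list(breast)
  stopifnot(width >= 1, length(core) == length(breast))
  if (sum(vapply(core, sum, 0)) == 0)
    stop("core mask is empty on every slice")
  band <- lapply(seq_along(core), function(k) {
    if (any(core[[k]] & !breast[[k]]))
      stop(sprintf("core outside breast at slice %d", k))
    dilate_disc(core[[k]], width) & !core[[k]] & breast[[k]]
  })
  structure(list(kind = paste0("margin", width), mask = band),
            class = "roi_selection")
}

#' Select an ROI from a patient record
#'
#' \code{"core"} returns the tumor core mask unchanged; \code{"margin5"},
#' \code{"margin10"} and \code{"margin15"} return the corresponding dilated
#' band via \code{\link{build_margin}}.
#'
#' @param record A \code{patient_record}.
#' @param kind One of \code{"core"}, \code{"margin5"}, \code{"margin10"},
#'   \code{"margin15"}.
#' @return A list of per-slice logical masks.
#' @export
select_roi <- function(record, kind) {
  stopifnot(inherits(record, "patient_record"))
  if (kind == "core") return(record$masks$core)
  if (grepl("^margin(5|10|15)$", kind)) {
    w <- as.numeric(sub("margin", "", kind))
    return(build_margin(record$masks$core, record$masks$breast, w)$mask)
  }
  stop(sprintf("unknown ROI kind '%s'", kind))
}
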