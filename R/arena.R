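#' Arena specifications
#'
#' Constructors for the three behavioral apparatuses handled by the package.
#' All coordinates are in cm with the origin at the lower-left corner of the
#' arena bounding box, x to the right and y up.
#'
#' @section Open field:
#' A square box of side `side_cm` divided into three zones: the "center"
#' zone is the innermost square of side `center_side_cm`, the "peripheral"
#' zone is the band within `peripheral_band_cm` of any wall, and the rest is
#' the "middle" zone.  Zone boundaries are closed toward the more extreme
#' zone: a point exactly on the center-square edge is center and a point
#' exactly `peripheral_band_cm` from a wall is peripheral.
#'
#' @section Elevated plus maze:
#' A plus-shaped maze with a central `center_side_cm` square, two open arms
#' along the x axis and two closed arms along the y axis, each arm
#' `arm_length_cm` long and `arm_width_cm` wide.  The bounding box is a
#' square of side `2 * arm_length_cm + center_side_cm`.  Points on the
#' center/arm boundary belong to the arm.
#'
#' @param side_cm open-field side length.
#' @param center_side_cm side of the open-field center square, or of the EPM
#'   central square.
#' @param peripheral_band_cm width of the open-field wall band.
#' @param object_xy length-2 numeric, position of the object in the open
#'   field (defaults to the arena center).
#' @param arm_length_cm,arm_width_cm EPM arm dimensions.
#' @param chamber_side_cm,gap_cm two-chamber apparatus dimensions.
#' @return An object of class `arena_spec`.
#' @examples
#' of <- open_field_arena()
#' epm <- epm_arena()
#' @export
open_field_arena <- function(side_cm = 40, center_side_cm = 20,
                             peripheral_band_cm = 5, object_xy = NULL) {
  stopifnot(side_cm > 0, center_side_cm > 0, peripheral_band_cm > 0)
  if (center_side_cm + 2 * peripheral_band_cm > side_cm)
    stop("zones overlap: center_side_cm + 2*peripheral_band_cm must be <= side_cm")
  if (is.null(object_xy)) object_xy <- c(side_cm / 2, side_cm / 2)
  object_xy <- as.numeric(object_xy)
  if (length(object_xy) != 2 || any(object_xy < 0) || any(object_xy > side_cm))
    stop("object_xy must be a point inside the arena")
  structure(list(kind = "open_field", side_cm = side_cm,
                 center_side_cm = center_side_cm,
                 peripheral_band_cm = peripheral_band_cm,
                 object_xy = object_xy,
                 bbox = c(side_cm, side_cm)),
            class = "arena_spec")
}

#' @rdname open_field_arena
#' @export
epm_arena <- function(arm_length_cm = 30, arm_width_cm = 5,
                      center_side_cm = 5) {
  stopifnot(arm_length_cm > 0, arm_width_cm > 0, center_side_cm > 0,
            arm_width_cm <= center_side_cm + 1e-9)
  side <- 2 * arm_length_cm + center_side_cm
  structure(list(kind = "epm", arm_length_cm = arm_length_cm,
                 arm_width_cm = arm_width_cm,
                 center_side_cm = center_side_cm,
                 bbox = c(side, side)),
            class = "arena_spec")
}

#' @rdname open_field_arena
#' @export
two_chamber_arena <- function(chamber_side_cm = 17, gap_cm = 5) {
  stopifnot(chamber_side_cm > 0, gap_cm > 0)
  structure(list(kind = "two_chamber", chamber_side_cm = chamber_side_cm,
                 gap_cm = gap_cm,
                 bbox = c(2 * chamber_side_cm + gap_cm, chamber_side_cm)),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat("<arena_spec>", x$kind, "bbox", paste(x$bbox, collapse = " x "), "cm\n")
  invisible(x)
}

#' Zone labels defined for an arena
#'
#' @param arena an `arena_spec`.
#' @return character vector of zone labels.
#' @export
arena_zones <- function(arena) {
  switch(arena$kind,
    open_field = c("center", "middle", "peripheral"),
    epm = c("open_arm_1", "open_arm_2", "closed_arm_1", "closed_arm_2",
            "epm_center"),
    two_chamber = c("chamber_1", "chamber_2", "gap"),
    stop("unknown arena kind"))
}
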