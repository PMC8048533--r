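#' Controlled vocabularies for road and vehicle condition
#'
#' Road segments and vehicles are described by categorical condition labels
#' chosen from closed vocabularies. Numeric penalty values attached to the
#' labels are a configuration of the tool, not user data: users pick a label,
#' the package maps it to a penalty on a monotone ordinal scale.
#'
#' @name condition-vocabularies
#' @keywords internal
NULL

#' @rdname condition-vocabularies
#' @export
ROAD_CONDITIONS <- c(
  "fully paved",
  "partially paved",
  "dirt road (good quality)",
  "dirt road (rough quality)",
  "boat access only",
  "foot access only",
  "not accessible"
)

#' @rdname condition-vocabularies
#' @export
VEHICLE_CONDITIONS <- c(
  "very reliable",
  "reliable",
  "somewhat reliable",
  "unreliable"
)

# Default penalty scales. The "not accessible" entry carries a numeric value
# (continuing the monotone scale) used only when averaging road penalties for
# scaling; such arcs are excluded from routing via availability = 0.
.default_road_penalties <- c(1, 2, 3, 5, 6, 8, 10)
.default_vehicle_penalties <- c(1, 2, 3, 4)

#' Map a road-condition label to a penalty and an availability flag
#'
#' @param label character vector of road-condition labels (see
#'   [ROAD_CONDITIONS]).
#' @param penalties optional numeric vector of length 7 overriding the default
#'   penalty scale (must be strictly increasing along the label order).
#' @return a list with components `gamma` (numeric penalty) and `available`
#'   (logical; `FALSE` exactly for "not accessible").
#' @examples
#' map_road_condition("fully paved")
#' map_road_condition("not accessible")$available
#' @export
map_road_condition <- function(label, penalties = .default_road_penalties) {
  stopifnot(length(penalties) == length(ROAD_CONDITIONS),
            all(diff(penalties) > 0))
  idx <- match(label, ROAD_CONDITIONS)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown road-condition label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  list(gamma = penalties[idx],
       available = label != "not accessible")
}

#' Map a vehicle-condition label to a penalty
#'
#' @param label character vector of vehicle-condition labels (see
#'   [VEHICLE_CONDITIONS]).
#' @param penalties optional numeric vector of length 4 overriding the default
#'   strictly increasing penalty scale.
#' @return numeric penalty beta (larger = less reliable).
#' @examples
#' map_vehicle_condition("very reliable")
#' map_vehicle_condition("unreliable")
#' @export
map_vehicle_condition <- function(label, penalties = .default_vehicle_penalties) {
  stopifnot(length(penalties) == length(VEHICLE_CONDITIONS),
            all(diff(penalties) > 0))
  idx <- match(label, VEHICLE_CONDITIONS)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown vehicle-condition label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  penalties[idx]
}
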