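#' Named anatomical landmark sets
#'
#' A `landmark_set` holds the named points that drive alignment. Primary
#' landmarks sit on the joint hierarchy (digit tips, interphalangeal and
#' metacarpophalangeal joint centers, palm centers, wrist base); accessory
#' landmarks are width markers, named `<base>_t` (thumb-side) and `<base>_p`
#' (pinky-side) after the primary landmark whose segment they pin. The anchor
#' is the wrist-base landmark used to pin translation after whole-model
#' alignment. 2D illustration landmarks carry a zero depth coordinate.
#'
#' The canonical hand scheme has 54 landmarks: 22 primary (5 digit tips,
#' 8 finger DIP/PIP joints, 1 thumb interphalangeal joint, 5 MCP joints,
#' palmar and dorsal palm centers, wrist base) and 32 accessory (28 segment
#' width markers, 2 wrist-palm junctions, 2 palm width markers).
#'
#' @param names character vector of unique landmark names.
#' @param roles character vector, `"primary"` or `"accessory"` per landmark.
#' @param positions numeric matrix of 3D positions, one row per landmark.
#' @param anchor name of the wrist-base landmark (must be primary).
#' @return object of class `landmark_set` with fields `names`, `roles`,
#'   `positions`, `anchor`.
#' @export
landmark_set <- function(names, roles, positions, anchor) {
  names <- as.character(names)
  roles <- as.character(roles)
  positions <- as_coord_matrix(positions, "positions")
  if (length(names) != length(roles) || length(names) != nrow(positions))
    stop("names, roles and positions lengths differ")
  if (anyDuplicated(names))
    stop("duplicate landmark names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (!all(roles %in% c("primary", "accessory")))
    stop("roles must be 'primary' or 'accessory'")
  primaries <- names[roles == "primary"]
  acc <- names[roles == "accessory"]
  dangling <- acc[!(landmark_base(acc) %in% primaries)]
  if (length(dangling))
    stop("accessory landmark(s) without a matching primary base name: ",
         paste(dangling, collapse = ", "))
  if (!(anchor %in% primaries))
    stop("anchor '", anchor, "' does not resolve to a primary landmark")
  structure(list(names = names, roles = roles, positions = positions,
                 anchor = anchor),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", sum(x$roles == "primary"), "primary +",
      sum(x$roles == "accessory"), "accessory, anchor '", x$anchor, "'\n",
      sep = " ")
  invisible(x)
}

#' @rdname landmark_set
#' @param x a vector of landmark names.
#' @export
landmark_base <- function(x) sub("_.*$", "", x)

#' Look up landmark positions by name
#'
#' @param lms a [landmark_set].
#' @param names character vector of landmark names.
#' @return numeric matrix of positions, one row per requested name.
#' @export
landmark_positions <- function(lms, names) {
  i <- match(names, lms$names)
  if (anyNA(i)) stop("unknown landmark(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  lms$positions[i, , drop = FALSE]
}

#' Read / write landmark sets as JSON
#'
#' Format: `{"anchor": "wrist", "landmarks": [{"name", "role", "position":
#' [x,y,z]}, ...]}`.
#'
#' @param path JSON file path.
#' @return `load_landmarks()` returns a [landmark_set].
#' @export
load_landmarks <- function(path) {
  if (!file.exists(path)) stop("cannot read landmark file: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$anchor) || is.null(j$landmarks))
    stop("landmark JSON must have 'anchor' and 'landmarks' fields")
  landmark_set(
    names = vapply(j$landmarks, function(l) l$name, ""),
    roles = vapply(j$landmarks, function(l) l$role, ""),
    positions = do.call(rbind, lapply(j$landmarks,
                                      function(l) as.numeric(l$position))),
    anchor = j$anchor)
}

#' @rdname load_landmarks
#' @param lms a [landmark_set].
#' @export
save_landmarks <- function(lms, path) {
  j <- list(anchor = lms$anchor,
            landmarks = lapply(seq_along(lms$names), function(i) {
              list(name = lms$names[i], role = lms$roles[i],
                   position = lms$positions[i, ])
            }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Replace the positions of a landmark set
#'
#' Returns a copy of `lms` with new positions (names, roles and anchor kept).
#'
#' @param lms a [landmark_set].
#' @param positions numeric matrix, one row per landmark, same order.
#' @return a [landmark_set].
#' @export
with_positions <- function(lms, positions) {
  lms$positions <- as_coord_matrix(positions, "positions")
  lms
}
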