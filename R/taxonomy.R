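#' Movement label taxonomy
#'
#' The movement vocabulary used throughout the package: 8 basic hand/wrist
#' movements and 6 combined movements.  Each combined movement is the
#' simultaneous execution of one wrist rotation (pronation or supination) and
#' one hand function (pinch, lateral pinch, or grip); its label is written
#' `"<rotation>+<function>"`.  All decoding rules depend only on which basic
#' classes are rotations and which are functions, so the identities of the
#' remaining basic classes are configurable placeholders.
#'
#' @param basic_classes Character vector of 8 basic-movement tokens.  Must
#'   contain `"pronation"`, `"supination"`, `"pinch"`, `"lateral_pinch"` and
#'   `"grip"`; the other three default to placeholder tokens.
#' @param rotations Tokens of `basic_classes` that are wrist rotations.
#' @param functions_ Tokens of `basic_classes` that are hand functions.
#'
#' @return An object of class `"emg_taxonomy"`: a list with `basic_classes`
#'   (length 8), `combined_classes` (length 6, rotation-major order),
#'   `rotations`, `functions`, and the index sets `rotation_indices` /
#'   `function_indices` into `basic_classes`.
#' @examples
#' tx <- emg_taxonomy()
#' tx$combined_classes
#' decompose_combined("pronation+grip", tx)
#' @export
emg_taxonomy <- function(basic_classes = c("pronation", "supination", "pinch",
                                           "lateral_pinch", "grip",
                                           "basic_6", "basic_7", "basic_8"),
                         rotations = c("pronation", "supination"),
                         functions_ = c("pinch", "lateral_pinch", "grip")) {
  basic_classes <- as.character(basic_classes)
  if (length(basic_classes) != 8L) {
    stopf("taxonomy requires exactly 8 basic classes, got %d", length(basic_classes))
  }
  if (anyDuplicated(basic_classes)) stopf("basic classes must be unique")
  if (!all(rotations %in% basic_classes)) stopf("rotations must be basic classes")
  if (!all(functions_ %in% basic_classes)) stopf("functions must be basic classes")
  if (length(intersect(rotations, functions_)) > 0L) {
    stopf("rotation and function sets must be disjoint")
  }
  if (length(rotations) != 2L || length(functions_) != 3L) {
    stopf("expected 2 rotations and 3 hand functions")
  }
  combined <- as.vector(t(outer(rotations, functions_, paste, sep = "+")))
  structure(list(
    basic_classes = basic_classes,
    combined_classes = combined,
    rotations = rotations,
    functions = functions_,
    rotation_indices = match(rotations, basic_classes),
    function_indices = match(functions_, basic_classes)
  ), class = "emg_taxonomy")
}

#' @export
print.emg_taxonomy <- function(x, ...) {
  cat("sEMG movement taxonomy\n")
  cat("  basic   :", paste(x$basic_classes, collapse = ", "), "\n")
  cat("  combined:", paste(x$combined_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Decompose a combined-movement label into its components
#'
#' @param label A combined-class token, e.g. `"pronation+pinch"`.
#' @param taxonomy An [emg_taxonomy()] object.
#' @return Named character vector with elements `rotation` and `fun`.
#' @seealso [compose_combined()]
#' @export
decompose_combined <- function(label, taxonomy = emg_taxonomy()) {
  label <- as.character(label)
  stopifnot(length(label) == 1L)
  if (label %in% taxonomy$basic_classes) {
    stopf("'%s' is not a combined class (it is a basic class)", label)
  }
  if (!label %in% taxonomy$combined_classes) {
    stopf("unknown combined class '%s'", label)
  }
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  c(rotation = parts[1L], fun = parts[2L])
}

#' Compose a combined-movement label from a rotation and a hand function
#'
#' @param rotation A rotation token of the taxonomy.
#' @param fun A hand-function token of the taxonomy.
#' @inheritParams decompose_combined
#' @return The combined-class token.
#' @export
compose_combined <- function(rotation, fun, taxonomy = emg_taxonomy()) {
  if (!rotation %in% taxonomy$rotations) stopf("unknown rotation '%s'", rotation)
  if (!fun %in% taxonomy$functions) stopf("unknown hand function '%s'", fun)
  paste(rotation, fun, sep = "+")
}

all_classes <- function(taxonomy) {
  c(taxonomy$basic_classes, taxonomy$combined_classes)
}
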