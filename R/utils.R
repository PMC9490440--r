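#' @keywords internal
"_PACKAGE"

# classed error helper so callers can condition on failure modes
abort_ba <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bioapatite_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical analysis zones of a bone cross-section
#'
#' Outer cortical (OC), mid-cortical (MC), inner cortical (IC) and points
#' around vascular (Haversian) canals (HC).
#'
#' @return Character vector of the four zone codes.
#' @export
empa_zones <- function() c("OC", "MC", "IC", "HC")

#' States a specimen can be declared in
#' @return Character vector `c("unburnt", "burnt")`.
#' @export
bone_states <- function() c("unburnt", "burnt")

check_state <- function(state) {
  if (!is.character(state) || length(state) != 1L || !state %in% bone_states())
    abort_ba(sprintf("state must be one of %s", paste(bone_states(), collapse = ", ")),
             "invalid_design_error")
  state
}
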