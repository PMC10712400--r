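#' BMI and CDC weight categories
#'
#' Two ordered category schemes are supported. `scheme4` is the standard CDC
#' four-level scheme; `scheme3` merges underweight into normal (the merged
#' "normal/underweight" state used when the underweight stratum is too thin
#' to estimate its own transition row).
#'
#' Cutoffs are half-open intervals: underweight `[0, 18.5)`, normal
#' `[18.5, 25)`, overweight `[25, 30)`, obese `[30, Inf)`. A BMI of exactly
#' 25 is overweight and exactly 30 is obese; for continuous data the boundary
#' convention is measure-zero.
#'
#' @name weight-states
NULL

.scheme3_states <- c("normal_or_under", "overweight", "obese")
.scheme4_states <- c("underweight", "normal", "overweight", "obese")

#' Ordered state labels for a category scheme
#'
#' @param scheme `"scheme3"` (merged normal/underweight) or `"scheme4"`.
#' @return Character vector of state labels in increasing BMI order.
#' @export
#' @examples
#' weight_states("scheme3")
weight_states <- function(scheme = c("scheme3", "scheme4")) {
  scheme <- match.arg(scheme)
  if (scheme == "scheme3") .scheme3_states else .scheme4_states
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms, strictly positive.
#' @param height_m Height in metres, strictly positive.
#' @return BMI in kg/m^2. Vectorised.
#' @export
#' @examples
#' bmi(70, 1.75)
bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    rlang::abort("`weight_kg` must be finite and strictly positive.")
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    rlang::abort("`height_m` must be finite and strictly positive.")
  }
  weight_kg / height_m^2
}

#' Assign a CDC weight category to a BMI value
#'
#' @param x BMI in kg/m^2, strictly positive. Vectorised.
#' @inheritParams weight_states
#' @return A factor with the scheme's ordered state labels as levels.
#' @export
#' @examples
#' categorize_bmi(c(17, 22, 27, 35), "scheme4")
#' categorize_bmi(25, "scheme3")  # boundary: overweight
categorize_bmi <- function(x, scheme = c("scheme3", "scheme4")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("BMI values must be finite and strictly positive.")
  }
  idx4 <- findInterval(x, c(18.5, 25, 30)) + 1L
  if (scheme == "scheme4") {
    factor(.scheme4_states[idx4], levels = .scheme4_states)
  } else {
    idx3 <- pmax(idx4 - 1L, 1L)
    factor(.scheme3_states[idx3], levels = .scheme3_states)
  }
}

#' Merge four-level states into the three-level scheme
#'
#' Maps underweight and normal to `normal_or_under`; overweight and obese
#' are unchanged.
#'
#' @param state Factor or character vector of `scheme4` states.
#' @return Factor of `scheme3` states.
#' @export
merge_states <- function(state) {
  s <- as.character(state)
  bad <- !s %in% .scheme4_states
  if (any(bad)) {
    rlang::abort(paste0("Unknown scheme4 state(s): ",
                        paste(unique(s[bad]), collapse = ", ")))
  }
  merged <- ifelse(s %in% c("underweight", "normal"), "normal_or_under", s)
  factor(merged, levels = .scheme3_states)
}

# BMI interval [lower, upper) backing each state label, used by the
# synthetic generator to draw a BMI inside a drawn category.  The open-ended
# CDC intervals are capped to keep generated records physiologic; the merged
# normal/underweight state uses [16, 25) so the draw stays inside the merged
# category under either scheme.
.state_bmi_interval <- function(state) {
  switch(state,
    underweight     = c(15, 18.5),
    normal          = c(18.5, 25),
    normal_or_under = c(16, 25),
    overweight      = c(25, 30),
    obese           = c(30, 60),
    rlang::abort(paste0("Unknown state: ", state))
  )
}
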