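#' Health states of the IRIS Markov model
#'
#' The model distinguishes five states, in a fixed order used by every
#' matrix, trace and report in the package:
#' \describe{
#'   \item{N}{not abused}
#'   \item{U}{abused but not identified}
#'   \item{A}{abused and identified, seeing the advocate educator}
#'   \item{I}{abused and identified, not seeing the advocate educator}
#'   \item{D}{dead (absorbing)}
#' }
#'
#' Movement is restricted: women in N can only become abused (N to U) or die;
#' women in U can recover (U to N), be identified (U to A or U to I) or die;
#' women in the two identified states can only recover to N, stay, or die.
#' Transitions between the identified states, and from an identified state
#' back to U, are structural zeros.
#'
#' @return Character vector of the five state codes in model order.
#' @export
#' @examples
#' iris_states()
iris_states <- function() c("N", "U", "A", "I", "D")

#' @rdname iris_states
#' @return `iris_state_labels()` returns a named character vector mapping
#'   state codes to descriptive labels.
#' @export
iris_state_labels <- function() {
  c(N = "not abused",
    U = "abused, not identified",
    A = "abused, identified, seeing advocate educator",
    I = "abused, identified, not seeing advocate educator",
    D = "dead")
}

# living states, i.e. everything except the absorbing death state
living_states <- function() c("N", "U", "A", "I")

# allowed exit targets per living state (structural sparsity of the model)
allowed_exits <- function() {
  list(N = c("U", "D"),
       U = c("N", "A", "I", "D"),
       A = c("N", "D"),
       I = c("N", "D"))
}
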