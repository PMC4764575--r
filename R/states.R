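# Pair-state bookkeeping. The hidden state of a sister pair is one of
# "++", "+-", "-+", "--", giving sister 1 and sister 2's K-fibre state
# (+ polymerising drive c_plus, - depolymerising drive c_minus). States are
# stored internally as integers 1:4 in the order above.

PAIR_STATES <- c("++", "+-", "-+", "--")
SIG1 <- c(1L, 1L, -1L, -1L)
SIG2 <- c(1L, -1L, 1L, -1L)
COHERENT_STATE <- c(FALSE, TRUE, TRUE, FALSE)
# Net pair drift direction of the two coherent states at the default drives:
# "+-" moves in +x, "-+" in -x.
STATE_DIRECTION <- c(NA_real_, 1, -1, NA_real_)

#' Pair-state codes
#'
#' The four hidden pair states, in their fixed internal order. Sister 1's
#' state is the first symbol, sister 2's the second; `+` denotes a net
#' polymerising K-fibre and `-` a net depolymerising one.
#'
#' @return Character vector `c("++", "+-", "-+", "--")`.
#' @export
pair_states <- function() PAIR_STATES

#' @rdname pair_states
#' @param state Integer codes in `1:4` or labels from [pair_states()].
#' @return `is_coherent()`: logical; coherent states are `"+-"` and `"-+"`
#'   (the two sisters translocating in the same spatial direction).
#' @export
is_coherent <- function(state) COHERENT_STATE[as_state_index(state)]

#' @rdname pair_states
#' @return `state_direction()`: `+1` for `"+-"`, `-1` for `"-+"`, `NA` for the
#'   incoherent states.
#' @export
state_direction <- function(state) STATE_DIRECTION[as_state_index(state)]

#' @rdname pair_states
#' @param sister `1` or `2`.
#' @return `sister_sign()`: `+1` or `-1`, the given sister's K-fibre state.
#' @export
sister_sign <- function(state, sister) {
  s <- as_state_index(state)
  if (sister == 1) SIG1[s] else SIG2[s]
}

as_state_index <- function(state) {
  if (is.character(state)) {
    idx <- match(state, PAIR_STATES)
    if (anyNA(idx)) stop("unknown pair state label: ",
                         paste(state[is.na(idx)], collapse = ", "))
    return(idx)
  }
  state <- as.integer(state)
  if (any(state < 1L | state > 4L, na.rm = TRUE)) {
    stop("pair state codes must lie in 1:4")
  }
  state
}

state_label <- function(state) PAIR_STATES[as_state_index(state)]

flip_sister <- function(state, sister) {
  s <- as_state_index(state)
  if (sister == 1) c(3L, 4L, 1L, 2L)[s] else c(2L, 1L, 4L, 3L)[s]
}

# 4x4 one-step transition matrix of the pair chain: with probability
# p_coherent (from a coherent state) or p_incoherent (from an incoherent
# state) exactly one sister flips, chosen uniformly; otherwise the state is
# unchanged. Double flips have probability zero.
transition_matrix <- function(p_incoherent, p_coherent) {
  M <- matrix(0, 4, 4, dimnames = list(PAIR_STATES, PAIR_STATES))
  for (s in 1:4) {
    p <- if (COHERENT_STATE[s]) p_coherent else p_incoherent
    M[s, s] <- 1 - p
    M[s, flip_sister(s, 1)] <- M[s, flip_sister(s, 1)] + p / 2
    M[s, flip_sister(s, 2)] <- M[s, flip_sister(s, 2)] + p / 2
  }
  M
}
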