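# Sobol low-discrepancy sequence, implemented from primitive-polynomial
# direction numbers (Joe & Kuo style initialisation) rather than delegating
# to an external solver, so the point stream is fully specified by this
# file. Gray-code construction; unscrambled.

# per-dimension (degree s, coefficient integer a, initial m_1..m_s)
.SOBOL_DIRECTIONS <- list(
  list(s = 1L, a = 0L,  m = c(1L)),
  list(s = 2L, a = 1L,  m = c(1L, 3L)),
  list(s = 3L, a = 1L,  m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L,  m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L,  m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L,  m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L,  m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L,  m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L,  m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L))
)

.SOBOL_BITS <- 30L

# direction integers v_1..v_BITS for dimension d (1-based; d = 1 is the
# van der Corput sequence in base 2)
.sobolDirections <- function(d) {
  B <- .SOBOL_BITS
  if (d == 1L) return(bitwShiftL(1L, B - seq_len(B)))
  def <- .SOBOL_DIRECTIONS[[d - 1L]]
  s <- def$s; a <- def$a
  m <- integer(B)
  m[seq_len(s)] <- def$m
  if (B > s) {
    for (k in (s + 1L):B) {
      mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      for (i in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
          mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
      }
      m[k] <- mk
    }
  }
  vapply(seq_len(B), function(k) bitwShiftL(m[k], B - k), integer(1))
}

#' Sobol quasi-random points in the unit cube
#'
#' Generates `q` points of the (unscrambled) Sobol low-discrepancy sequence
#' in `p` dimensions, used to place hyperparameter candidates uniformly in
#' the search space with a budget linear in `q` (never exponential in `p`).
#' Deterministic for a fixed `skip`; the default `skip = 1` drops the
#' initial all-zeros point, so the 1-D stream starts 0.5, 0.75, 0.25, ...
#'
#' @param q Number of points (>= 1).
#' @param p Dimension (1 to 12 supported by the built-in direction
#'   numbers).
#' @param skip Number of leading sequence elements to discard.
#' @return A `q x p` matrix with entries in \[0, 1).
#' @examples
#' sobolPoints(4, 2)
#' @export
sobolPoints <- function(q, p, skip = 1L) {
  if (q < 1 || p < 1) stop("q and p must be positive")
  if (p > length(.SOBOL_DIRECTIONS) + 1L)
    stop("dimension ", p, " exceeds the built-in direction numbers (max ",
         length(.SOBOL_DIRECTIONS) + 1L, ")")
  if (skip < 0) stop("skip must be non-negative")
  V <- vapply(seq_len(p), .sobolDirections, integer(.SOBOL_BITS))  # BITS x p
  total <- skip + q
  X <- matrix(0L, total, p)      # integer state per point
  state <- integer(p)
  for (i in seq_len(total - 1L)) {
    # index of the lowest zero bit of (i - 1)
    c <- 1L; val <- i - 1L
    while (bitwAnd(val, 1L) == 1L) { val <- bitwShiftR(val, 1L); c <- c + 1L }
    state <- bitwXor(state, V[c, ])
    X[i + 1L, ] <- state
  }
  X[(skip + 1L):total, , drop = FALSE] / 2^.SOBOL_BITS
}
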