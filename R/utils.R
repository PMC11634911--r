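# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library functions do not
#' perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @noRd
stop_phonopress <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "phonopress_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @noRd
assert_that <- function(ok, msg, class = "phonopress_validation_error") {
  if (!isTRUE(ok)) stop_phonopress(msg, class)
  invisible(TRUE)
}

# Centered moving average with replicated edges; k forced odd.
#' @noRd
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L))[(h + 1L):(h + length(x))]
}

# Rolling max/min with replicated edges (centered window of k samples).
#' @noRd
rolling_extreme <- function(x, k, which = c("max", "min")) {
  which <- match.arg(which)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  if (which == "max") {
    zoo::rollmax(xp, k, align = "center")
  } else {
    -zoo::rollmax(-xp, k, align = "center")
  }
}

#' @noRd
next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Local minima: strictly lower than both neighbours (plateaus take the first
# sample of the plateau).
#' @noRd
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # sign of slope before and after each interior point; treat zero slope as
  # continuation of the previous non-zero slope so flat plateaus resolve.
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(s[-length(s)] < 0 & s[-1L] > 0) + 1L
  idx
}
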