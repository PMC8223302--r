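#' Genome-wide significance threshold from marker count
#'
#' Uniform per-study threshold `p <= 1/n` where `n` is the number of markers
#' tested, the convention used throughout the association modules here.
#'
#' @param n_markers number of markers tested (positive integer).
#' @return The threshold `1/n_markers`.
#' @examples
#' gwas_threshold(558650)          # 1.789e-06
#' signif(gwas_threshold(558650), 2)  # 1.8e-06 as usually printed
#' @export
gwas_threshold <- function(n_markers) {
  if (!is.numeric(n_markers) || length(n_markers) != 1L || n_markers < 1)
    stop("'n_markers' must be a single positive number")
  1 / n_markers
}

#' Trapezoidal integral
#' @param x,y coordinate vectors of equal length.
#' @return scalar integral of y over x.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

## seed handling: every stochastic operation takes an explicit seed and
## restores the caller's RNG state on exit
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
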