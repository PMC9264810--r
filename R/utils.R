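# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables use conventional
#' half-up rounding (87.75 -> 87.8), so this is applied at presentation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Format a percentage with one decimal and a trailing "%"; NA -> "NA".
format_pct <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f%%", round_half_up(x, 1)))
}

# Evaluate an expression with the RNG seeded, restoring the caller's
# RNG state afterwards so simulation helpers do not clobber the session.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# md5 digest of an arbitrary R object, via a temporary serialization.
object_digest <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 3, compress = FALSE)
  unname(tools::md5sum(tf))
}

stop_sers <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "sersdisc_error", "error")))
}
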