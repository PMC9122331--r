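# Internal helpers: classed errors and deterministic child seeds.

ta_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "ta_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

ta_config_error     <- function(msg) ta_error("ta_config_error", msg)
ta_domain_error     <- function(msg) ta_error("ta_domain_error", msg)
ta_format_error     <- function(msg) ta_error("ta_format_error", msg)
ta_data_error       <- function(msg) ta_error("ta_data_error", msg)
ta_fit_error        <- function(msg) ta_error("ta_fit_error", msg)
ta_comparison_error <- function(msg) ta_error("ta_comparison_error", msg)
ta_internal_error   <- function(msg) ta_error("ta_internal_error", msg)

#' Derive a deterministic child seed from a master seed and a string key
#'
#' A stable polynomial byte hash of the key is folded into the master seed
#' modulo a Mersenne prime, so each (cohort, dataset) random stream is a pure
#' function of the master seed and its key: adding a dataset never perturbs
#' the streams of the others.
#'
#' @param seed integer master seed.
#' @param ... character fragments; concatenated with "/" to form the key.
#' @return an integer in [0, 2^31 - 2], usable with [set.seed()].
#' @export
child_seed <- function(seed, ...) {
  key <- paste(..., sep = "/", collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 + h) %% 2147483647)
}

# set.seed scoped to an expression; restores the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# log-normal sdlog giving a multiplicative coefficient of variation `cv`
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ta_config_error(sprintf("field '%s' must be a single finite number", name))
  if (positive && x <= 0)
    ta_config_error(sprintf("field '%s' must be > 0", name))
  invisible(x)
}
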