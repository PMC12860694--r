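`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' @param message error message.
#' @param class subclass tag, prefixed with `cannadid_`.
#' @noRd
abort2 <- function(message, class) {
  stop(structure(
    class = c(paste0("cannadid_", class, "_error"), "cannadid_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Deterministic integer hash of a string
#'
#' djb2-style rolling hash reduced modulo a Mersenne prime, used to fan a
#' single global seed out into independent per-stage seeds. Always returns a
#' value in [0, 2^31 - 2] so it is a valid R integer seed.
#' @noRd
string_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  h
}

#' Derive a per-stage seed from a global seed
#'
#' Stage seeds depend only on (seed, stage name), so enabling or disabling one
#' pipeline stage never perturbs the random stream of another.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  as.integer((abs(seed) + string_hash(stage)) %% 2147483647)
}

#' Short content hash of an R object (for run manifests)
#' @noRd
object_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  sprintf("%08x", string_hash(s))
}

# probability / simplex validators -------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    abort2(sprintf("field '%s' must contain probabilities in [0, 1]", name),
           "config")
  invisible(x)
}

check_simplex <- function(x, name, tol = 1e-9) {
  check_prob(x, name)
  if (abs(sum(x) - 1) > tol)
    abort2(sprintf("field '%s' must sum to 1 (got %.12f)", name, sum(x)),
           "config")
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0) || any(x != floor(x)))
    abort2(sprintf("field '%s' must contain positive integer counts", name),
           "config")
  invisible(x)
}
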