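#' Derive a child seed from a master seed and a string label
#'
#' All randomness in the package flows from a single integer seed. Independent
#' stages (each survey year, each Monte-Carlo run, each value of the mean
#' duration in a sensitivity analysis) draw their own child seed from the
#' master seed and a stable label, so adding one more stage never perturbs the
#' random numbers of the others.
#'
#' @param seed master integer seed.
#' @param ... one or more atomic values concatenated into the label.
#' @return An integer in `[1, 2^31 - 2]`, deterministic in `(seed, label)`.
#' @examples
#' child_seed(42, "mc", 15)
#' @export
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  # 32-bit polynomial rolling hash, kept in double precision (exact below 2^53)
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named numeric vector keyed by integer year -> tibble(year, value)
year_map_to_df <- function(x, value_name = "value") {
  out <- tibble::tibble(year = as.integer(names(x)), v = unname(x))
  names(out)[2] <- value_name
  out
}
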