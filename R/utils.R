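#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd median var quantile fft pt qgamma rgamma
#'   pgamma optim coef integrate uniroot nls predict cor setNames
#' @importFrom utils write.csv read.csv modifyList packageVersion
NULL

## run `code` under a temporary RNG state seeded by `seed`; the caller's RNG
## stream is untouched, so generators are pure functions of their spec
with_seed <- function(seed, code) {
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

## derive a child seed from a parent seed and a stream label, kept < 2^31
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + sum(utf8ToInt(as.character(stream)))) %%
    2147483647
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
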