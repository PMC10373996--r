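# Shared numeric helpers. Rounding conventions matter here: scoring uses
# round-half-up (59.5 -> 60) and coefficient trimming uses round-half-away-
# from-zero, neither of which is base round()'s banker's rounding.

round_half_up <- function(x) floor(x + 0.5)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Integer trimming of regression coefficients; `truncate` drops the
# fractional part instead of rounding.
trim_coefficients <- function(x, method = c("round", "truncate")) {
  method <- match.arg(method)
  if (method == "round") round_half_away(x) else trunc(x)
}

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < 1e-8
}

`%||%` <- function(a, b) if (is.null(a)) b else a
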