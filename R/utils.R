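# Shared internal helpers.

# Excel-style rounding: halves go away from zero, unlike base round().
# Used wherever published percentages are turned back into counts.
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# enum validation
match_enum <- function(x, choices, what) {
  x <- as.character(x)
  bad <- !x %in% choices
  if (any(bad)) {
    stop_(sprintf("invalid %s: %s (expected one of %s)",
                  what, paste(unique(x[bad]), collapse = ", "),
                  paste(choices, collapse = ", ")))
  }
  x
}

PHENOTYPES <- c("resistant", "susceptible")
SEXES <- c("male", "female")
SEXES_U <- c("male", "female", "unknown")
GT_STATES <- c("hom_ref", "het", "hom_alt")
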