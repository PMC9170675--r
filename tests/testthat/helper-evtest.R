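# Trapezoidal rule written independently of the package internals, used to
# cross-check every integral the package reports.
trap <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Write a draws vector to a temporary CSV, optionally with a header.
write_draws_csv <- function(draws, header = "delta") {
  path <- tempfile(fileext = ".csv")
  lines <- format(draws, digits = 17, scientific = FALSE, trim = TRUE)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  path
}

quiet_fbst <- function(...) suppressWarnings(fbst_test(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
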