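# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_ctx(msg)
  invisible(TRUE)
}

# Label for a design cell; the factorial analyses key everything on these.
cell_label <- function(age, drug, induction) {
  paste(age, drug, induction, sep = ".")
}

design_cells <- function(design) {
  cell_label(design$age, design$drug, design$induction)
}

# Format numerics for TSV output at 6 significant digits, ids untouched.
format_col <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(signif(v, 6), scientific = FALSE,
                                              trim = TRUE, digits = 15)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}
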