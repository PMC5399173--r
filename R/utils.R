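# internal helpers: logging and assertions

reo_log <- function(fmt, ...) {
  if (isTRUE(getOption("reosig.verbose", TRUE)))
    message("[reosig] ", sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# align two character id vectors, logging the intersection size (ids are
# matched by string equality, never by position)
.align_ids <- function(a, b, what = "samples") {
  shared <- intersect(a, b)
  reo_log("aligned %s: %d x %d -> %d shared", what, length(a), length(b),
          length(shared))
  shared
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)
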