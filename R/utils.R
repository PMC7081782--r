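`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

.warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Collapse a character vector into a readable, truncated listing for messages.
.id_list <- function(x, max = 10L) {
  x <- as.character(x)
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 1
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
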