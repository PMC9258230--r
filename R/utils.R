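# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# median rounded half-up to an integer; module taxonomy needs a genome count
round_half_up <- function(x) as.integer(floor(x + 0.5))

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

collapse_ids <- function(x, max_show = 10L) {
  shown <- utils::head(x, max_show)
  out <- paste(shown, collapse = ", ")
  if (length(x) > max_show) out <- paste0(out, ", ... (", length(x), " total)")
  out
}
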