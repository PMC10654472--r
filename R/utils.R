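# Internal helpers: classed error conditions so callers can distinguish
# configuration mistakes, malformed data/files and degenerate analyses.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("domescan_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("domescan_data_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("domescan_parse_error", "error")))
}

stop_analysis <- function(...) {
  stop(errorCondition(paste0(...), class = c("domescan_analysis_error", "error")))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_config("`", name, "` must be in [0, 1]")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || anyNA(x) || any(x != floor(x)) || any(x < min)) {
    stop_config("`", name, "` must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Significance stars at the conventional 0.05 / 0.01 / 0.001 cutpoints.
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
    ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}
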