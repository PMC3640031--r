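# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Format errors raised by readers/constructors carry a dedicated condition
# class so callers can distinguish malformed inputs from programming errors.
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("soilniche_format_error", "error")))
}

# round() in R rounds half to even; printed tables in this field round half up.
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Quantiles are the linearly interpolated order statistics (R type 7).
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, names = FALSE, type = 7))
}

# Run code with a temporarily fixed RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
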