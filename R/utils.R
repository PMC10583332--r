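# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
nn_stop <- function(msg, class = "nn_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "nn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

nn_stop_numeric <- function(msg) nn_stop(msg, class = "nn_numeric_error")

# Truncated normal via inverse-CDF; bounds may be infinite.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) nn_stop("truncation bounds leave no probability mass")
  qnorm(runif(n, plo, phi), mean, sd)
}

# Truncated log-normal via inverse-CDF on the positive line.
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- plnorm(lower, meanlog, sdlog)
  phi <- plnorm(upper, meanlog, sdlog)
  if (phi <= plo) nn_stop("truncation bounds leave no probability mass")
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

# CSV writer that preserves doubles exactly on round-trip (%.17g is the
# shortest format guaranteed to reproduce an IEEE double).
write_csv_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) nn_stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    nn_stop(sprintf(
      "file %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  df
}

# Header occupies line 1, so data row i sits on file line i + 1.
data_line <- function(row_idx) row_idx + 1L

is_binary01 <- function(x) all(x %in% c(0, 1))

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    nn_stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) nn_stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
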