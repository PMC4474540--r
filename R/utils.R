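abort_format <- function(message, ...) {
  abort(message, class = "pandys_format_error", ...)
}

abort_config <- function(message, ...) {
  abort(message, class = "pandys_config_error", ...)
}

# sample sds over rows of a matrix without looping
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# write-then-rename so readers never observe a partial file
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == trunc(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}
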