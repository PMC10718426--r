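# Shared output helper: numeric columns at 12 significant digits, missing
# values as empty fields (RFC-4180 style, header row, no quoting).
.write_num_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      s <- vapply(df[[j]], function(v)
        if (is.na(v)) "" else format(v, digits = 12), character(1))
      df[[j]] <- s
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
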