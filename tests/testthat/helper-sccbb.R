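# shared fixture builders

# write a plate matrix CSV (rows x cols of OD values) and return its path
write_plate_matrix_csv <- function(od_matrix, rows = LETTERS[seq_len(nrow(od_matrix))]) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  df <- data.frame(row = rows, od_matrix, check.names = FALSE)
  colnames(df) <- c("row", seq_len(ncol(od_matrix)))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# independent closed form for the purity-given-growth probability:
# sum_i (exp(-lam (1 - p_i)) - exp(-lam)) / (1 - exp(-lam))
purity_closed_form <- function(lam, p) {
  sum(exp(-lam * (1 - p)) - exp(-lam)) / (1 - exp(-lam))
}

# the published five-factor screen as a factor_def
l01_pb_factors <- function() {
  tab <- l01_pb_screen()
  factor_def(tab$factor, low = tab$low, high = tab$high, units = tab$units)
}
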