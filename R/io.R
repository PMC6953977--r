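#' Read a trajectory from delimited text
#'
#' Expects a comma-separated table with a header row of channel names and one
#' row per time sample; the result is transposed to channels-by-time. Empty
#' fields and `NA` mark missing entries.
#'
#' @param path File path.
#' @return `D x T` numeric matrix with channel names as row names.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  M <- t(as.matrix(tab))
  storage.mode(M) <- "double"
  M
}

#' Write a trajectory to delimited text
#'
#' One row per time sample, channels as columns with a header row; missing
#' entries become empty fields.
#'
#' @param M `D x T` numeric matrix (row names used as channel names).
#' @param path File path.
#' @export
write_trajectory <- function(M, path) {
  M <- as.matrix(M)
  tab <- as.data.frame(t(M))
  if (!is.null(rownames(M))) names(tab) <- rownames(M)
  else names(tab) <- paste0("ch", seq_len(nrow(M)))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
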