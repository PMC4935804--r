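#' Write / read a trace table
#'
#' Long-format delimited text: `cell_id`, `time_min`, `ikba_total`,
#' `nfkb_nt`.
#'
#' @param traces long data frame.
#' @param file path.
#' @export
write_traces <- function(traces, file) {
  utils::write.csv(traces, file, row.names = FALSE)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  tr <- utils::read.csv(file)
  need <- c("cell_id", "time_min", "ikba_total")
  if (!all(need %in% names(tr)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  # normalize each cell's IkBa intensity to its t = 0 value on load
  for (id in unique(tr$cell_id)) {
    w <- tr$cell_id == id
    t0 <- tr$ikba_total[w][which.min(tr$time_min[w])]
    if (t0 > 0) tr$ikba_total[w] <- tr$ikba_total[w] / t0
  }
  tr
}

#' Write a trajectory as delimited text
#'
#' Columns: `time_min`, species, then observables.
#'
#' @param traj an `nfkb_trajectory`.
#' @param file path.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
}

#' Write / read a count matrix with gene classes
#'
#' Delimited text with a `gene` and `class` column followed by one column
#' per sample named `<condition>.<replicate>`.
#'
#' @param x an `nfkb_counts`.
#' @param file path.
#' @export
write_counts <- function(x, file) {
  df <- data.frame(gene = rownames(x$counts), class = x$gene_class,
                   x$counts, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste(x$condition, x$replicate, sep = ".")
  utils::write.csv(df, file, row.names = FALSE)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$gene
  lab <- strsplit(colnames(m), ".", fixed = TRUE)
  count_matrix(m, df$class,
               condition = vapply(lab, `[`, "", 1),
               replicate = as.integer(vapply(lab, `[`, "", 2)))
}

#' Write / read model parameters as structured text
#'
#' YAML with keys exactly matching the [nfkb_params()] field names.
#'
#' @param params parameter list.
#' @param file path.
#' @export
write_params <- function(params, file) {
  yaml::write_yaml(unclass(params), file, precision = 12)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  do.call(nfkb_params, yaml::read_yaml(file))
}

#' Write / read a stimulation protocol as structured text
#'
#' @param protocol an `nfkb_protocol`.
#' @param file path.
#' @export
write_protocol <- function(protocol, file) {
  yaml::write_yaml(list(t_end = protocol$t_end,
                        pulses = lapply(seq_len(nrow(protocol$pulses)),
                                        function(i) as.list(protocol$pulses[i, ]))),
                   file)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(file) {
  x <- yaml::read_yaml(file)
  pulses <- if (length(x$pulses))
    do.call(rbind, lapply(x$pulses, as.data.frame)) else NULL
  nfkb_protocol(pulses, t_end = x$t_end)
}
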