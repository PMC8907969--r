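#' Read and write parameter-set configuration files
#'
#' Flat `key: value` structured text with SI units and an explicit
#' `domain: biological|hardware` tag.
#'
#' @param params an [adex_params()] object.
#' @param path file path.
#' @return `read_params()` returns an [adex_params()]; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "adex_params"))
  num <- params[!vapply(params, is.logical, logical(1))]
  lgl <- params[vapply(params, is.logical, logical(1))]
  lines <- c(sprintf("domain: %s", attr(params, "domain")),
             sprintf("%s: %.17g", names(num), as.numeric(num)),
             sprintf("%s: %s", names(lgl), tolower(as.character(unlist(lgl)))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  get <- function(k) vals[match(k, keys)]
  num <- function(k) as.numeric(get(k))
  lgl <- function(k) identical(get(k), "true")
  adex_params(C_m = num("C_m"), g_l = num("g_l"), E_l = num("E_l"),
              Delta_T = num("Delta_T"), V_T = num("V_T"),
              V_th = num("V_th"), V_r = num("V_r"), t_r = num("t_r"),
              a = num("a"), b = num("b"), tau_w = num("tau_w"),
              enable_exp = lgl("enable_exp"),
              enable_adapt = lgl("enable_adapt"),
              enable_leak = lgl("enable_leak"),
              enable_threshold = lgl("enable_threshold"),
              I_exp_max = num("I_exp_max"),
              domain = get("domain"))
}

#' Read and write trace files
#'
#' Delimiter-separated files with header `time_s,neuron_id,V,w`.
#'
#' @param time,V,w trace vectors (or matrices with one column per neuron).
#' @param path file path.
#' @param neuron_id id(s) of the traced unit(s).
#' @return `read_traces()` returns a data frame; writers return `path`
#'   invisibly.
#' @export
write_traces <- function(time, V, w, path, neuron_id = 1) {
  V <- as.matrix(V); w <- as.matrix(w)
  ids <- if (length(neuron_id) == ncol(V)) neuron_id else seq_len(ncol(V))
  df <- do.call(rbind, lapply(seq_len(ncol(V)), function(j)
    data.frame(time_s = time, neuron_id = ids[j], V = V[, j], w = w[, j])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) utils::read.csv(path)

#' Read and write spike files
#'
#' Rows `time_s,neuron_id` sorted by time.
#'
#' @param times spike times (s).
#' @param neuron_id unit ids (recycled).
#' @param path file path.
#' @return `read_spikes()` returns a data frame; writers return `path`
#'   invisibly.
#' @export
write_spikes <- function(times, neuron_id, path) {
  df <- data.frame(time_s = times, neuron_id = neuron_id)
  df <- df[order(df$time_s), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) utils::read.csv(path)

#' Read and write crossbar event files
#'
#' Rows `time_s,row,label,payload`.
#'
#' @param events data frame with columns `time_s`, `row`, `label`,
#'   `payload`.
#' @param path file path.
#' @return `read_events()` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("time_s", "row", "label", "payload") %in% names(events)))
  utils::write.csv(events[order(events$time_s), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) utils::read.csv(path)
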