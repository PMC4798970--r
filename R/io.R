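# Validated readers/writers for the two data formats: long CSV for traces,
# wide TSV for expression matrices; JSON for parameter/forcing configs.

#' Write / read single-cell traces (long CSV)
#'
#' Columns \code{cell_id, time_min, nci}; UTF-8, '.' decimal, header
#' mandatory. The reader validates uniform sampling per cell and
#' non-negative NCI, and fails loudly otherwise.
#'
#' @param traces a [trace_set()].
#' @param path file path.
#' @return \code{write_traces} the path invisibly; \code{read_traces} a
#'   \code{trace_set}.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- do.call(rbind, lapply(names(traces$cells), function(id)
    data.frame(cell_id = id, time_min = traces$cells[[id]]$times,
               nci = traces$cells[[id]]$nci)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param sampling_interval expected sampling step (min); inferred from the
#'   first cell when NULL.
#' @export
read_traces <- function(path, sampling_interval = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "nci")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$time_min)) || any(!is.finite(df$nci)))
    stop("non-finite values in trace CSV (rows ",
         paste(utils::head(which(!is.finite(df$time_min) | !is.finite(df$nci)), 5),
               collapse = ", "), ")")
  ids <- unique(df$cell_id)
  cells <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, ]
    list(times = sub$time_min, nci = sub$nci)
  })
  names(cells) <- ids
  if (is.null(sampling_interval)) {
    tt <- cells[[1]]$times
    if (length(tt) < 2) stop("cannot infer sampling interval from a 1-point track")
    sampling_interval <- tt[2] - tt[1]
  }
  trace_set(cells, sampling_interval)
}

#' Write / read expression matrices (wide TSV)
#'
#' First column \code{gene_id}, remaining columns \code{time_<min>}. An
#' optional parallel TSV of detection p-values shares the layout.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @param detection_p_path optional path for the detection p-value TSV.
#' @return \code{write_expression} the path invisibly;
#'   \code{read_expression} an \code{expression_matrix}.
#' @export
write_expression <- function(em, path, detection_p_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  hdr <- c("gene_id", paste0("time_", em$timepoints))
  df <- data.frame(gene_id = rownames(em$values), em$values)
  names(df) <- hdr
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(detection_p_path) && !is.null(em$detection_p)) {
    dp <- data.frame(gene_id = rownames(em$values), em$detection_p)
    names(dp) <- hdr
    utils::write.table(dp, detection_p_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, detection_p_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  tcols <- names(df)[-1]
  if (!all(grepl("^time_", tcols)))
    stop("expression TSV columns must be named time_<min>")
  tp <- as.numeric(sub("^time_", "", tcols))
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(df$gene_id, NULL)
  dp <- NULL
  if (!is.null(detection_p_path)) {
    dpf <- utils::read.delim(detection_p_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    dp <- as.matrix(dpf[, -1, drop = FALSE])
    dimnames(dp) <- list(dpf$gene_id, NULL)
    dp <- dp[rownames(v), , drop = FALSE]
  }
  expression_matrix(v, tp, dp)
}

#' Write / read a model configuration (JSON)
#'
#' A named parameter set (values + uncertainty degrees) and, optionally,
#' named forcing protocols.
#'
#' @param params a [kinetic_params()].
#' @param degrees named uncertainty degrees.
#' @param forcings named list of [forcing_signal()] objects.
#' @param path file path.
#' @return \code{write_config} the path invisibly; \code{read_config} a
#'   list with \code{params}, \code{degrees}, \code{forcings}.
#' @export
write_config <- function(params, degrees = default_degrees(),
                         forcings = list(), path) {
  stopifnot(inherits(params, "kinetic_params"))
  cfg <- list(
    parameters = as.list(unlist(params[.kinetic_names])),
    repressor_active = params$repressor_active,
    degrees = as.list(degrees),
    forcings = lapply(forcings, function(f) {
      f <- unclass(f)
      if (!is.finite(f$t_end)) f$t_end <- NULL  # JSON has no Inf
      f[!vapply(f, is.null, logical(1))]
    }))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg),
                     c("parameters", "repressor_active", "degrees", "forcings"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(kinetic_params,
                    c(as.list(cfg$parameters),
                      list(repressor_active = isTRUE(cfg$repressor_active))))
  degrees <- unlist(cfg$degrees)
  forcings <- lapply(cfg$forcings, function(f) {
    f <- as.list(f)
    do.call(forcing_signal, f[!vapply(f, is.null, logical(1))])
  })
  list(params = params, degrees = degrees, forcings = forcings)
}
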