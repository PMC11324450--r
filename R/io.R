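# Delimited-table readers/writers for sweep and trace data, and structured
# report output. Files carry Pa units (the instrument's scale); the in-memory
# containers use kPa. Comma is the default delimiter; tab is accepted.

sweep_columns <- list(
  frequency = c("frequency_hz", "storage_pa", "loss_pa"),
  strain = c("strain_pct", "storage_pa", "loss_pa"),
  relaxation = c("time_s", "stress_pa")
)

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a sweep or trace table
#'
#' Parses a delimited text export (comma or tab, detected from the header)
#' into the matching container. Required columns by kind: `frequency` needs
#' `frequency_hz, storage_pa, loss_pa`; `strain` needs
#' `strain_pct, storage_pa, loss_pa`; `relaxation` needs `time_s, stress_pa`.
#' Values are unit-normalized (Pa on disk, kPa in memory), rows are sorted
#' on the abscissa, and the container's invariants (positive moduli, no
#' duplicate abscissae) are enforced.
#'
#' @param path File path.
#' @param kind `"frequency"`, `"strain"` or `"relaxation"`.
#' @param strain_step Step amplitude used to convert relaxation stress to a
#'   relaxation modulus (dimensionless). Default 0.001 (0.1%).
#' @param ... Passed to the container constructor (e.g. `strain_amplitude`).
#' @return A [frequency_sweep()], [strain_sweep()] or [relaxation_trace()].
#' @export
read_sweep_table <- function(path, kind = c("frequency", "strain", "relaxation"),
                             strain_step = 0.001, ...) {
  kind <- match.arg(kind)
  d <- read_delim_auto(path)
  need <- sweep_columns[[kind]]
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("read_sweep_table: ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) | is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("read_sweep_table: non-numeric cell at row %d, column '%s' of %s",
                   bad[1], col, path), call. = FALSE)
    d[[col]] <- v
  }
  xcol <- need[1]
  if (anyDuplicated(d[[xcol]]))
    stop("read_sweep_table: duplicate ", xcol, " values in ", path,
         call. = FALSE)
  d <- d[order(d[[xcol]]), , drop = FALSE]
  switch(kind,
    frequency = frequency_sweep(d$frequency_hz, d$storage_pa / 1000,
                                d$loss_pa / 1000, ...),
    strain = strain_sweep(d$strain_pct, d$storage_pa / 1000,
                          d$loss_pa / 1000, ...),
    relaxation = relaxation_trace(d$time_s,
                                  d$stress_pa / strain_step / 1000,
                                  strain_step = strain_step, ...))
}

#' Write a sweep or trace table
#'
#' Inverse of [read_sweep_table()]: emits the delimited text form (Pa units,
#' comma-separated) so that a write-then-read round trip reproduces the
#' container.
#'
#' @param x A [frequency_sweep()], [strain_sweep()] or [relaxation_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(x, path) {
  d <- if (inherits(x, "frequency_sweep")) {
    data.frame(frequency_hz = x$frequency, storage_pa = x$storage * 1000,
               loss_pa = x$loss * 1000)
  } else if (inherits(x, "strain_sweep")) {
    data.frame(strain_pct = x$strain_pct, storage_pa = x$storage * 1000,
               loss_pa = x$loss * 1000)
  } else if (inherits(x, "relaxation_trace")) {
    step <- attr(x, "strain_step")
    data.frame(time_s = x$time,
               stress_pa = x$relaxation_modulus * 1000 * step)
  } else stop("write_sweep_table: unsupported object", call. = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes a results table with a metadata block (frequency convention, seed,
#' package version, and any extra fields) so numbers stay interpretable.
#' CSV reports carry the metadata as leading `# key: value` comment lines;
#' JSON reports nest it under `metadata`. Column order is preserved, so
#' output is deterministic for a given input.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param metadata Named list; `convention` defaults to `"hz"` and
#'   `package_version` is always recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json"),
                         metadata = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (is.null(metadata$convention)) metadata$convention <- "hz"
  metadata$package_version <-
    as.character(utils::packageVersion("rheofrac"))
  if (format == "json") {
    jsonlite::write_json(list(metadata = metadata, results = results), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(metadata))
      writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
    utils::write.csv(results, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Literature elastography/rheometry frequency bands
#'
#' The frequency bands at which published studies report shear moduli of
#' the four organs (single frequencies have `f_hi = NA`). Used to
#' extrapolate a fitted springpot model onto each band for comparison with
#' the literature.
#'
#' @return A data frame with columns `organ_group` (measured organ, porcine
#'   or human), `profile` (which built-in organ profile supplies the model
#'   parameters), `f_lo`, `f_hi` (Hz).
#' @export
literature_frequency_bands <- function() {
  d <- rbind(
    data.frame(organ_group = "porcine heart", profile = "heart",
               f_lo = c(80, 40), f_hi = c(NA, 500)),
    data.frame(organ_group = "porcine kidney", profile = "kidney",
               f_lo = c(0.1, 0.01, 75, 50), f_hi = c(4, 20, 300, 500)),
    data.frame(organ_group = c(rep("porcine liver", 4), "human liver"),
               profile = "liver",
               f_lo = c(100, 75, 0.1, 0.1, 1), f_hi = c(200, 300, NA, 10, 30)),
    data.frame(organ_group = c(rep("porcine brain", 6), rep("human brain", 4)),
               profile = "brain",
               f_lo = c(589, 20, 260, 1, 0.04, 20, 25, 9, 2, 50),
               f_hi = c(NA, 200, 1000, 10, 16, 200, 62.5, 10, 10, NA))
  )
  rownames(d) <- NULL
  d
}

#' Predicted storage moduli over the literature frequency bands
#'
#' Evaluates each built-in organ profile's springpot storage modulus at the
#' endpoints of every band of [literature_frequency_bands()], rounding
#' half-up to 2 decimals, and formats single frequencies as one value and
#' bands as "lo-hi".
#'
#' @param convention `"hz"` (default) or `"rad"`.
#' @return The band table with columns `predicted_lo`, `predicted_hi` (kPa)
#'   and the formatted `predicted` string.
#' @export
sfkv_prediction_table <- function(convention = "hz") {
  bands <- literature_frequency_bands()
  profs <- lapply(stats::setNames(nm = unique(bands$profile)), organ_profile)
  lo <- hi <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    p <- profs[[bands$profile[i]]]$params
    lo[i] <- extrapolate_storage(p, bands$f_lo[i], convention)$rounded
    hi[i] <- if (is.na(bands$f_hi[i])) NA_real_ else
      extrapolate_storage(p, bands$f_hi[i], convention)$rounded
  }
  bands$predicted_lo <- lo
  bands$predicted_hi <- hi
  bands$predicted <- ifelse(is.na(hi), sprintf("%.2f", lo),
                            sprintf("%.2f-%.2f", lo, hi))
  bands
}
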