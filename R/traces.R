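#' Construct a single time-intensity trace
#'
#' An intensity trace is one replicate of a FRAP or FLAP acquisition: a
#' strictly increasing time axis in seconds and the fluorescence intensity
#' measured in the region of interest, either raw or normalized to the total
#' intensity of the protein pool.
#'
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing, at least 4 points.
#' @param intensities Numeric vector of the same length; arbitrary
#'   fluorescence units or normalized fraction.
#' @param modality `"FRAP"` (recovery of a bleached interior) or `"FLAP"`
#'   (loss of a photo-labelled interior pool).
#' @param label Free-text identifier (protein / replicate).
#' @return An object of class `intensity_trace` with fields `times`,
#'   `intensities`, `modality`, `label`.
#' @seealso [trace_set()], [read_traces()], [normalize_trace()]
#' @export
#' @examples
#' tr <- intensity_trace(seq(0, 90, 10), c(0, .2, .33, .42, .48, .52, .55, .56, .57, .58))
#' tr
intensity_trace <- function(times, intensities, modality = c("FRAP", "FLAP"),
                            label = "trace") {
  modality <- match.arg(toupper(modality[[1L]]), c("FRAP", "FLAP"))
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("`times` and `intensities` must have the same length")
  if (length(times) < 4L)
    stop("an intensity trace needs at least 4 points, got ", length(times))
  if (anyNA(times) || anyNA(intensities))
    stop("missing values are not allowed in a trace; drop them pairwise first")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(
    list(times = times, intensities = intensities,
         modality = modality, label = as.character(label)[[1L]]),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s, %s, %d points, t = [%g, %g] s\n",
              x$label, x$modality, length(x$times),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.intensity_trace <- function(x) length(x$times)

#' @export
as.data.frame.intensity_trace <- function(x, ...) {
  data.frame(time = x$times, intensity = x$intensities,
             modality = x$modality, label = x$label)
}

#' Construct a set of replicate traces for one protein
#'
#' @param traces List of [intensity_trace()] objects, all sharing the same
#'   modality.
#' @param protein Label for the protein the replicates belong to.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, protein = "protein") {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  if (!is.list(traces) || length(traces) == 0L)
    stop("`traces` must be a nonempty list of intensity traces")
  ok <- vapply(traces, inherits, logical(1L), what = "intensity_trace")
  if (!all(ok)) stop("all elements of `traces` must be intensity_trace objects")
  mods <- unique(vapply(traces, `[[`, character(1L), "modality"))
  if (length(mods) != 1L)
    stop("all traces in a set must share one modality, found: ",
         paste(mods, collapse = ", "))
  structure(list(traces = traces, protein = as.character(protein)[[1L]],
                 modality = mods),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %s: %d %s replicate(s)\n",
              x$protein, length(x$traces), x$modality))
  invisible(x)
}

#' @export
length.trace_set <- function(x) length(x$traces)

#' @export
`[.trace_set` <- function(x, i) trace_set(x$traces[i], protein = x$protein)

#' @export
as.data.frame.trace_set <- function(x, ...) {
  do.call(rbind, lapply(x$traces, as.data.frame))
}

#' Read replicate traces from a delimited text table
#'
#' The file must hold one time column (seconds, first column) followed by one
#' or more replicate intensity columns.  The field separator (comma, tab or
#' semicolon) is auto-detected and a header row is optional: a first row that
#' does not parse as numbers is treated as the header.  Missing cells (`NA`,
#' `NaN`, empty) are dropped pairwise with their time point, per replicate.
#'
#' @param path Path to the delimited file.
#' @param modality `"FRAP"` or `"FLAP"`.
#' @param dec Decimal mark, `"."` (default) or `","` for locales whose
#'   microscopy exports use the comma.
#' @param protein Protein label for the returned set; defaults to the file
#'   base name.
#' @return A [trace_set()] with one trace per intensity column.
#' @export
read_traces <- function(path, modality = c("FRAP", "FLAP"), dec = ".",
                        protein = NULL) {
  if (!is.character(path) || !file.exists(path))
    stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty file: ", path)

  seps <- c("\t", ",", ";")
  if (dec == ",") seps <- setdiff(seps, ",")
  counts <- vapply(seps, function(s)
    lengths(regmatches(lines[[1L]], gregexpr(s, lines[[1L]], fixed = TRUE))),
    integer(1L))
  sep <- if (all(counts == 0L)) "\t" else seps[[which.max(counts)]]

  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  first_num <- suppressWarnings(as.numeric(sub(",", ".", first, fixed = TRUE)))
  header <- anyNA(first_num)

  tab <- utils::read.table(text = lines, sep = sep, dec = dec, header = header,
                           na.strings = c("NA", "NaN", ""), fill = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("need a time column plus at least one intensity column")
  times <- as.numeric(tab[[1L]])
  keep_t <- !is.na(times)
  tab <- tab[keep_t, , drop = FALSE]
  times <- times[keep_t]
  if (any(diff(times) <= 0))
    stop("time column must be strictly increasing (non-monotone input)")

  labels <- if (header) colnames(tab)[-1L] else paste0("rep", seq_len(ncol(tab) - 1L))
  if (is.null(protein))
    protein <- sub("\\.[^.]*$", "", basename(path))
  traces <- vector("list", ncol(tab) - 1L)
  for (j in seq_along(traces)) {
    y <- as.numeric(tab[[j + 1L]])
    ok <- !is.na(y)
    if (sum(ok) < 4L)
      stop("replicate '", labels[[j]], "' has fewer than 4 valid points")
    traces[[j]] <- intensity_trace(times[ok], y[ok], modality = modality,
                                   label = labels[[j]])
  }
  trace_set(traces, protein = protein)
}

#' Write a trace set to a delimited text table
#'
#' Traces must share a common time grid (they are written as columns of one
#' table, readable back with [read_traces()]).
#'
#' @param x A [trace_set()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "trace_set"))
  times <- x$traces[[1L]]$times
  same <- vapply(x$traces, function(tr)
    length(tr$times) == length(times) && isTRUE(all.equal(tr$times, times)),
    logical(1L))
  if (!all(same)) stop("all traces must share one time grid to be written as a table")
  tab <- data.frame(time = times)
  for (tr in x$traces) tab[[tr$label]] <- tr$intensities
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a trace by a reference intensity
#'
#' Divides the intensities by a positive reference (typically the mean
#' pre-bleach or the total per-protein intensity), leaving times and modality
#' untouched.
#'
#' @param trace An [intensity_trace()].
#' @param reference Positive scalar; when `NULL` the reference is the mean of
#'   any pre-bleach points (`t < 0`) if present, else the maximum intensity.
#' @return The normalized trace.
#' @export
normalize_trace <- function(trace, reference = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(reference)) {
    pre <- trace$intensities[trace$times < 0]
    reference <- if (length(pre)) mean(pre) else max(trace$intensities)
  }
  if (!is.numeric(reference) || length(reference) != 1L || !is.finite(reference) ||
      reference <= 0)
    stop("`reference` must be a positive scalar")
  intensity_trace(trace$times, trace$intensities / reference,
                  modality = trace$modality, label = trace$label)
}

.rates_cols <- c("protein", "k_t", "sigma_k_t", "k_in", "sigma_k_in",
                 "k_out", "sigma_k_out", "n_in_bar", "sigma_n_in_bar")

#' Write dynamic rates to a delimited table
#'
#' One row per protein with columns protein, k_t, sigma_k_t, k_in,
#' sigma_k_in, k_out, sigma_k_out, n_in_bar, sigma_n_in_bar (rates in /s).
#' Values are printed with 15 significant digits so the table reads back to
#' identical values well beyond 12 significant digits.
#'
#' @param rates A [dynamic_rates()] object or a list of them.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @seealso [read_rates_table()]
#' @export
write_rates_table <- function(rates, path) {
  if (inherits(rates, "dynamic_rates")) rates <- list(rates)
  if (!is.list(rates) || length(rates) == 0L)
    stop("`rates` must be a nonempty list of dynamic_rates")
  rows <- lapply(rates, function(r) {
    stopifnot(inherits(r, "dynamic_rates"))
    data.frame(protein = r$protein,
               k_t = r$k_t, sigma_k_t = r$sigma_k_t,
               k_in = r$k_in, sigma_k_in = r$sigma_k_in,
               k_out = r$k_out, sigma_k_out = r$sigma_k_out,
               n_in_bar = r$n_in_bar, sigma_n_in_bar = r$sigma_n_in_bar)
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], formatC, digits = 15, format = "g")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dynamic-rates table written by [write_rates_table()]
#'
#' @param path Path to the tab-separated table.
#' @return A list of [dynamic_rates()] objects.
#' @export
read_rates_table <- function(path) {
  if (!file.exists(path)) stop("rates table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(.rates_cols %in% colnames(tab)))
    stop("not a rates table: missing columns")
  lapply(seq_len(nrow(tab)), function(i)
    dynamic_rates(k_t = tab$k_t[i], n_in_bar = tab$n_in_bar[i],
                  sigma_k_t = tab$sigma_k_t[i],
                  sigma_n_in_bar = tab$sigma_n_in_bar[i],
                  protein = tab$protein[i]))
}
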