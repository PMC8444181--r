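#' Per-cell fluorescence event tables
#'
#' An `event_table` is a validated `data.frame` of single-cell multiplexed
#' flow-cytometry events, one row per cell, carrying the two measured
#' channels (total STAT3 and STAT3 phosphorylated at Y705) together with the
#' condition metadata that identifies where the cell was measured: genotype,
#' Hy-IL-6 dose, stimulation time and replicate. It is the unit of all
#' downstream mutual-information and channel-capacity computation.
#'
#' Required columns (exact names): `cell_index`, `stat3`, `pstat3`,
#' `genotype`, `dose_ng_ml`, `time_min`, `replicate`. Channels are stored on
#' a linear intensity scale (arbitrary units) until [log_transform()] is
#' applied; `(genotype, dose_ng_ml, time_min, replicate)` jointly identify a
#' condition.
#'
#' @param df data.frame with the required columns.
#' @return `df` validated and classed as `event_table`.
#' @seealso [read_event_table()], [log_transform()], [display_subsample()]
#' @export
event_table <- function(df) {
  validate_event_table(df)
}

#' Genotype levels recognised throughout the package
#'
#' `wt`: wild-type MEF; `dEx3`: SHP2 exon-3 deletion mutant (SHP2 cannot be
#' recruited to gp130); `dEx3_SHP2`: the mutant reconstituted with wild-type
#' SHP2; `wt_U0126`: wild-type pre-treated with the MEK inhibitor U0126.
#'
#' @export
GENOTYPES <- c("wt", "dEx3", "dEx3_SHP2", "wt_U0126")

#' @export
EVENT_COLUMNS <- c(
  "cell_index", "stat3", "pstat3", "genotype",
  "dose_ng_ml", "time_min", "replicate"
)

validate_event_table <- function(df, context = "event table") {
  if (!is.data.frame(df)) {
    stop(context, ": expected a data.frame, got ", class(df)[1L], call. = FALSE)
  }
  missing <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing)) {
    stop(
      context, ": missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) {
    stop(context, ": table contains no events", call. = FALSE)
  }
  for (col in c("stat3", "pstat3", "dose_ng_ml", "time_min")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop(context, ": column '", col, "' must be numeric", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop(context, ": column '", col, "' contains non-finite values",
        call. = FALSE
      )
    }
    df[[col]] <- as.numeric(v) # integer-parsed CSV columns become double
  }
  if (any(df$dose_ng_ml < 0)) {
    stop(context, ": doses must be >= 0 ng/ml", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$genotype)), GENOTYPES)
  if (length(bad)) {
    stop(
      context, ": unknown genotype(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(GENOTYPES, collapse = ", "), ")",
      call. = FALSE
    )
  }
  class(df) <- unique(c("event_table", class(df)))
  df
}

#' Read a per-cell event table from CSV
#'
#' Reads a CSV file with the canonical columns `cell_index, stat3, pstat3,
#' genotype, dose_ng_ml, time_min, replicate` and validates it. Row order is
#' preserved.
#'
#' @param path path to a CSV file.
#' @return an [event_table()].
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop("empty event table: ", path, call. = FALSE)
  }
  validate_event_table(df, context = path)
}

#' Write an event table to CSV
#'
#' @param events an [event_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  events <- validate_event_table(events)
  utils::write.csv(as.data.frame(events)[EVENT_COLUMNS], path,
    row.names = FALSE
  )
  invisible(path)
}

#' Log10-transform fluorescence channels with a positive floor
#'
#' Replaces both channel columns by `log10(pmax(value, floor))`. Methanol-
#' fixed flow data can contain near-zero events; flooring at a small positive
#' intensity (default 1 a.u.) keeps the transform defined while leaving all
#' values above the floor exactly invertible. The number of floored values is
#' attached as attribute `n_floored`.
#'
#' @param events an [event_table()] on the linear intensity scale.
#' @param floor positive intensity below which values are clipped before the
#'   log (a.u.).
#' @return an [event_table()] with `stat3`/`pstat3` on the log10 scale;
#'   attributes `n_floored` (count of clipped values) and `log10 = TRUE`.
#' @export
log_transform <- function(events, floor = 1) {
  events <- validate_event_table(events)
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  if (isTRUE(attr(events, "log10"))) {
    stop("event table is already log10-transformed", call. = FALSE)
  }
  n_floored <- 0L
  for (col in c("stat3", "pstat3")) {
    v <- events[[col]]
    n_floored <- n_floored + sum(v < floor)
    events[[col]] <- log10(pmax(v, floor))
  }
  attr(events, "n_floored") <- n_floored
  attr(events, "log10") <- TRUE
  events
}

#' Normalise a channel so the largest condition mean equals 100%
#'
#' The display convention for fluorescence intensities: the channel is
#' rescaled by one global factor `100 / max(condition means)` so the
#' condition with the largest mean fluorescence sits at exactly 100%.
#' Conditions are defined by `(genotype, dose_ng_ml, time_min, replicate)`
#' when a single table is given; a list of tables is treated as one table
#' per condition.
#'
#' @param tables an [event_table()] or a list of them.
#' @param channel `"stat3"` or `"pstat3"`.
#' @return same shape as `tables`, with the channel rescaled; attribute
#'   `scale_factor` records the applied factor.
#' @export
normalize_to_max_mean <- function(tables, channel = c("pstat3", "stat3")) {
  channel <- match.arg(channel)
  single <- is.data.frame(tables)
  tabs <- if (single) {
    tab <- validate_event_table(tables)
    key <- interaction(tab$genotype, tab$dose_ng_ml, tab$time_min,
      tab$replicate,
      drop = TRUE
    )
    split(as.data.frame(tab), key)
  } else {
    lapply(tables, validate_event_table)
  }
  if (!length(tabs)) stop("no conditions supplied", call. = FALSE)
  means <- vapply(tabs, function(t) mean(t[[channel]]), numeric(1))
  top <- max(means)
  if (!is.finite(top) || top <= 0) {
    stop(
      "degenerate normalisation: largest condition mean of '", channel,
      "' is ", top,
      call. = FALSE
    )
  }
  factor <- 100 / top
  rescale <- function(t) {
    t[[channel]] <- t[[channel]] * factor
    t
  }
  if (single) {
    out <- tables
    out[[channel]] <- out[[channel]] * factor
    attr(out, "scale_factor") <- factor
    return(out)
  }
  out <- lapply(tables, rescale)
  attr(out, "scale_factor") <- factor
  out
}

#' Random display subsample of an event table
#'
#' Uniform subsample without replacement of `min(n, nrow)` events,
#' reproducible under `seed`; matches the convention of displaying ~1000
#' randomly selected events per concentration rather than every recorded
#' cell. The caller's RNG state is left untouched.
#'
#' @param events an [event_table()].
#' @param n number of events to keep (default 1000).
#' @param seed integer seed controlling the draw.
#' @return an [event_table()] with at most `n` rows.
#' @export
display_subsample <- function(events, n = 1000, seed = 1) {
  events <- validate_event_table(events)
  stopifnot(n >= 0)
  if (n >= nrow(events)) {
    return(events)
  }
  idx <- with_seed(seed, sample.int(nrow(events), n))
  out <- events[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
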